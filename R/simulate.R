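#' Parameters for the synthetic owner-response cohort
#'
#' Assembles the parameter list driving [simulate_cohort()].  The
#' defaults emulate the two-group study population the analyses assume:
#' 343 PPID and 269 non-PPID horses, group age distributions of
#' 24.34 +/- 6.60 and 19.84 +/- 5.16 years, covariate category
#' frequencies close to the published population profile, and a latent
#' severity
#' \deqn{\theta = \beta_{ppid} PPID + \beta_{chronic} chronic +
#'   \beta_{age}(age - \bar a) + \epsilon,\quad \epsilon \sim N(0,1)}
#' from which ordinal item responses are generated by a
#' proportional-odds (graded-response) link: the item latent is
#' \eqn{a\theta} plus standard logistic noise, cut at equally spaced
#' thresholds.  Effect sizes and thresholds are calibrated so that
#' scored group HRQoL medians land near 0.33 (PPID) and 0.20
#' (non-PPID), the separation the instrument is meant to resolve.
#'
#' @param n_ppid,n_control Group sizes.
#' @param age_ppid,age_control \code{c(mean, sd)} of the per-group
#'   normal age model (years).
#' @param beta Named vector of latent-severity coefficients:
#'   \code{ppid}, \code{chronic}, \code{age} (per year, centred at
#'   \code{age_center}).
#' @param age_center Centre of the age covariate in the latent model.
#' @param theta_sd SD of the latent noise term.
#' @param discrimination Default item discrimination (loading of the
#'   item latent on theta).
#' @param th_first,th_step First threshold and spacing of the equally
#'   spaced item thresholds.
#' @param p_unobs Probability of answering "I have not been able to
#'   observe this" where offered, independent of severity
#'   (unobservability reflects housing, not disease).
#' @param p_na Probability of the "does not receive meds/suppl." answer
#'   where offered.
#' @param qol_discrimination,qol_thresholds Proportional-odds model of
#'   the owner's global 1--5 QoL rating on theta (rating increases,
#'   i.e. worsens, with severity).
#' @param chronic_prev Named prevalence of other chronic conditions per
#'   group.
#' @param treated_prev Proportion of PPID horses on treatment.
#' @param years_diag \code{c(meanlog, sdlog)} of the log-normal years
#'   since diagnosis (median 2, quartile ratio matching IQR 1--6).
#' @param rater List: \code{subject_mean}, \code{subject_sd} of the
#'   true score among reliability subjects, \code{rater_sd} (between
#'   rater systematic offsets) and \code{occasion_sd} (within-rater
#'   noise), all on the HRQoL score scale.
#' @param planted Named list of per-item structure overrides used by
#'   the planted refinement bank: each element is a list with
#'   \code{type} in \code{"nondiscriminating"} (item loads on an
#'   idiosyncratic latent shared by neither group), \code{"noise"}
#'   (item responds to group membership only, not severity;
#'   \code{group_shift}) or \code{"redundant"} (item copies the latent
#'   draw of item \code{of} plus \code{sd} noise).
#' @param seed Default RNG seed used by the simulators.
#' @return List of class \code{simulation_params}.
#' @export
simulation_params <- function(n_ppid = 343, n_control = 269,
                              age_ppid = c(24.34, 6.60),
                              age_control = c(19.84, 5.16),
                              beta = c(ppid = 0.65, chronic = 0.35,
                                       age = 0.02),
                              age_center = 22.4,
                              theta_sd = 1,
                              discrimination = 1.2,
                              th_first = 0.40, th_step = 1.27,
                              p_unobs = 0.03, p_na = 0.12,
                              qol_discrimination = 1.0,
                              qol_thresholds = c(0.8, 4.0, 5.6, 7.4),
                              chronic_prev = c(ppid = 0.353,
                                               control = 0.480),
                              treated_prev = 0.869,
                              years_diag = c(meanlog = log(2),
                                             sdlog = 1.328),
                              rater = list(subject_mean = 0.30,
                                           subject_sd = 0.12,
                                           rater_sd = 0.03,
                                           occasion_sd = 0.03),
                              planted = NULL,
                              seed = NULL) {
  p <- as.list(environment())
  stopifnot(n_ppid > 0, n_control > 0, theta_sd > 0,
            all(diff(c(p$th_first,
                       p$th_first + p$th_step * seq_len(3))) > 0),
            all(diff(qol_thresholds) > 0),
            p_unobs >= 0, p_unobs < 1, p_na >= 0, p_na < 1)
  structure(p, class = "simulation_params")
}

item_thresholds <- function(ncat, params) {
  if (ncat < 2) stop("item needs >= 2 ordered categories", call. = FALSE)
  params$th_first + params$th_step * (0:(ncat - 2))
}

# Table 3-style covariate category frequencies (renormalized).
cov_frequencies <- function() {
  list(
    breed = list(
      levels = c("native", "warmblood", "thoroughbred", "arabian",
                 "draught", "cross", "other"),
      ppid = c(48.1, 9.9, 9.3, 6.4, 4.4, 8.5, 13.1),
      control = c(44.2, 16.7, 16.4, 4.1, 5.9, 6.7, 5.9)),
    sex = list(
      levels = c("mare", "gelding", "stallion"),
      ppid = c(43.7, 56.0, 0.3),
      control = c(35.3, 63.9, 0.7)),
    body_condition = list(
      levels = c("very underweight", "slightly underweight",
                 "ideal weight", "slightly overweight",
                 "very overweight"),
      ppid = c(3.8, 20.7, 53.4, 21.0, 1.2),
      control = c(0.7, 7.1, 41.3, 46.8, 3.7)))
}

sample_cat <- function(n, spec, group_field) {
  p <- spec[[group_field]]
  sample(spec$levels, n, replace = TRUE, prob = p / sum(p))
}

#' Simulate an owner-response cohort
#'
#' Draws a cohort of horses (group membership, covariates, latent
#' severity) and their owners' item responses to an instrument, plus
#' the owner's global 1--5 QoL rating.  Responses are ordinal
#' proportional-odds draws that shift toward worse-scored options as
#' latent severity increases; planted item structures (see
#' [simulation_params()]) allow non-discriminating, noise-only and
#' redundant items for testing the refinement pipeline.
#'
#' Identical parameters and seed give byte-identical output.
#'
#' @param params A [simulation_params()] list.
#' @param instrument The instrument to answer; defaults to the packaged
#'   \code{"ppid-final-24"}.
#' @param seed RNG seed (defaults to \code{params$seed}).
#' @return Data frame with one row per horse: \code{horse_id},
#'   \code{group}, \code{ppid}, covariates, \code{owner_global_qol}
#'   and one response-label column per item id.  The latent severity
#'   is attached as attribute \code{"theta"}.
#' @export
#' @examples
#' co <- simulate_cohort(simulation_params(n_ppid = 30, n_control = 30),
#'                       seed = 1)
#' table(co$group)
simulate_cohort <- function(params = simulation_params(),
                            instrument = NULL, seed = params$seed) {
  stopifnot(inherits(params, "simulation_params"))
  if (is.null(instrument)) instrument <- load_instrument("ppid-final-24")
  if (!is.null(seed)) set.seed(seed)
  n1 <- params$n_ppid; n0 <- params$n_control; n <- n1 + n0
  ppid <- rep(c(1L, 0L), c(n1, n0))
  grp <- ifelse(ppid == 1L, "ppid", "non-ppid")
  age <- c(stats::rnorm(n1, params$age_ppid[1], params$age_ppid[2]),
           stats::rnorm(n0, params$age_control[1], params$age_control[2]))
  age <- pmax(age, 5)
  chronic <- stats::rbinom(n, 1,
    ifelse(ppid == 1L, params$chronic_prev[["ppid"]],
           params$chronic_prev[["control"]]))
  fr <- cov_frequencies()
  pick <- function(spec) {
    out <- character(n)
    out[ppid == 1L] <- sample_cat(n1, spec, "ppid")
    out[ppid == 0L] <- sample_cat(n0, spec, "control")
    out
  }
  breed <- pick(fr$breed)
  sex <- pick(fr$sex)
  bcs <- pick(fr$body_condition)
  treatment <- ifelse(ppid == 1L,
                      ifelse(stats::runif(n) < params$treated_prev,
                             "treated", "untreated"),
                      "none")
  years_diag <- ifelse(ppid == 1L,
                       stats::rlnorm(n, params$years_diag[["meanlog"]],
                                     params$years_diag[["sdlog"]]),
                       NA_real_)

  b <- params$beta
  theta <- b[["ppid"]] * ppid + b[["chronic"]] * chronic +
    b[["age"]] * (age - params$age_center) +
    stats::rnorm(n, 0, params$theta_sd)

  planted <- params$planted %||% list()
  latents <- list()    # per-item continuous draws, for redundancy
  resp <- list()
  for (id in item_ids(instrument)) {
    it <- instrument$items[[id]]
    reg <- it$options[it$options$kind == "regular", ]
    reg <- reg[order(reg$score), , drop = FALSE]
    th <- item_thresholds(nrow(reg), params)
    pl <- planted[[id]]
    type <- pl$type %||% "normal"
    a <- pl$discrimination %||% params$discrimination
    v <- switch(type,
      normal = a * theta + stats::rlogis(n),
      nondiscriminating = a * stats::rnorm(n) + stats::rlogis(n),
      noise = (pl$group_shift %||% 1.2) * ppid + stats::rlogis(n),
      redundant = {
        of <- pl$of
        if (is.null(latents[[of]]))
          stop("redundant item ", id, " must follow its partner ", of,
               call. = FALSE)
        latents[[of]] + stats::rnorm(n, 0, pl$sd %||% 0.8)
      },
      stop("unknown planted type '", type, "' for item ", id,
           call. = FALSE))
    latents[[id]] <- v
    lab <- reg$label[findInterval(v, th) + 1L]
    for (kind in c("unobservable", "not-applicable")) {
      sp <- it$options[it$options$kind == kind, , drop = FALSE]
      if (nrow(sp)) {
        pr <- if (kind == "unobservable") params$p_unobs else params$p_na
        hit <- stats::runif(n) < pr
        lab[hit] <- sp$label[1L]
      }
    }
    resp[[id]] <- lab
  }

  vq <- params$qol_discrimination * theta + stats::rlogis(n)
  qol <- findInterval(vq, params$qol_thresholds) + 1L

  out <- data.frame(horse_id = sprintf("h%04d", seq_len(n)),
                    group = grp, ppid = ppid, age = age,
                    chronic = chronic, breed = breed, sex = sex,
                    body_condition = bcs, treatment = treatment,
                    years_diagnosed = years_diag,
                    owner_global_qol = qol,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(resp, stringsAsFactors = FALSE))
  attr(out, "theta") <- theta
  out
}

#' The planted 10-item refinement test bank
#'
#' An instrument built in code for exercising [refine_items()] with a
#' known ground truth: six ordinary severity-loaded items (p01--p06),
#' one redundant twin of p01 in the same domain (p07), two
#' non-discriminating items (p08, p09) and one group-only noise item
#' (p10).  [planted_params()] returns the matching
#' [simulation_params()] with these structures planted; the expected
#' terminal dispositions are: p08 and p09 dropped (non-discriminating),
#' p01 and p07 merged, p10 dropped (low item-total), p02--p06 retained.
#'
#' @return An \code{hrqol_instrument} with 10 four-option items.
#' @export
planted_bank <- function() {
  freq <- list(list(label = "Never", score = 0),
               list(label = "Occasionally", score = 1),
               list(label = "Often", score = 2),
               list(label = "All the time", score = 3))
  doms <- c(p01 = "demeanour", p02 = "appearance", p03 = "condition",
            p04 = "health", p05 = "appetite", p06 = "management",
            p07 = "demeanour", p08 = "health", p09 = "management",
            p10 = "appetite")
  items <- lapply(names(doms), function(id)
    list(id = id, domain = doms[[id]], polarity = "negative",
         text = paste("synthetic planted item", id), options = freq))
  parse_instrument(list(name = "planted-bank-10", items = items,
                        weights = as.list(stats::setNames(
                          rep(5L, 7), hrqol_domains()))),
                   source = "<planted-bank>")
}

#' @rdname planted_bank
#' @param ... Overrides passed to [simulation_params()].
#' @export
planted_params <- function(...) {
  simulation_params(
    discrimination = 1.5,
    beta = c(ppid = 1.0, chronic = 0.35, age = 0.02),
    planted = list(
      p07 = list(type = "redundant", of = "p01", sd = 0.8),
      p08 = list(type = "nondiscriminating"),
      p09 = list(type = "nondiscriminating"),
      p10 = list(type = "noise", group_shift = 1.2)),
    ...)
}

#' Simulate paired-rater HRQoL scores
#'
#' Generates the two reliability designs: \code{inter} -- two raters
#' scoring the same horses at the same time (shared true score, per
#' rater systematic offset, independent occasion noise) -- and
#' \code{intra} -- one rater scoring the same horses on two occasions
#' (shared true score and rater offset, independent occasion noise).
#'
#' @param n_inter,n_intra Numbers of horses in each design.
#' @param params A [simulation_params()]; its \code{rater} element
#'   supplies the variance components unless overridden.
#' @param subject_mean,subject_sd,rater_sd,occasion_sd Optional
#'   overrides of the rater model components.
#' @param truth Optional vector of true subject scores (e.g. scored
#'   HRQoL of a cohort subset); overrides the normal subject model.
#' @param seed RNG seed (defaults to \code{params$seed}).
#' @return List of class \code{rater_sim} with matrices \code{inter}
#'   (n_inter x 2, columns = raters) and \code{intra} (n_intra x 2,
#'   columns = occasions).
#' @export
simulate_raters <- function(n_inter = 8, n_intra = 7,
                            params = simulation_params(),
                            subject_mean = NULL, subject_sd = NULL,
                            rater_sd = NULL, occasion_sd = NULL,
                            truth = NULL, seed = params$seed) {
  r <- params$rater
  subject_mean <- subject_mean %||% r$subject_mean
  subject_sd <- subject_sd %||% r$subject_sd
  rater_sd <- rater_sd %||% r$rater_sd
  occasion_sd <- occasion_sd %||% r$occasion_sd
  if (!is.null(seed)) set.seed(seed)

  draw_truth <- function(n) {
    if (!is.null(truth)) {
      if (length(truth) < n)
        stop("'truth' shorter than the requested subset", call. = FALSE)
      truth[seq_len(n)]
    } else stats::rnorm(n, subject_mean, subject_sd)
  }
  t_inter <- draw_truth(n_inter)
  off <- stats::rnorm(2, 0, rater_sd)           # two raters
  inter <- cbind(
    rater1 = t_inter + off[1] + stats::rnorm(n_inter, 0, occasion_sd),
    rater2 = t_inter + off[2] + stats::rnorm(n_inter, 0, occasion_sd))

  t_intra <- draw_truth(n_intra)
  off1 <- stats::rnorm(1, 0, rater_sd)          # the single rater
  intra <- cbind(
    occasion1 = t_intra + off1 + stats::rnorm(n_intra, 0, occasion_sd),
    occasion2 = t_intra + off1 + stats::rnorm(n_intra, 0, occasion_sd))

  structure(list(inter = inter, intra = intra), class = "rater_sim")
}

#' Raw item score matrix from a cohort table
#'
#' Converts the response-label columns of a simulated or read cohort
#' into the numeric score matrix used by the psychometric stage.
#'
#' @param instrument The instrument the responses answer.
#' @param cohort Cohort data frame with one column per item id.
#' @return Numeric matrix, rows = horses, columns = item ids.
#' @export
cohort_score_matrix <- function(instrument, cohort) {
  ids <- item_ids(instrument)
  absent <- setdiff(ids, names(cohort))
  if (length(absent))
    stop("cohort lacks item column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  m <- vapply(ids, function(id) {
    it <- instrument$items[[id]]
    vapply(cohort[[id]], function(l) score_item(it, l), numeric(1),
           USE.NAMES = FALSE)
  }, numeric(nrow(cohort)))
  rownames(m) <- cohort$horse_id
  m
}
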