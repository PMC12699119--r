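#' Square-root transform of HRQoL scores
#'
#' HRQoL scores are bounded in [0, 1] and right-skewed in typical
#' cohorts; the square root is the variance-stabilising transform used
#' before the linear-model stage.
#'
#' @param scores Numeric vector with entries in [0, 1].
#' @return Element-wise square root.
#' @export
sqrt_transform <- function(scores) {
  if (!is.numeric(scores) || anyNA(scores))
    stop("scores must be numeric without NA", call. = FALSE)
  if (any(scores < 0) || any(scores > 1))
    stop("scores must lie in [0, 1]", call. = FALSE)
  sqrt(scores)
}

#' Model presets for the HRQoL association stage
#'
#' Two packaged model specifications:
#' \describe{
#'   \item{\code{"all-horses"}}{fixed binary factors PPID diagnosis and
#'     other chronic conditions; categorical factors breed, sex and
#'     body condition; covariate age; two-way interactions of every
#'     factor with age.}
#'   \item{\code{"ppid-only"}}{fixed binary factors PPID treatment and
#'     other chronic conditions; categorical factors breed, sex and
#'     body condition; covariates age and years since diagnosis;
#'     two-way interactions of every factor with each covariate.}
#' }
#' Only factor-by-covariate interactions enter; covariate-by-covariate
#' and factor-by-factor interactions are excluded to limit the number
#' of tests.
#'
#' @param preset \code{"all-horses"} or \code{"ppid-only"}.
#' @return List with \code{dependent}, \code{fixed},
#'   \code{categorical}, \code{covariates} and \code{interactions}
#'   (character vector of \code{a:b} terms).
#' @export
model_preset <- function(preset = c("all-horses", "ppid-only")) {
  preset <- match.arg(preset)
  spec <- if (preset == "all-horses") {
    list(fixed = c("ppid", "chronic"),
         categorical = c("breed", "sex", "body_condition"),
         covariates = "age")
  } else {
    list(fixed = c("treatment", "chronic"),
         categorical = c("breed", "sex", "body_condition"),
         covariates = c("age", "years_diagnosed"))
  }
  spec$dependent <- "hrqol_sqrt"
  spec$interactions <- as.vector(outer(
    c(spec$fixed, spec$categorical), spec$covariates, paste, sep = ":"))
  spec$name <- preset
  spec
}

#' Fit the HRQoL general linear model
#'
#' Least-squares fit of square-root-transformed HRQoL scores on the
#' preset's factors, covariates and factor-by-covariate interactions,
#' with Type III sums of squares (sum-to-zero contrasts) and F tests
#' against the residual mean square.  Rows with missing model
#' variables are dropped listwise.  Residual diagnostics (Shapiro-Wilk
#' normality; a Breusch-Pagan-style homoscedasticity flag from
#' regressing squared residuals on fitted values) are attached.
#'
#' Breed, sex and body condition are fitted as fixed categorical
#' effects; all terms are tested against the residual mean square
#' rather than expected-mean-square composites.
#'
#' @param data Data frame with an \code{hrqol} column (scores in
#'   [0, 1]) or an \code{hrqol_sqrt} column, plus the preset's model
#'   variables.
#' @param preset Preset name (see [model_preset()]) or a preset list.
#' @return An object of class \code{association_report}: \code{table}
#'   (term, F, df1, df2, p), \code{diagnostics}, \code{n_used},
#'   \code{n_dropped}, \code{fit} (the underlying \code{lm}).
#' @export
fit_hrqol_glm <- function(data, preset = "all-horses") {
  if (is.character(preset)) preset <- model_preset(preset)
  stopifnot(is.data.frame(data))
  if (is.null(data$hrqol_sqrt)) {
    if (is.null(data$hrqol))
      stop("data needs an 'hrqol' or 'hrqol_sqrt' column", call. = FALSE)
    data$hrqol_sqrt <- sqrt_transform(data$hrqol)
  }
  vars <- c(preset$fixed, preset$categorical, preset$covariates)
  absent <- setdiff(vars, names(data))
  if (length(absent))
    stop("data lacks model variable(s): ", paste(absent, collapse = ", "),
         call. = FALSE)

  keep <- stats::complete.cases(data[, c(preset$dependent, vars)])
  n_dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  for (v in c(preset$fixed, preset$categorical))
    d[[v]] <- droplevels(factor(d[[v]]))
  # a level needs more observations than its interaction columns
  # (1 + number of covariates) to be estimable; thinner levels are
  # excluded and reported
  min_level <- length(preset$covariates) + 2L
  rare <- character(0)
  for (v in c(preset$fixed, preset$categorical)) {
    tab <- table(d[[v]])
    lv <- names(tab)[tab < min_level]
    if (length(lv)) {
      rare <- c(rare, paste0(v, "=", lv))
      d <- d[!d[[v]] %in% lv, , drop = FALSE]
      d[[v]] <- droplevels(d[[v]])
    }
  }
  # centre covariates so Type III main effects of factors are evaluated
  # at the covariate mean rather than at zero
  centers <- vapply(preset$covariates, function(v) mean(d[[v]]),
                    numeric(1))
  for (v in preset$covariates) d[[v]] <- d[[v]] - mean(d[[v]])
  single <- vars[vapply(vars, function(v)
    is.factor(d[[v]]) && nlevels(d[[v]]) < 2, logical(1))]
  d <- d[, setdiff(names(d), single), drop = FALSE]
  use_fac <- setdiff(c(preset$fixed, preset$categorical), single)
  terms <- c(use_fac, preset$covariates,
             as.vector(outer(use_fac, preset$covariates, paste,
                             sep = ":")))
  fml <- stats::reformulate(terms, response = preset$dependent)
  contr <- stats::setNames(
    replicate(length(use_fac), "contr.sum", simplify = FALSE), use_fac)
  fit <- stats::lm(fml, data = d, contrasts = contr)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("singular design; aliased coefficients: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  an <- car::Anova(fit, type = "III")
  rows <- setdiff(rownames(an), c("(Intercept)", "Residuals"))
  df2 <- an["Residuals", "Df"]
  tab <- data.frame(term = rows,
                    F = an[rows, "F value"],
                    df1 = an[rows, "Df"],
                    df2 = df2,
                    p = an[rows, "Pr(>F)"],
                    row.names = NULL, stringsAsFactors = FALSE)

  res <- stats::residuals(fit)
  norm <- if (length(res) >= 3 && length(res) <= 5000 &&
              stats::var(res) > 0) {
    check_normality(res)
  } else list(W = NA_real_, p.value = NA_real_)
  bp <- bp_flag(fit)
  structure(list(table = tab,
                 diagnostics = list(shapiro_W = norm$W,
                                    shapiro_p = norm$p.value,
                                    bp_p = bp$p.value,
                                    heteroscedastic = bp$flag),
                 n_used = nrow(d), n_dropped = n_dropped,
                 covariate_centers = centers,
                 dropped_rare_levels = rare,
                 dropped_single_level = single,
                 preset = preset$name %||% "custom", fit = fit),
            class = "association_report")
}

# Breusch-Pagan-style spread check: squared residuals on fitted values.
bp_flag <- function(fit, alpha = 0.05) {
  r2 <- stats::residuals(fit)^2
  f <- stats::fitted(fit)
  if (stats::var(f) == 0 || stats::var(r2) == 0)
    return(list(p.value = NA_real_, flag = NA))
  aux <- stats::lm(r2 ~ f)
  p <- stats::anova(aux)[["Pr(>F)"]][1]
  list(p.value = p, flag = p < alpha)
}

#' Shapiro-Wilk normality check
#'
#' @param residuals Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with \code{W} and \code{p.value}.
#' @export
check_normality <- function(residuals) {
  n <- length(residuals)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  if (stats::var(residuals) == 0)
    stop("constant residuals: normality test undefined", call. = FALSE)
  ht <- stats::shapiro.test(residuals)
  list(W = unname(ht$statistic), p.value = ht$p.value)
}

#' @export
print.association_report <- function(x, ...) {
  cat("HRQoL association model (preset '", x$preset, "', Type III)\n",
      sep = "")
  cat(sprintf(" n = %d (%d row(s) dropped for missing values)\n",
              x$n_used, x$n_dropped))
  if (length(x$dropped_single_level))
    cat(" single-level factor(s) omitted:",
        paste(x$dropped_single_level, collapse = ", "), "\n")
  if (length(x$dropped_rare_levels))
    cat(" rows in single-observation level(s) excluded:",
        paste(x$dropped_rare_levels, collapse = ", "), "\n")
  tt <- x$table
  for (i in seq_len(nrow(tt)))
    cat(sprintf("  %-28s F(%d,%d) = %8.3f  p = %.4g%s\n", tt$term[i],
                tt$df1[i], tt$df2[i], tt$F[i], tt$p[i],
                if (tt$p[i] < 0.05) " *" else ""))
  d <- x$diagnostics
  cat(sprintf(" residual normality: W = %.3f, p = %.3g; %s\n",
              d$shapiro_W, d$shapiro_p,
              if (isTRUE(d$heteroscedastic))
                "heteroscedasticity flagged"
              else "no heteroscedasticity flag"))
  invisible(x)
}
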