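#' Cronbach's alpha
#'
#' Internal-consistency coefficient of a set of items,
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i var_i}{var_{total}}\right)}
#' with sample variances (denominator \eqn{n-1}) and
#' \eqn{var_{total}} the variance of the respondent total score.
#'
#' @param x Numeric matrix or data frame: rows = respondents, columns =
#'   items (raw unweighted item scores), no missing entries.
#' @return A single number, at most 1 (may be negative for
#'   inconsistent item sets).
#' @export
#' @examples
#' m <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
#' cronbach_alpha(m)
cronbach_alpha <- function(x) {
  x <- as_score_matrix(x, min_items = 2L, min_rows = 3L)
  total <- rowSums(x)
  vt <- stats::var(total)
  if (vt == 0)
    stop("total-score variance is zero: alpha undefined", call. = FALSE)
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / vt)
}

as_score_matrix <- function(x, min_items = 2L, min_rows = 3L) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("item scores must be numeric", call. = FALSE)
  if (anyNA(x)) stop("item score matrix contains missing entries",
                     call. = FALSE)
  if (ncol(x) < min_items)
    stop("need at least ", min_items, " items", call. = FALSE)
  if (nrow(x) < min_rows)
    stop("need at least ", min_rows, " respondents", call. = FALSE)
  x
}

#' Corrected item-total correlations
#'
#' For each item, the Pearson correlation between the item and the sum
#' of all \emph{other} items.  Items that correlate poorly
#' (conventionally r < 0.30) with the corrected total are candidates
#' for removal during refinement.
#'
#' @inheritParams cronbach_alpha
#' @return Named numeric vector of corrected correlations; \code{NA}
#'   (with a warning) for zero-variance items.
#' @export
item_total_correlations <- function(x) {
  x <- as_score_matrix(x)
  total <- rowSums(x)
  r <- vapply(seq_len(ncol(x)), function(j) {
    rest <- total - x[, j]
    if (stats::var(x[, j]) == 0 || stats::var(rest) == 0) NA_real_
    else stats::cor(x[, j], rest)
  }, numeric(1))
  names(r) <- colnames(x)
  if (anyNA(r))
    warning("zero-variance item(s): ",
            paste(names(r)[is.na(r)], collapse = ", "),
            "; correlation undefined", call. = FALSE)
  r
}

#' Inter-item correlation matrix
#'
#' Pearson correlations between all item pairs; symmetric with unit
#' diagonal.  Within-domain pairs above r = 0.60 are treated as
#' redundant during refinement.
#'
#' @inheritParams cronbach_alpha
#' @return Symmetric correlation matrix; rows/columns of zero-variance
#'   items are \code{NA} with a warning.
#' @export
inter_item_matrix <- function(x) {
  x <- as_score_matrix(x)
  zv <- apply(x, 2, stats::var) == 0
  if (any(zv))
    warning("zero-variance item(s): ",
            paste(colnames(x)[zv], collapse = ", "), call. = FALSE)
  r <- suppressWarnings(stats::cor(x))
  diag(r) <- 1
  r
}

#' Chi-squared item discrimination between groups
#'
#' Pearson chi-squared test of independence between an item's response
#' categories and group membership (PPID vs. non-PPID).  Items whose
#' response distributions do not differ between groups (p >= 0.05 by
#' default) are considered non-distinctive for the disease impact and
#' are dropped during refinement.
#'
#' No continuity correction is applied.  Expected cell counts below 5
#' trigger a warning but no automatic collapsing of categories.  A
#' degenerate table (a single observed response category) leaves the
#' test undefined; the item is flagged for manual review instead of
#' being auto-classified.
#'
#' @param responses Vector of response categories (factor, character or
#'   scores), one per respondent.
#' @param group Group label per respondent (two levels).
#' @param p_threshold Retention threshold, default 0.05.
#' @return An object of class \code{hrqol_chi2}: list with
#'   \code{statistic}, \code{df}, \code{p.value}, \code{retain},
#'   \code{table}, \code{low_expected} and \code{undefined}.
#' @export
chi2_discrimination <- function(responses, group, p_threshold = 0.05) {
  if (length(responses) != length(group))
    stop("responses and group must have equal length", call. = FALSE)
  tab <- table(factor(responses), factor(group))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) != 2L)
    stop("need exactly two groups with observations", call. = FALSE)
  if (nrow(tab) < 2L) {
    return(structure(list(statistic = NA_real_, df = NA_integer_,
                          p.value = NA_real_, retain = NA, table = tab,
                          low_expected = FALSE, undefined = TRUE),
                     class = "hrqol_chi2"))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  low <- any(ht$expected < 5)
  if (low)
    warning("expected cell counts below 5; chi-squared approximation ",
            "may be poor", call. = FALSE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = unname(ht$p.value),
                 retain = unname(ht$p.value) < p_threshold,
                 table = tab, low_expected = low, undefined = FALSE),
            class = "hrqol_chi2")
}

#' @export
print.hrqol_chi2 <- function(x, ...) {
  if (x$undefined) {
    cat("chi-squared discrimination: undefined (single response",
        "category); flagged for manual review\n")
  } else {
    cat(sprintf("chi-squared(%d) = %.3f, p = %.4g -> %s\n", x$df,
                x$statistic, x$p.value,
                if (x$retain) "retain (discriminates groups)"
                else "drop (non-discriminating)"))
  }
  invisible(x)
}

#' Derive domain weights from owner importance ratings
#'
#' Per-domain median of the 1--5 importance ratings, used to weight
#' every item of that domain.  With an even number of raters the
#' midpoint of the two central values is taken and rounded half-up to
#' an integer, so weights remain integer importance levels.
#'
#' @param ratings Data frame or matrix: rows = respondents, columns
#'   named by domain, entries in 1..5.  \code{NA}s are ignored
#'   per-domain.
#' @return [domain_weights()] vector.
#' @export
#' @examples
#' r <- data.frame(demeanour = 5, appearance = 4, condition = 4,
#'                 health = 5, appetite = 5, ingestion = 5,
#'                 management = 5)
#' compute_domain_weights(r)
compute_domain_weights <- function(ratings) {
  ratings <- as.data.frame(ratings)
  doms <- hrqol_domains()
  missing <- setdiff(doms, names(ratings))
  if (length(missing))
    stop("ratings lack domain column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  w <- vapply(doms, function(d) {
    v <- ratings[[d]]
    v <- v[!is.na(v)]
    if (!length(v)) stop("no ratings for domain '", d, "'", call. = FALSE)
    if (any(v < 1 | v > 5 | v != round(v)))
      stop("ratings for '", d, "' must be integers in 1..5", call. = FALSE)
    floor(stats::median(v) + 0.5)  # midpoint for even n, rounded half-up
  }, numeric(1))
  domain_weights(w)
}

#' Stepwise item refinement
#'
#' Reduces an item bank by the three-stage procedure used to develop
#' the PPID HRQoL tool:
#' \enumerate{
#'   \item \strong{Discrimination filter}: every item whose response
#'     distribution does not differ between PPID and non-PPID horses
#'     (chi-squared p >= \code{p_threshold}) is dropped.
#'   \item \strong{Redundancy merge} (PPID rows only): same-domain item
#'     pairs with inter-item Pearson r > \code{r_merge} are combined
#'     into a single item; by default the merged responses are the
#'     element-wise maximum of the pair.
#'   \item \strong{Item-total pruning} (PPID rows only): iteratively,
#'     among items with corrected item-total r < \code{r_prune}, the
#'     one whose removal most increases Cronbach's alpha is removed;
#'     the stage stops when no such removal increases alpha.
#' }
#' All internal-consistency statistics are computed on the raw
#' unweighted scores of the PPID group only.  The final alpha is
#' compared against the adequacy criterion alpha > \code{alpha_adequate}.
#'
#' @param instrument The \code{hrqol_instrument} the items belong to
#'   (supplies item domains).
#' @param scores Numeric matrix of raw item scores, columns named by
#'   item id, rows = respondents, no missing entries.
#' @param group Group label per row; rows where
#'   \code{group == ppid_level} form the PPID group.
#' @param ppid_level Which group value denotes PPID horses
#'   (default \code{"ppid"}; logical \code{group} uses \code{TRUE}).
#' @param p_threshold,r_merge,r_prune,alpha_adequate Stage thresholds
#'   (defaults 0.05, 0.60, 0.30, 0.70).
#' @param merge_method How merged responses are formed:
#'   \code{"max"} (worst-case, default), \code{"mean"} or
#'   \code{"first"}.
#' @param stages Stage order; by default discrimination, merge, prune.
#' @return An object of class \code{refinement_report}: \code{steps}
#'   data frame (stage, action, items, statistics, alpha trajectory),
#'   \code{final_items}, \code{final_alpha}, \code{alpha_adequate},
#'   \code{dispositions} (terminal fate of every input item) and
#'   \code{warnings}.
#' @export
refine_items <- function(instrument, scores, group,
                         ppid_level = "ppid",
                         p_threshold = 0.05, r_merge = 0.60,
                         r_prune = 0.30, alpha_adequate = 0.70,
                         merge_method = c("max", "mean", "first"),
                         stages = c("discrimination", "merge", "prune")) {
  stopifnot(inherits(instrument, "hrqol_instrument"))
  merge_method <- match.arg(merge_method)
  stages <- match.arg(stages, several.ok = TRUE)
  scores <- as_score_matrix(scores)
  if (is.null(colnames(scores)))
    stop("score columns must be named by item id", call. = FALSE)
  unknown <- setdiff(colnames(scores), item_ids(instrument))
  if (length(unknown))
    stop("scores contain items not in the instrument: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  is_ppid <- if (is.logical(group)) group else group == ppid_level
  if (length(is_ppid) != nrow(scores))
    stop("group must have one entry per row of scores", call. = FALSE)
  if (!any(is_ppid) || all(is_ppid))
    stop("both groups must be represented", call. = FALSE)

  domains <- vapply(colnames(scores),
                    function(id) instrument_item(instrument, id)$domain,
                    character(1))
  work <- scores
  warnings <- character(0)
  steps <- list()
  add_step <- function(...) steps[[length(steps) + 1L]] <<- list(...)
  ppid_alpha <- function(m) {
    if (ncol(m) < 2) return(NA_real_)
    cronbach_alpha(m[is_ppid, , drop = FALSE])
  }

  for (stage in stages) {
    if (stage == "discrimination") {
      drop <- character(0)
      for (id in colnames(work)) {
        ch <- suppressWarnings(
          chi2_discrimination(work[, id], is_ppid, p_threshold))
        if (ch$undefined) {
          warnings <- c(warnings, paste0(
            "item ", id, ": degenerate response table, chi-squared ",
            "undefined; retained pending manual review"))
          add_step(stage = "discrimination", action = "manual-review",
                   items = id, statistic = NA_real_, df = NA_real_,
                   p = NA_real_, r = NA_real_,
                   alpha_before = NA_real_, alpha_after = NA_real_)
        } else {
          add_step(stage = "discrimination",
                   action = if (ch$retain) "retain"
                            else "drop-nondiscriminating",
                   items = id, statistic = ch$statistic,
                   df = as.numeric(ch$df), p = ch$p.value, r = NA_real_,
                   alpha_before = NA_real_, alpha_after = NA_real_)
          if (!ch$retain) drop <- c(drop, id)
        }
      }
      work <- work[, setdiff(colnames(work), drop), drop = FALSE]
      domains <- domains[colnames(work)]
    } else if (stage == "merge") {
      repeat {
        if (ncol(work) < 2) break
        cm <- suppressWarnings(
          inter_item_matrix(work[is_ppid, , drop = FALSE]))
        cm[upper.tri(cm, diag = TRUE)] <- NA
        same_dom <- outer(domains, domains, "==")
        cand <- which(!is.na(cm) & cm > r_merge & same_dom,
                      arr.ind = TRUE)
        if (!nrow(cand)) break
        best <- cand[which.max(cm[cand]), , drop = TRUE]
        j1 <- min(best); j2 <- max(best)   # j1 keeps its position
        id1 <- colnames(work)[j1]; id2 <- colnames(work)[j2]
        a0 <- ppid_alpha(work)
        merged <- switch(merge_method,
                         max   = pmax(work[, j1], work[, j2]),
                         mean  = (work[, j1] + work[, j2]) / 2,
                         first = work[, j1])
        work[, j1] <- merged
        dom <- domains[[j1]]
        work <- work[, -j2, drop = FALSE]
        colnames(work)[colnames(work) == id1] <- paste0(id1, "+", id2)
        domains <- vapply(colnames(work), function(id)
          if (id == paste0(id1, "+", id2)) dom else domains[[id]],
          character(1))
        add_step(stage = "merge", action = "merge-redundant",
                 items = paste(id1, id2, sep = "+"),
                 statistic = NA_real_, df = NA_real_, p = NA_real_,
                 r = cm[j2, j1], alpha_before = a0,
                 alpha_after = ppid_alpha(work))
      }
    } else if (stage == "prune") {
      repeat {
        if (ncol(work) <= 2) break
        a0 <- ppid_alpha(work)
        rit <- suppressWarnings(
          item_total_correlations(work[is_ppid, , drop = FALSE]))
        cand <- names(rit)[!is.na(rit) & rit < r_prune]
        if (!length(cand)) break
        gain <- vapply(cand, function(id)
          ppid_alpha(work[, setdiff(colnames(work), id),
                          drop = FALSE]) - a0, numeric(1))
        if (all(gain <= 0)) break
        # best alpha improvement; ties -> lowest item-total r, then order
        top <- cand[gain == max(gain)]
        victim <- top[order(rit[top])][1L]
        add_step(stage = "prune", action = "drop-low-item-total",
                 items = victim, statistic = NA_real_, df = NA_real_,
                 p = NA_real_, r = unname(rit[victim]),
                 alpha_before = a0, alpha_after = a0 + max(gain))
        work <- work[, setdiff(colnames(work), victim), drop = FALSE]
        domains <- domains[colnames(work)]
      }
    }
  }

  if (ncol(work) < 2)
    stop("refinement left fewer than 2 items", call. = FALSE)
  emptied <- setdiff(unique(vapply(colnames(scores), function(id)
    instrument_item(instrument, id)$domain, character(1))),
    unique(domains))
  if (length(emptied))
    warnings <- c(warnings,
                  paste("refinement emptied domain(s):",
                        paste(emptied, collapse = ", ")))

  steps_df <- do.call(rbind, lapply(steps, function(s)
    data.frame(s, stringsAsFactors = FALSE)))
  final_alpha <- ppid_alpha(work)
  structure(list(steps = steps_df,
                 final_items = colnames(work),
                 final_alpha = final_alpha,
                 alpha_criterion = alpha_adequate,
                 alpha_adequate = final_alpha > alpha_adequate,
                 dispositions = item_dispositions(colnames(scores),
                                                  colnames(work), steps_df),
                 warnings = warnings),
            class = "refinement_report")
}

# Terminal fate of every input item: retained / merged / one of the drops.
item_dispositions <- function(input_ids, final_ids, steps) {
  fate <- stats::setNames(rep("retained", length(input_ids)), input_ids)
  if (!is.null(steps) && nrow(steps)) {
    for (i in seq_len(nrow(steps))) {
      act <- steps$action[i]
      if (act == "drop-nondiscriminating" || act == "drop-low-item-total") {
        for (id in intersect(strsplit(steps$items[i], "\\+")[[1]],
                             input_ids))
          fate[id] <- act
      } else if (act == "merge-redundant") {
        for (id in intersect(strsplit(steps$items[i], "\\+")[[1]],
                             input_ids))
          fate[id] <- "merged"
      }
    }
  }
  fate
}

#' @export
print.refinement_report <- function(x, ...) {
  cat("Item refinement report\n")
  s <- x$steps
  n_drop1 <- sum(s$action == "drop-nondiscriminating")
  n_merge <- sum(s$action == "merge-redundant")
  n_prune <- sum(s$action == "drop-low-item-total")
  cat(sprintf(" stage 1: %d item(s) dropped as non-discriminating\n",
              n_drop1))
  for (i in which(s$action == "drop-nondiscriminating"))
    cat(sprintf("   - %s: chi2(%g) = %.3f, p = %.3g\n", s$items[i],
                s$df[i], s$statistic[i], s$p[i]))
  cat(sprintf(" stage 2: %d redundant pair(s) merged\n", n_merge))
  for (i in which(s$action == "merge-redundant"))
    cat(sprintf("   - %s: r = %.3f, alpha %.3f -> %.3f\n", s$items[i],
                s$r[i], s$alpha_before[i], s$alpha_after[i]))
  cat(sprintf(" stage 3: %d item(s) pruned (low item-total r)\n", n_prune))
  for (i in which(s$action == "drop-low-item-total"))
    cat(sprintf("   - %s: r = %.3f, alpha %.3f -> %.3f\n", s$items[i],
                s$r[i], s$alpha_before[i], s$alpha_after[i]))
  cat(sprintf(" final: %d items, Cronbach's alpha = %.3f (%s criterion of > %.2f)\n",
              length(x$final_items), x$final_alpha,
              if (x$alpha_adequate) "meets" else "FAILS", x$alpha_criterion))
  for (w in x$warnings) cat(" note:", w, "\n")
  invisible(x)
}
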