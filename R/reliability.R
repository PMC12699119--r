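#' Intraclass correlation coefficient (two-way, single measures)
#'
#' Rater-agreement ICC from the subjects-by-raters two-way ANOVA mean
#' squares.  With \eqn{n} subjects, \eqn{k} raters, between-subject
#' mean square \eqn{MS_R}, between-rater mean square \eqn{MS_C} and
#' residual mean square \eqn{MS_E}:
#' \deqn{ICC(C,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E}}
#' for the consistency definition, and
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{n}(MS_C - MS_E)}}
#' for absolute agreement, which additionally penalizes systematic
#' rater mean differences.  95\% confidence intervals use the exact-F
#' method.  The qualitative band follows the usual convention:
#' below 0.50 poor, 0.50--0.75 moderate, 0.75--0.90 good, above 0.90
#' excellent.
#'
#' @param ratings Numeric matrix or data frame: rows = subjects
#'   (horses), columns = raters or occasions (>= 2), no missing cells.
#' @param definition \code{"consistency"} (intra-rater style) or
#'   \code{"agreement"} (absolute agreement, inter-rater style).
#' @param conf Confidence level, default 0.95.
#' @return An object of class \code{icc_report}: list with
#'   \code{icc}, \code{definition}, \code{model}, \code{ci}
#'   (length-2 vector), \code{band}, mean squares and dimensions.
#'   Zero between-subject variance yields \code{icc = NA} with band
#'   \code{"undefined"}.
#' @export
#' @examples
#' m <- cbind(r1 = c(7, 5, 8, 4, 6, 9), r2 = c(8, 5, 9, 5, 7, 9))
#' icc(m, "agreement")
icc <- function(ratings, definition = c("consistency", "agreement"),
                conf = 0.95) {
  definition <- match.arg(definition)
  x <- as.matrix(ratings)
  if (!is.numeric(x) || anyNA(x))
    stop("ratings must be numeric with no missing cells", call. = FALSE)
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2)
    stop("need at least 3 subjects and 2 raters", call. = FALSE)

  grand <- mean(x)
  rm_ <- rowMeans(x); cm_ <- colMeans(x)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (ssr <= .Machine$double.eps * sst) {
    return(structure(list(icc = NA_real_, definition = definition,
                          model = "two-way, single measures",
                          ci = c(NA_real_, NA_real_), band = "undefined",
                          msr = msr, msc = msc, mse = mse, n = n, k = k,
                          conf = conf),
                     class = "icc_report"))
  }

  a <- 1 - conf
  if (definition == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse == 0) {
      ci <- c(1, 1)
    } else {
      fobs <- msr / mse
      df1 <- n - 1; df2 <- (n - 1) * (k - 1)
      fl <- fobs / stats::qf(1 - a / 2, df1, df2)
      fu <- fobs * stats::qf(1 - a / 2, df2, df1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    # Satterthwaite df for the rater + error composite (McGraw & Wong)
    aa <- (k * est) / (n * (1 - est))
    bb <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (aa * msc + bb * mse)^2 /
      ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - a / 2, n - 1, v)
    f2 <- stats::qf(1 - a / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lo, hi)
  }
  structure(list(icc = est, definition = definition,
                 model = "two-way, single measures",
                 ci = ci, band = icc_band(est),
                 msr = msr, msc = msc, mse = mse, n = n, k = k,
                 conf = conf),
            class = "icc_report")
}

icc_band <- function(est) {
  if (is.na(est)) "undefined"
  else if (est < 0.50) "poor"
  else if (est < 0.75) "moderate"
  else if (est <= 0.90) "good"
  else "excellent"
}

#' @export
print.icc_report <- function(x, ...) {
  cat(sprintf("ICC (%s, %s): %s\n", x$definition, x$model,
              if (is.na(x$icc)) "undefined (no between-subject variance)"
              else sprintf("%.3f, %d%% CI %.3f-%.3f -> %s reliability",
                           x$icc, round(100 * x$conf), x$ci[1], x$ci[2],
                           x$band)))
  invisible(x)
}

#' Face validity: Spearman correlation with owner global QoL
#'
#' Rank correlation (average ranks for ties, two-sided asymptotic p)
#' between the owner's direct 1 (very good) -- 5 (very poor) overall
#' QoL rating and the computed HRQoL score.  A positive, at least
#' moderate correlation supports face validity of the instrument.
#'
#' @param global_qol Integer vector of owner ratings in 1..5.
#' @param hrqol Numeric vector of HRQoL scores, same length.
#' @return List with \code{rs} and \code{p.value}; \code{NA} with a
#'   warning when either vector is constant.
#' @export
spearman_validity <- function(global_qol, hrqol) {
  if (length(global_qol) != length(hrqol) || length(hrqol) < 3)
    stop("need two equal-length vectors of length >= 3", call. = FALSE)
  if (stats::var(global_qol) == 0 || stats::var(hrqol) == 0) {
    warning("constant input: Spearman correlation undefined",
            call. = FALSE)
    return(list(rs = NA_real_, p.value = NA_real_))
  }
  ht <- suppressWarnings(
    stats::cor.test(global_qol, hrqol, method = "spearman",
                    exact = FALSE))
  list(rs = unname(ht$estimate), p.value = ht$p.value)
}

#' Stuart's tau-c ordinal association between two groups
#'
#' Measures ordinal association between group membership and an
#' ordered rating (e.g. 1--5 domain importance) on the 2 x m
#' contingency table, using Stuart's tau-c, which corrects tau for
#' rectangular tables:
#' \deqn{\tau_c = \frac{m (P - Q)}{n^2 (m - 1)}}
#' where P and Q are twice the numbers of concordant and discordant
#' pairs and m is the smaller table dimension.  The two-sided p-value
#' uses the asymptotic normal approximation under independence.
#'
#' @param a,b Ordinal samples (e.g. ratings from PPID and non-PPID
#'   owners).
#' @return List with \code{tau_c}, \code{statistic} (z), \code{p.value}
#'   and the underlying \code{table}.  If only one rating level is
#'   observed overall, tau-c is 0 with a warning.
#' @export
kendall_tau_c <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  g <- factor(rep(c("A", "B"), c(length(a), length(b))))
  r <- factor(c(a, b))
  tab <- table(g, r)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2) {
    warning("single shared rating category: tau-c = 0", call. = FALSE)
    return(list(tau_c = 0, statistic = NA_real_, p.value = NA_real_,
                table = tab))
  }
  nij <- unclass(tab)
  R <- nrow(nij); C <- ncol(nij); n <- sum(nij)
  m <- min(R, C)
  conc <- disc <- matrix(0, R, C)
  for (i in seq_len(R)) for (j in seq_len(C)) {
    conc[i, j] <- sum(nij[seq_len(R) < i, seq_len(C) < j]) +
      sum(nij[seq_len(R) > i, seq_len(C) > j])
    disc[i, j] <- sum(nij[seq_len(R) < i, seq_len(C) > j]) +
      sum(nij[seq_len(R) > i, seq_len(C) < j])
  }
  P <- sum(nij * conc); Q <- sum(nij * disc)
  tau <- m * (P - Q) / (n^2 * (m - 1))
  s2 <- sum(nij * (conc - disc)^2) - (P - Q)^2 / n
  z <- if (s2 > 0) (P - Q) / (2 * sqrt(s2)) else NA_real_
  list(tau_c = tau, statistic = z,
       p.value = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
       table = tab)
}
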