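# Independent brute-force oracles used to cross-check the package's
# hand-written statistics.

# Cronbach's alpha via the covariance-matrix identity:
# alpha = k/(k-1) * (1 - tr(C) / sum(C)), C the item covariance matrix.
alpha_covariance_oracle <- function(x) {
  C <- cov(as.matrix(x))
  k <- ncol(C)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# Pearson chi-squared statistic from first principles.
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(statistic = sum((tab - expected)^2 / expected),
       df = (nrow(tab) - 1) * (ncol(tab) - 1),
       expected = expected)
}

# Stuart's tau-c by direct O(n^2) pair counting over observations.
tauc_pair_oracle <- function(a, b) {
  x <- rep(c(1, 2), c(length(a), length(b)))   # group as ordinal
  y <- as.numeric(c(a, b))
  n <- length(y)
  cd <- 0
  for (i in seq_len(n - 1)) {
    sx <- sign(x[(i + 1):n] - x[i])
    sy <- sign(y[(i + 1):n] - y[i])
    cd <- cd + sum(sx * sy)
  }
  m <- min(length(unique(x)), length(unique(y)))
  2 * m * cd / (n^2 * (m - 1))
}

# Tiny instrument built in code: two items, known maxima and weights.
toy_instrument <- function(weights = NULL) {
  freq <- list(list(label = "Never", score = 0),
               list(label = "Sometimes", score = 2),
               list(label = "Always", score = 4))
  doc <- list(
    name = "toy",
    items = list(
      list(id = "t1", domain = "health", polarity = "negative",
           text = "toy item one", options = freq),
      list(id = "t2", domain = "appetite", polarity = "negative",
           text = "toy item two",
           options = list(list(label = "No", score = 0),
                          list(label = "Yes", score = 3)))),
    weights = as.list(stats::setNames(rep(1L, 7), hrqol_domains())))
  if (!is.null(weights)) doc$weights <- as.list(weights)
  ppidqol:::parse_instrument(doc, source = "<toy>")
}

# Expected terminal dispositions of the planted 10-item bank.
planted_recovered <- function(report) {
  d <- report$dispositions
  all(d[c("p08", "p09", "p10")] %in%
        c("drop-nondiscriminating", "drop-low-item-total")) &&
    all(d[c("p01", "p07")] == "merged") &&
    all(d[paste0("p0", 2:6)] == "retained") &&
    sum(report$steps$action == "merge-redundant") == 1
}
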