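#' Read and write cohort response tables
#'
#' Cohorts are interchanged as headered, comma-separated UTF-8 text:
#' one row per horse, columns for covariates and one column per item id
#' holding the response label.  \code{read_cohort(write_cohort(x))}
#' restores the table.
#'
#' @param cohort Data frame (e.g. from [simulate_cohort()]).
#' @param path File path.
#' @return \code{read_cohort}: the data frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = "")
}

#' Write an instrument definition back to YAML
#'
#' Inverse of [load_instrument()]: \code{load_instrument} on the
#' written file reproduces the instrument.
#'
#' @param instrument An \code{hrqol_instrument}.
#' @param path Output YAML path.
#' @export
write_instrument <- function(instrument, path) {
  stopifnot(inherits(instrument, "hrqol_instrument"))
  doc <- list(
    schema = "hrqol-instrument/1",
    name = instrument$name,
    weights = as.list(instrument$weights),
    items = lapply(unname(instrument$items), function(it) {
      reg <- it$options[it$options$kind == "regular", , drop = FALSE]
      sp <- it$options[it$options$kind != "regular", , drop = FALSE]
      out <- list(id = it$id, domain = it$domain,
                  polarity = it$polarity, text = it$text,
                  options = lapply(seq_len(nrow(reg)), function(i)
                    list(label = reg$label[i], score = reg$score[i])))
      if (nrow(sp))
        out$special <- lapply(seq_len(nrow(sp)), function(i)
          list(label = sp$label[i], score = sp$score[i],
               kind = sp$kind[i]))
      out
    }))
  if (!is.null(instrument$alt_weights))
    doc$alt_weights <- lapply(instrument$alt_weights, as.list)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read and write wide rater tables
#'
#' Wide comma-separated layout: a subject id column followed by one
#' numeric column per rater or occasion.
#'
#' @param ratings Numeric matrix (rows = subjects).
#' @param path File path.
#' @param id Subject ids; defaults to row numbers.
#' @return \code{read_ratings}: numeric matrix with subject ids as row
#'   names.
#' @export
write_ratings <- function(ratings, path, id = NULL) {
  m <- as.matrix(ratings)
  d <- data.frame(subject = id %||% sprintf("s%03d", seq_len(nrow(m))),
                  m, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings
#' @export
read_ratings <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- d[[1]]
  m
}

#' Serialize a refinement report
#'
#' Writes the step ledger and dispositions as YAML, and the
#' human-readable narrative (the printed report) alongside as
#' \code{.log}.
#'
#' @param report A \code{refinement_report}.
#' @param path Output YAML path; the log goes to \code{path.log}.
#' @export
write_refinement_report <- function(report, path) {
  stopifnot(inherits(report, "refinement_report"))
  doc <- list(final_items = report$final_items,
              final_alpha = report$final_alpha,
              alpha_criterion = report$alpha_criterion,
              alpha_adequate = report$alpha_adequate,
              dispositions = as.list(report$dispositions),
              warnings = report$warnings,
              steps = lapply(seq_len(nrow(report$steps)), function(i)
                as.list(report$steps[i, ])))
  yaml::write_yaml(doc, path)
  writeLines(utils::capture.output(print(report)),
             paste0(path, ".log"))
  invisible(path)
}
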