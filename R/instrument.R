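#' @keywords internal
"_PACKAGE"

#' Domains of the PPID HRQoL instrument
#'
#' The instrument groups items into seven construct domains covering the
#' behavioural, physical and management impacts of pituitary pars
#' intermedia dysfunction (PPID) on a horse's quality of life.
#'
#' @return Character vector of the seven domain names.
#' @export
#' @examples
#' hrqol_domains()
hrqol_domains <- function() {
  c("demeanour", "appearance", "condition", "health",
    "appetite", "ingestion", "management")
}

#' Load an HRQoL instrument definition
#'
#' Reads an instrument (item bank, ordered response options with numeric
#' scores, and domain importance weights) from a YAML definition.  Two
#' instruments ship with the package: \code{"ppid-final-24"}, the final
#' 24-item tool, and \code{"ppid-survey-37"}, the 37-item bank fielded in
#' the owner survey before statistical refinement.
#'
#' Scores encode direction: the most favourable answer of every item
#' scores 0 and the least favourable scores the item maximum (3 or 4 in
#' the packaged instruments), so positively phrased items carry reversed
#' option scores.  "I have not been able to observe this" is scored at
#' the item midpoint (1.5 on a 0--3 item) so that unobservable items
#' neither raise nor lower the final score.
#'
#' @param source Name of a packaged instrument (\code{"ppid-final-24"},
#'   \code{"ppid-survey-37"}, or \code{"planted-bank-10"} for the
#'   synthetic refinement test bank of [planted_bank()]) or path to a
#'   YAML file with the same schema.
#' @return An object of class \code{hrqol_instrument}: a list with
#'   elements \code{name}, \code{items} (named list of
#'   \code{hrqol_item}), \code{weights} (named integer vector over the
#'   seven domains) and, when present in the file, \code{alt_weights}.
#' @seealso [score_response()], [max_weighted_score()], [score_item()]
#' @export
#' @examples
#' instr <- load_instrument("ppid-final-24")
#' instr
load_instrument <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (source == "planted-bank-10") return(planted_bank())
  packaged <- c("ppid-final-24"  = "instrument-ppid-final-24.yaml",
                "ppid-survey-37" = "instrument-ppid-survey-37.yaml")
  path <- if (source %in% names(packaged)) {
    system.file("extdata", packaged[[source]], package = "ppidqol",
                mustWork = TRUE)
  } else {
    if (!file.exists(source))
      stop("no packaged instrument or file named '", source, "'",
           call. = FALSE)
    source
  }
  doc <- yaml::read_yaml(path)
  parse_instrument(doc, source = path)
}

parse_instrument <- function(doc, source = "<document>") {
  if (is.null(doc$items) || is.null(doc$weights))
    stop("malformed instrument document '", source,
         "': needs 'items' and 'weights'", call. = FALSE)
  items <- lapply(doc$items, parse_item)
  ids <- vapply(items, function(it) it$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate item ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  names(items) <- ids
  weights <- domain_weights(unlist(doc$weights))
  missing_w <- setdiff(unique(vapply(items, `[[`, character(1), "domain")),
                       names(weights))
  if (length(missing_w))
    stop("missing domain weight for: ", paste(missing_w, collapse = ", "),
         call. = FALSE)
  out <- structure(
    list(name = doc$name %||% "unnamed", items = items, weights = weights),
    class = "hrqol_instrument")
  if (!is.null(doc$alt_weights))
    out$alt_weights <- lapply(doc$alt_weights,
                              function(w) domain_weights(unlist(w)))
  out
}

parse_item <- function(x) {
  for (f in c("id", "domain", "text", "options"))
    if (is.null(x[[f]]))
      stop("item ", x$id %||% "<no id>", ": missing field '", f, "'",
           call. = FALSE)
  opts <- do.call(rbind, lapply(x$options, function(o) {
    if (is.null(o$label) || is.null(o$score))
      stop("item ", x$id, ": option without label or score", call. = FALSE)
    data.frame(label = as.character(o$label), score = as.numeric(o$score),
               kind = "regular", stringsAsFactors = FALSE)
  }))
  if (!is.null(x$special)) {
    sp <- do.call(rbind, lapply(x$special, function(o) {
      if (is.null(o$label) || is.null(o$score))
        stop("item ", x$id, ": special option without label or score",
             call. = FALSE)
      data.frame(label = as.character(o$label), score = as.numeric(o$score),
                 kind = o$kind %||% "special", stringsAsFactors = FALSE)
    }))
    opts <- rbind(opts, sp)
  }
  it <- structure(
    list(id = as.character(x$id), domain = as.character(x$domain),
         text = as.character(x$text),
         polarity = x$polarity %||% "negative", options = opts),
    class = "hrqol_item")
  validate_item(it)
  it
}

validate_item <- function(it) {
  if (!it$domain %in% hrqol_domains())
    stop("item ", it$id, ": unknown domain '", it$domain, "'", call. = FALSE)
  reg <- it$options[it$options$kind == "regular", ]
  if (nrow(reg) < 2L)
    stop("item ", it$id, ": needs at least 2 regular options", call. = FALSE)
  if (anyDuplicated(it$options$label))
    stop("item ", it$id, ": duplicate option labels", call. = FALSE)
  if (any(it$options$score < 0) || any(!is.finite(it$options$score)))
    stop("item ", it$id, ": option scores must be finite and non-negative",
         call. = FALSE)
  if (min(reg$score) != 0)
    stop("item ", it$id, ": most favourable option must score 0",
         call. = FALSE)
  unobs <- it$options[it$options$kind == "unobservable", ]
  if (nrow(unobs)) {
    mid <- (min(reg$score) + max(reg$score)) / 2
    if (any(unobs$score != mid))
      stop("item ", it$id, ": unobservable option must score the item ",
           "midpoint ", mid, call. = FALSE)
  }
  invisible(it)
}

#' Domain importance weights
#'
#' Validates a named vector of per-domain importance weights (median
#' owner ratings on the 1 = "not important at all" to 5 = "very
#' important" scale).  All seven domains must be present.
#'
#' @param x Named numeric vector, names in [hrqol_domains()], values
#'   integers in 1..5.
#' @return Named integer vector of class-checked weights.
#' @seealso [compute_domain_weights()] to derive weights from owner
#'   importance ratings.
#' @export
#' @examples
#' domain_weights(c(demeanour = 5, appearance = 4, condition = 4,
#'                  health = 5, appetite = 5, ingestion = 5,
#'                  management = 5))
domain_weights <- function(x) {
  doms <- hrqol_domains()
  if (is.null(names(x)) || !setequal(names(x), doms))
    stop("weights must name all seven domains: ",
         paste(setdiff(doms, names(x)), collapse = ", "), call. = FALSE)
  x <- x[doms]
  if (any(x != round(x)) || any(x < 1) || any(x > 5))
    stop("weights must be integers in 1..5", call. = FALSE)
  storage.mode(x) <- "integer"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hrqol_instrument <- function(x, ...) {
  doms <- table(factor(vapply(x$items, `[[`, character(1), "domain"),
                       levels = hrqol_domains()))
  cat("HRQoL instrument '", x$name, "': ", length(x$items),
      " items in ", sum(doms > 0), " domains\n", sep = "")
  for (d in names(doms)[doms > 0])
    cat(sprintf("  %-11s %d item%s (weight %d)\n", d, doms[[d]],
                if (doms[[d]] > 1) "s" else "", x$weights[[d]]))
  invisible(x)
}

#' @export
print.hrqol_item <- function(x, ...) {
  cat("[", x$id, "] (", x$domain, ", ", x$polarity, ")\n  ",
      x$text, "\n", sep = "")
  apply(x$options, 1, function(o)
    cat("   - ", o[["label"]], " (", o[["score"]], ")\n", sep = ""))
  invisible(x)
}

#' Retrieve a single item from an instrument
#'
#' @param instrument An \code{hrqol_instrument}.
#' @param id Item id, e.g. \code{"item14"}.
#' @return The \code{hrqol_item}.
#' @export
instrument_item <- function(instrument, id) {
  stopifnot(inherits(instrument, "hrqol_instrument"))
  it <- instrument$items[[id]]
  if (is.null(it))
    stop("instrument '", instrument$name, "' has no item '", id, "'",
         call. = FALSE)
  it
}

#' Item ids of an instrument
#' @param instrument An \code{hrqol_instrument}.
#' @return Character vector of item ids in instrument order.
#' @export
item_ids <- function(instrument) {
  stopifnot(inherits(instrument, "hrqol_instrument"))
  names(instrument$items)
}

#' Score a single item response
#'
#' Maps a response label to its configured numeric score, e.g.
#' "All the time" on a negatively phrased frequency item scores 3 and
#' "I have not been able to observe this" scores the item midpoint.
#'
#' @param item An \code{hrqol_item} (see [instrument_item()]).
#' @param label A response label, matched case-insensitively.
#' @return The numeric score of the option.
#' @export
#' @examples
#' instr <- load_instrument("ppid-final-24")
#' score_item(instrument_item(instr, "item01"), "All the time")  # 3
#' score_item(instrument_item(instr, "item14"),
#'            "I have not been able to observe this")            # 1.5
score_item <- function(item, label) {
  stopifnot(inherits(item, "hrqol_item"))
  i <- match(tolower(trimws(label)), tolower(item$options$label))
  if (is.na(i))
    stop("item ", item$id, ": unknown response label '", label, "'",
         call. = FALSE)
  item$options$score[i]
}

item_max_score <- function(item) {
  max(item$options$score[item$options$kind == "regular"])
}

#' Total maximum weighted score of an instrument
#'
#' The denominator of the normalized HRQoL score: the sum over items of
#' the item's maximum option score multiplied by its domain weight.  For
#' the packaged final 24-item tool with the default PPID-owner weights
#' this is 383.
#'
#' @param instrument An \code{hrqol_instrument}.
#' @param weights Optional alternative [domain_weights()]; defaults to
#'   the instrument's packaged weights.
#' @return A single number.
#' @export
#' @examples
#' max_weighted_score(load_instrument("ppid-final-24"))  # 383
max_weighted_score <- function(instrument, weights = NULL) {
  stopifnot(inherits(instrument, "hrqol_instrument"))
  w <- if (is.null(weights)) instrument$weights else domain_weights(weights)
  sum(vapply(instrument$items, function(it)
    item_max_score(it) * w[[it$domain]], numeric(1)))
}

#' Score a complete response record
#'
#' Computes the normalized HRQoL score for one horse:
#' \deqn{HRQoL = \frac{\sum_i w_{d(i)} s_i}{\sum_i w_{d(i)} \max_i}}
#' where \eqn{s_i} is the option score of the answer to item \eqn{i} and
#' \eqn{w_{d(i)}} the importance weight of its domain.  The score runs
#' from 0 (best possible quality of life) to 1 (worst possible).
#'
#' Records that leave any instrument item unanswered are refused, the
#' behaviour used when the instrument was developed (incomplete survey
#' responses were excluded).  Setting \code{impute_midpoint = TRUE}
#' substitutes the item midpoint for missing answers instead; this is an
#' extension, not part of the validated scoring rule.
#'
#' @param instrument An \code{hrqol_instrument}.
#' @param answers Named character vector or list mapping item id to
#'   response label.  Extra names (covariates etc.) are ignored.
#' @param weights Optional alternative [domain_weights()].
#' @param impute_midpoint If \code{TRUE}, score missing answers at the
#'   item midpoint instead of refusing the record.
#' @return An object of class \code{hrqol_score}: list with
#'   \code{item_scores}, \code{weighted_scores}, \code{total_max} and
#'   \code{hrqol}.
#' @export
#' @examples
#' instr <- load_instrument("ppid-final-24")
#' best <- best_response(instr)
#' score_response(instr, best)$hrqol  # 0
score_response <- function(instrument, answers, weights = NULL,
                           impute_midpoint = FALSE) {
  stopifnot(inherits(instrument, "hrqol_instrument"))
  answers <- unlist(answers)
  w <- if (is.null(weights)) instrument$weights else domain_weights(weights)
  ids <- item_ids(instrument)
  missing <- ids[!ids %in% names(answers) | is.na(answers[ids])]
  if (length(missing) && !impute_midpoint)
    stop("incomplete record, unanswered items: ",
         paste(missing, collapse = ", "), call. = FALSE)
  s <- vapply(ids, function(id) {
    it <- instrument$items[[id]]
    if (id %in% missing) {
      reg <- it$options$score[it$options$kind == "regular"]
      (min(reg) + max(reg)) / 2
    } else {
      score_item(it, answers[[id]])
    }
  }, numeric(1))
  wts <- vapply(ids, function(id) w[[instrument$items[[id]]$domain]],
                numeric(1))
  total_max <- max_weighted_score(instrument, weights = w)
  structure(list(item_scores = s, weighted_scores = wts * s,
                 total_max = total_max,
                 hrqol = sum(wts * s) / total_max,
                 imputed = missing),
            class = "hrqol_score")
}

#' @export
print.hrqol_score <- function(x, ...) {
  cat(sprintf("HRQoL score: %.4f  (weighted sum %.1f / max %.1f)\n",
              x$hrqol, sum(x$weighted_scores), x$total_max))
  if (length(x$imputed))
    cat("  midpoint-imputed items:", paste(x$imputed, collapse = ", "), "\n")
  invisible(x)
}

#' Score every row of a response table
#'
#' @param instrument An \code{hrqol_instrument}.
#' @param data Data frame with one column per item id (response labels)
#'   plus any covariate columns, one row per horse.
#' @param weights,impute_midpoint Passed to [score_response()].
#' @return \code{data} with an appended numeric \code{hrqol} column.
#' @export
score_cohort <- function(instrument, data, weights = NULL,
                         impute_midpoint = FALSE) {
  stopifnot(is.data.frame(data))
  ids <- item_ids(instrument)
  absent <- setdiff(ids, names(data))
  if (length(absent))
    stop("response table lacks item columns: ",
         paste(absent, collapse = ", "), call. = FALSE)
  data$hrqol <- vapply(seq_len(nrow(data)), function(i) {
    ans <- lapply(data[i, ids, drop = FALSE], as.character)
    score_response(instrument, ans, weights = weights,
                   impute_midpoint = impute_midpoint)$hrqol
  }, numeric(1))
  data
}

#' Reference response records
#'
#' \code{best_response()} answers every item with its most favourable
#' (score 0) option; \code{worst_response()} with its least favourable
#' (maximum score) option.  Useful as scoring anchors: they score
#' exactly 0 and 1.
#'
#' @param instrument An \code{hrqol_instrument}.
#' @return Named character vector of response labels.
#' @export
#' @examples
#' instr <- load_instrument("ppid-final-24")
#' score_response(instr, worst_response(instr))$hrqol  # 1
best_response <- function(instrument) {
  extreme_response(instrument, which.min)
}

#' @rdname best_response
#' @export
worst_response <- function(instrument) {
  extreme_response(instrument, which.max)
}

extreme_response <- function(instrument, pick) {
  stopifnot(inherits(instrument, "hrqol_instrument"))
  vapply(instrument$items, function(it) {
    reg <- it$options[it$options$kind == "regular", ]
    reg$label[pick(reg$score)]
  }, character(1))
}
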