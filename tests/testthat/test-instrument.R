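final24 <- load_instrument("ppid-final-24")
survey37 <- load_instrument("ppid-survey-37")

test_that("packaged instruments have the documented structure", {
  expect_length(final24$items, 24)
  expect_length(survey37$items, 37)
  doms <- vapply(final24$items, `[[`, character(1), "domain")
  expect_setequal(unique(doms), hrqol_domains())
  expect_identical(unname(final24$weights[hrqol_domains()]),
                   c(5L, 4L, 4L, 5L, 5L, 5L, 5L))
  # every final item's maximum is 3 or 4
  maxima <- vapply(final24$items, ppidqol:::item_max_score, numeric(1))
  expect_true(all(maxima %in% c(3, 4)))
  # survey bank covers the same seven domains
  expect_setequal(unique(vapply(survey37$items, `[[`, character(1),
                                "domain")), hrqol_domains())
})

test_that("single item responses score as configured", {
  expect_equal(score_item(instrument_item(final24, "item01"),
                          "All the time"), 3)
  expect_equal(score_item(instrument_item(final24, "item01"),
                          "all the time"), 3)   # case-insensitive
  expect_equal(score_item(instrument_item(final24, "item14"),
                          "I have not been able to observe this"), 1.5)
  # positively phrased item is reverse-scored
  expect_equal(score_item(instrument_item(final24, "item13"),
                          "All the time"), 0)
  expect_equal(score_item(instrument_item(final24, "item17"),
                          "My horse does not receive any meds/suppl."), 0)
  expect_error(score_item(instrument_item(final24, "item01"), "sort of"),
               "item01.*sort of")
  expect_error(instrument_item(final24, "item99"), "item99")
})

test_that("instrument validation names the offending construct", {
  base <- yaml::read_yaml(system.file("extdata",
                                      "instrument-ppid-final-24.yaml",
                                      package = "ppidqol"))
  bad <- base
  bad$weights$health <- NULL
  expect_error(ppidqol:::parse_instrument(bad), "health")
  bad <- base
  bad$items[[2]]$id <- "item01"
  expect_error(ppidqol:::parse_instrument(bad), "duplicate")
  bad <- base
  bad$items[[1]]$options[[1]]$score <- NULL
  expect_error(ppidqol:::parse_instrument(bad), "item01")
  # unobservable option must sit at the item midpoint
  bad <- base
  bad$items[[14]]$special[[1]]$score <- 2
  expect_error(ppidqol:::parse_instrument(bad), "midpoint")
  expect_error(load_instrument("no-such-instrument"), "no-such-instrument")
})

test_that("maximum weighted score sums item maxima times domain weights", {
  expect_equal(max_weighted_score(final24), 383)
  ones <- stats::setNames(rep(1, 7), hrqol_domains())
  expect_equal(max_weighted_score(final24, weights = ones), 82)
  # single-item toy: max 4 x weight 5
  toy <- toy_instrument()
  toy$items$t2 <- NULL
  fives <- stats::setNames(rep(5, 7), hrqol_domains())
  expect_equal(max_weighted_score(toy, weights = fives), 20)
})

test_that("scoring anchors and hand-computed records", {
  expect_equal(score_response(final24, best_response(final24))$hrqol, 0)
  expect_equal(score_response(final24, worst_response(final24))$hrqol, 1)
  ans <- best_response(final24)
  ans["item01"] <- "All the time"   # worst demeanour only: 3 x 5 / 383
  expect_equal(score_response(final24, ans)$hrqol, 15 / 383)
})

test_that("incomplete records are refused unless midpoint imputation is chosen", {
  ans <- best_response(final24)
  ans <- ans[setdiff(names(ans), c("item03", "item20"))]
  expect_error(score_response(final24, ans), "item03.*item20")
  sc <- score_response(final24, ans, impute_midpoint = TRUE)
  expect_setequal(sc$imputed, c("item03", "item20"))
  expect_equal(sc$hrqol, (1.5 * 4 + 2 * 5) / 383)
})

test_that("hrqol is bounded, monotone and permutation invariant", {
  set.seed(42)
  for (rep in 1:25) {
    ans <- vapply(final24$items, function(it) {
      sample(it$options$label, 1)
    }, character(1))
    h <- score_response(final24, ans)$hrqol
    expect_gte(h, 0); expect_lte(h, 1)

    # worsening exactly one answer strictly increases the score
    id <- sample(item_ids(final24), 1)
    it <- final24$items[[id]]
    cur <- score_item(it, ans[[id]])
    worse <- it$options[it$options$score > cur, , drop = FALSE]
    if (nrow(worse)) {
      ans2 <- ans
      ans2[[id]] <- worse$label[sample.int(nrow(worse), 1)]
      expect_gt(score_response(final24, ans2)$hrqol, h)
    }

    # shuffling record and instrument item order changes nothing
    shuf <- final24
    shuf$items <- shuf$items[sample(seq_along(shuf$items))]
    expect_equal(score_response(shuf, ans[sample(names(ans))])$hrqol, h)
  }
})

test_that("common rescaling of all weights leaves hrqol unchanged", {
  set.seed(7)
  ans <- vapply(final24$items, function(it)
    sample(it$options$label, 1), character(1))
  w1 <- stats::setNames(rep(2, 7), hrqol_domains())
  w2 <- 2 * w1
  expect_equal(score_response(final24, ans, weights = w1)$hrqol,
               score_response(final24, ans, weights = w2)$hrqol)
})

test_that("score_cohort appends hrqol per row and checks columns", {
  tab <- as.data.frame(rbind(best_response(final24),
                             worst_response(final24)),
                       stringsAsFactors = FALSE)
  out <- score_cohort(final24, tab)
  expect_equal(out$hrqol, c(0, 1))
  expect_error(score_cohort(final24, tab[, -3]), "item")
})

test_that("domain weights are validated", {
  expect_error(domain_weights(c(demeanour = 5)), "management")
  w <- stats::setNames(rep(5, 7), hrqol_domains())
  expect_error(domain_weights(replace(w, 1, 6)), "1..5")
  expect_error(domain_weights(replace(w, 1, 2.5)), "1..5")
})
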