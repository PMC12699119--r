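Package: ppidqol
Title: Scoring and Psychometric Development of an Equine PPID
    Quality-of-Life Instrument
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements an owner-reported health-related quality-of-life
    (HRQoL) instrument for horses with pituitary pars intermedia
    dysfunction (PPID): item scoring on ordered Likert responses,
    domain-importance weighting and a normalized 0 (best) to 1 (worst)
    score.  Also provides the psychometric development pipeline used to
    refine such instruments (chi-squared item discrimination between
    diseased and control groups, redundancy merging and corrected
    item-total pruning guided by Cronbach's alpha), reliability and
    validity statistics (two-way single-measure intraclass correlation,
    Spearman face validity, Stuart's tau-c), a Type III general linear
    model stage for factors associated with HRQoL scores, and a
    latent-severity graded-response simulator that generates owner
    cohorts and rater pairs with the structure the analyses assume.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
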