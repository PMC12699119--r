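---
title: "Methods: the PPID HRQoL instrument, its development pipeline and the cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the PPID HRQoL instrument, its development pipeline and the cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppidqol)
```

## The instrument and its score

The instrument is an owner-completed questionnaire about a horse with
(or without) pituitary pars intermedia dysfunction (PPID).  Each item
is an ordered Likert question with a fixed numeric score per option:
0 for the most favourable answer, rising to the item maximum (3 on
frequency and coat-extent scales, 4 on five-point agreement scales)
for the least favourable.  Positively phrased items ("My horse looks
healthy") carry reversed option scores, so the direction of every
score is the same: higher is worse.  Where offered, "I have not been
able to observe this" scores the midpoint of the item's range (1.5 on
a 0–3 item) so that an unobservable behaviour neither inflates nor
deflates the total; the loader enforces this midpoint invariant.

Items belong to one of seven domains — demeanour, appearance,
condition, health, appetite, ingestion, management — and every item is
weighted by its domain's importance weight, an integer 1–5 derived as
the median importance rating given by owners of PPID horses.  The
normalized score of a complete record is the weighted item-score sum
divided by the weighted maximum, giving a 0 (best) to 1 (worst) scale.
For the packaged 24-item tool and default weights the denominator is
383, and the two extreme response records score exactly 0 and 1.

```{r}
instr <- load_instrument("ppid-final-24")
max_weighted_score(instr)
score_response(instr, worst_response(instr))$hrqol
```

Scoring decisions worth making explicit:

* **Incomplete records are refused**, not imputed, matching how the
  instrument was developed (incomplete survey responses were excluded
  from analysis).  `score_response(..., impute_midpoint = TRUE)` is an
  explicitly labelled extension that substitutes the item midpoint.
* The ingestion item's "my horse does not receive any meds/suppl."
  option has no published score; the package scores it 0, reasoning
  that no medication burden means no negative QoL impact, consistent
  with the adjacent "never (0)" anchor.  The value is configurable in
  the instrument YAML.
* The published final-item table numbers its nineteenth item "29", an
  apparent typo; the packaged fixture renumbers sequentially
  item01–item24.
* Default weights are the PPID-owner medians and are applied to all
  horses, including controls; a non-PPID-owner weight set ships as
  `alt_weights` and any [domain_weights()] vector can be passed.
* Scores are plain doubles.  Every option score is a multiple of 0.5,
  so sums and the rational score are exact in binary floating point;
  reported values are conventionally rounded to 4 decimals for
  display only.

The 37-item survey bank (`"ppid-survey-37"`) is packaged alongside the
final tool.  Its bookkeeping deserves a note: the published refinement
narrative lists 7 chi-squared removals, 5 item-total prunings and two
wording merges starting from 37 items, which arithmetically yields 23,
yet the final tool has 24 items.  The packaged bank resolves this by
carrying the two demeanour merge ancestors as separate survey items
while treating the ingestion combination as a wording revision of a
single survey item (it was a research-team judgement, not a
correlation-driven merge), so that 37 − 7 − 5 − 1 = 24 exactly.  The
discrepancy is documented rather than hidden.

## The refinement pipeline

`refine_items()` reduces an item bank in three stages, in the order
the development narrative describes; the order is configurable via the
`stages` argument because the original description does not state
whether merging preceded pruning.

1. **Discrimination filter.**  Each item's response categories are
   cross-tabulated against group (PPID vs. non-PPID) and tested with
   Pearson's chi-squared (no continuity correction).  Items with
   p ≥ 0.05 are dropped: an item that does not separate the groups is
   not informative about the disease's QoL impact.  Expected counts
   below 5 warn but do not trigger category collapsing; a degenerate
   single-category table leaves the item flagged for manual review
   rather than auto-classified.
2. **Redundancy merge** (PPID rows only).  Same-domain pairs with
   inter-item Pearson r > 0.60 are considered to record the same
   information.  The original process merged question *wordings* and
   describes no score arithmetic; as a deterministic default the
   package takes the element-wise maximum of the two response columns
   (a worst-case reading), with `"mean"` and `"first"` selectable.
   When several pairs qualify, the highest-correlation pair merges
   first and the matrix is re-examined.
3. **Item-total pruning** (PPID rows only).  Among items with
   corrected item-total correlation r < 0.30, the one whose removal
   most increases Cronbach's alpha is removed, iterating until no such
   removal helps.  Ties on the alpha gain are broken by the lower
   item-total correlation, then by item order, making the procedure
   fully deterministic.  By construction alpha never decreases along
   the pruning trajectory.

All internal-consistency statistics (alpha, item-total and inter-item
correlations) are computed on raw unweighted scores of the PPID group
only, because the construct being tightened is the QoL impact of PPID.
The final alpha is compared against the adequacy criterion α > 0.70.
Thresholds (0.05, 0.60, 0.30, 0.70) are configuration defaults, not
hard-coded.  The report records every action with its justifying
statistic and the alpha trajectory, and assigns every input item
exactly one terminal disposition.

Median weights from owner ratings (`compute_domain_weights()`) use the
midpoint of the two central values for even n, rounded half-up to keep
weights on the integer 1–5 importance scale.

## Reliability and validity statistics

`icc()` implements the two-way, single-measure intraclass correlations
from the subjects × raters ANOVA decomposition: the *consistency*
form (MS_R − MS_E)/(MS_R + (k−1)MS_E), which ignores systematic rater
offsets, and the *absolute agreement* form, which penalizes them
through the rater mean square.  The two-way model was chosen because
it makes the consistency/absolute distinction meaningful — the two
published reliability analyses are named by exactly these definitions.
Confidence intervals use the exact-F method (with a Satterthwaite
denominator df for the agreement form).  Qualitative bands follow the
published convention: < 0.50 poor, 0.50–0.75 moderate, 0.75–0.90 good,
> 0.90 excellent.  A ratings matrix with zero between-subject variance
has no defined ICC and is reported as such.

`spearman_validity()` is the face-validity check: the rank correlation
between the owner's direct 1 (very good) – 5 (very poor) global QoL
rating and the computed score.  `kendall_tau_c()` implements Stuart's
tau-c on the 2 × m group-by-rating table — appropriate for rectangular
tables where tau-b saturates below 1 — with the asymptotic normal
p-value from the concordance-count variance under independence.  Both
hand-written statistics are cross-checked in the test suite against
independent brute-force pair counting and against values frozen from
an independent reference implementation.

## The association stage

`fit_hrqol_glm()` models the square-root of the HRQoL score (the
bounded score is right-skewed in realistic cohorts; the square root
stabilises it) as a linear model with Type III sums of squares,
computed with sum-to-zero contrasts via `car::Anova`.  Two presets
mirror the published analyses: `"all-horses"` (fixed: PPID, other
chronic conditions; categorical: breed, sex, body condition;
covariate: age) and `"ppid-only"` (fixed: treatment, chronic;
covariates: age and years since diagnosis).  Only factor × covariate
two-way interactions enter, never covariate × covariate or factor ×
factor, to limit the multiplicity of tests.

Modelling decisions:

* Breed, sex and body condition are fitted as **fixed categorical
  effects** and all terms are tested against the residual mean square.
  The original software's expected-mean-squares quasi-F denominators
  are deliberately not replicated: the published F statistics carry
  residual-style denominator degrees of freedom, and the
  fixed-effects reading reproduces that structure.
* **Covariates are centred** before fitting.  With a factor ×
  covariate interaction present, the Type III main-effect hypothesis
  for the factor refers to the covariate value zero; centring makes it
  refer to the covariate mean (a horse of average age) instead of an
  extrapolated age-zero animal.
* Rows with missing model variables are dropped listwise and counted.
  Factor levels with fewer observations than their interaction columns
  (1 + number of covariates) are inestimable — a single stallion
  cannot support a sex × age interaction — and their rows are excluded
  and reported rather than letting the design go singular.  Remaining
  exact aliasing raises an error naming the aliased coefficients.
* Diagnostics: Shapiro–Wilk on residuals (for 3 ≤ n ≤ 5000), and a
  Breusch–Pagan-style flag from regressing squared residuals on
  fitted values — a numeric stand-in for the visual
  residual-vs-predicted assessment, which has no published numeric
  criterion.

## The cohort simulator

No response-level data are deposited with the instrument, so the
package ships a generator whose defaults encode the documented study
conditions and whose structure matches what the analyses assume.

Each horse receives a latent severity
θ = β_ppid·PPID + β_chronic·chronic + β_age·(age − 22.4) + ε,
ε ~ N(0, 1).  Item responses follow a proportional-odds
(graded-response) link: the item latent is a·θ plus standard logistic
noise, cut at equally spaced thresholds — chosen over direct
multinomial sampling because it guarantees, by construction, that
raising θ shifts every item's response distribution toward
worse-scored options.  The owner's global QoL rating comes from the
same latent through its own proportional-odds model, which is what
makes the face-validity correlation moderate rather than perfect.
"I have not been able to observe this" is emitted with a small fixed
probability (3%) independent of θ: unobservability is a property of
housing and turnout, not of disease severity.

Fixed-once defaults and their sources:

* Group sizes 343/269 and age models 24.34 ± 6.60 vs. 19.84 ± 5.16
  years: the documented cohort profile.
* Covariate category frequencies (breed, sex, body condition, chronic
  prevalence, treatment uptake) follow the published population
  profile table; years since diagnosis is log-normal with median 2 and
  σ_log matched to the published 1–6 interquartile range (the three
  quantiles cannot all be matched exactly; the median is matched and
  the IQR ratio sets the spread).
* Effect sizes and thresholds (β_ppid = 0.65, thresholds 0.40 +
  1.27·j, item discrimination 1.2) were calibrated once so that scored
  group medians land near 0.33 (PPID) and 0.20 (non-PPID) — the
  separation the real instrument resolves — and the global-QoL
  marginals sit near the reported 52/42/6 split.  This is emulation of
  scale, not reproduction of data-dependent results.
* The rater model shares the subject's true score between raters and
  adds a per-rater systematic offset (hurting absolute agreement but
  not consistency) plus independent occasion noise.

`planted_bank()` and `planted_params()` define a 10-item bank with
known ground truth for exercising the refinement pipeline: six
ordinary severity-loaded items, a redundant twin of the first item in
the same domain (latent copied plus noise), two non-discriminating
items driven by an idiosyncratic latent with identical distributions
in both groups, and a noise item that responds to group membership
but not to severity — so it survives the chi-squared filter yet shows
a near-zero item-total correlation and is pruned.  The planted bank
uses a stronger group effect (β_ppid = 1.0) than the emulation
default: a ground-truth fixture should make its planted
discriminations unambiguous.  Recovery is judged on *terminal
dispositions* (which items end up dropped, merged, retained), not on
the stage at which a drop happens: a non-discriminating item passes
the 5%-level chi-squared filter in about 1 run in 20 by construction
of the test, and is then caught by the item-total stage.

What the simulator does **not** emulate — and hence what passing tests
do not show about real data: owners are exchangeable (no
owner-attitude clustering or response styles), items are conditionally
independent given the latent (no local dependence beyond the planted
twin), covariates do not influence item thresholds directly (only
through θ), and breed/boarding/usage enter as marginal frequencies
only, without the associations a real population carries.

## Numerical conventions and degenerate inputs

* Alpha requires ≥ 2 items, ≥ 3 respondents and positive total-score
  variance; zero total variance is an error, zero-variance single
  items yield flagged `NA` correlations.
* Chi-squared on a single-category table is undefined → manual-review
  flag; expected counts < 5 → warning, no collapsing.
* tau-c on a single shared category is 0 with a warning.
* ICC on zero between-subject variance is `NA`/"undefined"; identical
  columns give ICC 1 with a degenerate CI of [1, 1].
* The simulator validates strictly increasing thresholds and refuses
  unknown planted types; identical parameters and seed give
  byte-identical cohorts.

## Problem sizes used by the test suites

The property and end-to-end suites run at sizes chosen to make their
tolerances meaningful: alpha oracle checks on 100 random matrices (≤ 6
items × ≤ 20 rows) at 1e−10; the k = 2 closed form at n = 100 000
within ±0.02; chi-squared type-I rate over 2 000 null tables of
n = 300; ICC recovery as the mean of ten n = 500 panels per
variance-ratio preset within ±0.05; refinement recovery over 200
seeded full-size cohorts with a ≥ 95% criterion; GLM null calibration
over 1 000 cohorts of n = 120 (Kolmogorov–Smirnov uniformity) and
power over 40 full-size cohorts with a ≥ 90% criterion.

## Known limitations

* The published data-dependent results (overall α = 0.835, ICCs
  0.835/0.915, group medians 0.33/0.20, r_s = 0.466, the F table)
  rest on an undeposited 612-response survey; this package emulates
  their structure and scale but cannot and does not reproduce them.
* Test–retest reliability over long horizons is out of scope, as it
  is for the original instrument.
* The initial 42-item interview-derived bank is represented only by a
  metadata stub; the five pre-survey removals have no recorded
  wording.
* No imputation model for missing covariates; rows are dropped
  listwise in the GLM stage.
* The merge semantics of redundant items (element-wise maximum) is a
  package convention; the original merged wordings before fielding the
  final tool, so no observed-score merging rule exists to match.
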