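---
title: "Difficulty scoring and IOC risk modelling for laparoscopic liver resection: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Difficulty scoring and IOC risk modelling for laparoscopic liver resection: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llrdss)
```

## The problem

Laparoscopic liver resection (LLR) spans a wide range of technical
complexity, from peripheral wedge resections to major hepatectomies.  The
Halls difficulty scoring system (DSS) turns five preoperative risk factors
into a 0–15 point score that predicts the probability of an intraoperative
complication (IOC), defined as the composite of excessive blood loss
(> 775 mL), conversion to an open approach, or unintentional damage to
surrounding structures.  `llrdss` implements the score, the statistical
machinery of its external validation, and a continuous mean risk curve that
maps any score to an IOC probability — together with a synthetic cohort
generator so the whole pipeline runs without confidential patient data.

## The scoring system

Points: neoadjuvant chemotherapy 1; previous open liver resection 5;
malignant lesion 2; lesion size < 3 cm 0, 3–5 cm 2, > 5 cm 3; resection
class minor 0, technically major 2, anatomically major 4.  Totals bucket
into four difficulty levels — 0–2 low, 3–5 moderate, 6–9 high, 10–15
extremely high — with predicted IOC bands < 10%, 10–20%, 20–50% and > 50%.

Two conventions the published tables leave open are fixed here and are
deliberate design choices:

* **Size-category boundaries.** The printed categories are "< 3", "3–5",
  "> 5".  Sizes of exactly 3 cm and 5 cm fall in the middle (2-point)
  category, because the middle range is the only one that names both
  endpoints.
* **Band endpoints.** Adjacent probability bands share their printed
  endpoints as \[0, 0.10) / \[0.10, 0.20\] / (0.20, 0.50\] / (0.50, 1\].
  The bands are reporting metadata and enter no computation.

Blood-loss comparison for the IOC is strictly greater than the cut-off: a
loss of exactly 775 mL is not an event.  A missing blood loss contributes
`FALSE` to the excessive-loss marker — IOC components are observed events,
not imputed — and the count of such records is surfaced in the pipeline
warnings.  Clavien–Dindo grades 3a–4b count as major postoperative
morbidity; grade 5 (death) is tracked separately.

## The synthetic cohort generator

`cohort_spec()` defaults encode the marginal structure of the published
128-patient validation cohort: 17.2% neoadjuvant chemotherapy, 1.6%
previous open resection, 69.5% malignant lesions, size categories at
37.5/34.4/28.1% and resection classes at 72.6/14.1/13.3%.  Factors are
drawn independently — the study reported absolute inter-factor correlations
of only 0.005–0.321, and the generator's purpose is structural, not
patient-realistic.  Lesion sizes are uniform within the sampled category on
\[0.5, 3), \[3, 5\] and (5, 12\] cm; size enters the score only through its
category, so the within-category law matters only for the covariate coding
of the regression models.

The IOC indicator is drawn Bernoulli with probability
`weibull_cdf(total score)` under the spec's risk curve (default
λ = 8.085, k = 2.871), which makes the generator the end-to-end
parameter-recovery harness for the curve-fitting stage.  Outcome fields are
then realised consistently: an IOC record receives exactly one primary
mechanism — excessive loss, conversion, or damage — drawn with weights
defaulting to 8:18:0, the published event counts (8 excessive-loss events,
18 conversions, no damage); a non-IOC record gets sub-cut-off loss and
neither marker.  Blood loss follows a lognormal centred on the published
110 mL median, truncated at the cut-off on the appropriate side (and
rounded away from it, so the marker can never flip).  Secondary outcomes
use the published per-level rates where informative, lightly monotonised
where the 2-patient extreme group makes the printed rate uninformative
(e.g. its 0% clamping rate), so that difficulty carries signal into the
secondary endpoints: transfusion 3/17/20/50%, clamping 6/30/33/40%, major
morbidity 3/6/22/50%, operative-time location 120/150/210/310 min.

A single stream is seeded once and consumed in fixed field order, so an
identical spec yields a byte-identical cohort CSV.  What passing tests on
these cohorts do **not** show: behaviour under correlated risk factors,
realistic joint outcome distributions, or any cohort-specific quantity of
the real patients (those require the confidential data).

## Per-level statistics

`summarize_levels()` reports counts, IOC and secondary-outcome rates per
difficulty level; `risk_by_score()` gives the empirical IOC fraction per
score, with risk 1 optionally assumed at unobserved scores above 10 (the
study's convention, kept as a flag and never hard-coded into fitting).
Association tests are Pearson chi-square without continuity correction and
classical one-way ANOVA; by default the extremely-high group is excluded
from tests (the study's rule for its 2-patient group) but retained in all
summaries.  No multiplicity correction is applied, matching the original
analysis; exact (Fisher) tests are out of scope and flagged as an
extension.

Percentages print at one decimal place.  The published tables are not
internally consistent about how that decimal is obtained: 15/27 prints as
55.5 and 23/128 as 17.9 (truncation), while 27/128 prints as 21.1 and
2/128 as 1.6 (rounding).  `format_percent()` therefore supports both
conventions; truncation is the default.

## Regression models

The multivariate models use x1 (chemotherapy), x2 (prior open resection),
x3 (malignancy), x4 (lesion size) and x5 (resection class).  The published
coefficients come without units, so the coding is a documented choice:
x4 is the size in centimetres, because the printed 0.35112-per-unit
coefficient then contributes ≈ 3 points for an 8–9 cm lesion, matching the
scoring table's 3-point ceiling, whereas a 0/1/2 category coding could
contribute at most ≈ 0.7; and x5 is ordinal 0/1/2, since 2 × 1.88364 ≈ 3.8
matches the 4 points of an anatomically major resection.  Both codings are
available (`size_coding = "cm"` or `"category"`).

`fit_linear()` is ordinary least squares with normal-theory standard
errors and t-test p-values.  A covariate constant in the cohort (typical
for prior open resection at n ≈ 128 and 1.6% prevalence) is not estimable;
it is dropped with a zero coefficient and flagged, rather than aborting the
pipeline.

The nonlinear model is a conditional average estimator: a normalized
Gaussian-basis regression on standardized covariates, predicting by
`sum(y_n w_n) / sum(w_n)` with `w_n = exp(-||z - z_n||² / (2σ²))`.  The
source literature for this estimator does not pin down the width-selection
schedule, so the single free parameter σ is chosen by leave-one-out
cross-validation over 25 logarithmically spaced widths in \[0.05, 5\]
standardized units.  Standardization before fitting is itself an adopted
choice (the original analysis does not state it).  Predictions are convex
combinations of training scores, hence bounded by their range; if all
kernel weights underflow, the nearest exemplar's score is returned.

`compare_scores()` reports the comparison metrics used in the validation:
Pearson correlation, the through-origin slope k of `m = k·h`, the affine
fit `m = a·h + b` with its R², and residual summaries.  Residuals are
continuous, so the "mode (commonest)" is the maximizer of a Gaussian
kernel density (Silverman rule-of-thumb bandwidth, 1001-point grid over the
residual range) — a discrete tally could not produce the real-valued modes
the validation reports.

## The mean risk curve

The risk curve is the Weibull CDF `y_W(x) = 1 − exp(−(x/λ)^k)`.
`fit_weibull()` minimises the sum of squared differences between per-score
risks and the curve with a bounded quasi-Newton optimizer (L-BFGS-B,
analytic gradient, objective tolerance 1e-10, multi-start from four
documented initial points; default start: λ₀ = midpoint of the score
range, k₀ = 2).  The default objective is **unweighted** over the expanded
per-score points — three zeros for scores 0–2 and six ones for 10–15 —
with per-score sample-size weighting available through `weights`.

This convention matters.  On the published 16-point table the unweighted
global optimum is λ = 7.865, k = 3.083 (confirmed by an independent
Levenberg–Marquardt optimizer), while the published parameters are
λ = 8.085, k = 2.871; fits weighted by plausible per-score patient counts
consistent with the published tables land at λ ≈ 8.1–8.3, k ≈ 2.85–2.90.
The published values are therefore best explained by a patient-level
(count-weighted) fit, whose exact weights cannot be reconstructed because
per-score counts were not printed.  The package reports what its own
stated convention computes and documents the sensitivity here rather than
tuning the point set toward the published numbers.

Goodness of fit is a one-sample Kolmogorov–Smirnov test: the statistic is
the exact supremum over the sample's jump points (ties permitted), and the
p-value comes from the asymptotic Kolmogorov series truncated at 100 terms.
Exact small-sample tables are a known limitation, deliberately not
implemented.  In the pipeline the KS sample is the difficulty scores of
the IOC patients; the sample underlying the originally reported KS result
is not defined in the source and is not reproduced.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → score → validate → model → fit-curve
in fixed order and returns one consolidated report; any stage error aborts
with the stage name.  Provenance embeds the configuration and seed rather
than a wall-clock timestamp, so identical inputs serialize to byte-identical
JSON — reproducibility is preferred over audit timestamps, which a caller
can add externally.  Low-count factors, assumed risk points and missing
blood-loss records are collected as warnings inside the report.

Problem sizes used by the test-suite: marginal-recovery and
risk-curve-recovery checks run at n = 10⁵ (where 3 binomial standard
errors give sub-percent resolution), the chi-square null calibration at
2000 replicates of n = 400, and pipeline smoke tests at the study's
n = 128.

## Known limitations

* Risk factors are simulated independently; a Gaussian-copula correlation
  knob is a possible extension, and results on correlated cohorts are
  unverified.
* The KS p-value is asymptotic; for very small samples it is only
  indicative.
* Cohort-specific results of the original validation (its correlation
  coefficients, its regression coefficients re-estimated from patient
  data) require the confidential cohort and are out of scope; the package
  reproduces the methodology, the published worked values, and the in-paper
  tables that are printed in full.
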