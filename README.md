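# llrdss

Difficulty scoring and intraoperative-complication risk modelling for
laparoscopic liver resection (LLR).

Preoperative difficulty assessment is central to safe adoption of LLR: the
Halls difficulty scoring system (DSS) assigns points to five risk factors —
neoadjuvant chemotherapy (1), previous open liver resection (5), malignant
lesion (2), lesion size (< 3 cm: 0, 3–5 cm: 2, > 5 cm: 3) and resection
class (minor: 0, technically major: 2, anatomically major: 4) — and maps the
0–15 total onto four difficulty levels (low 0–2, moderate 3–5, high 6–9,
extremely high 10–15) predicting the probability of an intraoperative
complication (IOC): blood loss > 775 mL, conversion to open surgery, or
unintentional damage to surrounding structures.

`llrdss` is aimed at surgical-outcomes researchers validating such scores.
It implements:

* the scoring system and IOC endpoint (`score_components()`,
  `derive_ioc()`);
* per-level outcome summaries, per-factor chi-square associations and
  one-way ANOVA, with the low-count extremely-high group excluded from
  tests (`summarize_levels()`, `factor_association_table()`,
  `level_outcome_tests()`);
* a multivariate linear score model and a conditional-average (Gaussian
  kernel) nonlinear model with score-comparison metrics (`fit_linear()`,
  `fit_cae()`, `compare_scores()`);
* the continuous mean risk curve: a Weibull CDF
  `y_W(x) = 1 − exp(−(x/λ)^k)` fitted to per-score IOC risks by nonlinear
  least squares, with a one-sample Kolmogorov–Smirnov goodness-of-fit test
  (`fit_weibull()`, `ks_test_weibull()`, `mean_risk()`);
* a synthetic cohort generator reproducing the marginal structure of the
  published 128-patient external-validation cohort, with IOC events drawn
  from the risk curve (`generate_cohort()`), so every stage runs without
  confidential patient data;
* a one-call pipeline (`run_pipeline()`) and a thin CLI
  (`inst/cli/llrdss` with subcommands `simulate`, `score`, `validate`,
  `model`, `fit-curve`, `run`).

## Worked example

```r
library(llrdss)

coh <- score_cohort(generate_cohort(cohort_spec(n = 128, seed = 42)))
table(coh$difficulty_level)
#>            low       moderate           high extremely_high
#>             37             61             29              1

rep <- run_pipeline(run_config(seed = 42), spec = cohort_spec(n = 128, seed = 42))
rep
#> LLR difficulty-score validation report
#>   cohort: n = 128 (synthetic)
#>   levels: overall 128 (100.0%), low 37 (28.9%), moderate 61 (47.6%), high 29 (22.6%), extremely_high 1 (0.7%)
#> Weibull risk curve: lambda = 9.4050 (scale), k = 2.1477 (shape)
#>   least-squares objective: 0.783394 over 16 points
#> Kolmogorov-Smirnov: D = 0.4730, p = 0.0000 (n = 26, asymptotic)
#> Score comparison: r = 0.9561, m = 0.98043 h, m = 0.91408 h + 0.34837 (R2 = 0.91408)
#>   residuals (model - reference): mean -0.00000, median 0.13732, mode -0.64115, max |r| 1.257
#> Score comparison: r = 0.9983, m = 0.99847 h, m = 0.99463 h + 0.02016 (R2 = 0.99663)
#>   residuals (model - reference): mean -0.00161, median 0.00000, mode -0.00064, max |r| 1.001
#>   notes: factor(s) not computable: previous_open_liver_resection; 5 assumed unit-risk score point(s) above 10
```

Reading the output: the synthetic cohort's level mix is close to the
published 36/63/27/2 split; the two score comparisons show how well the
linear (r = 0.956) and kernel (r = 0.998) models reconstruct the 0–15
score from the raw covariates on this cohort.  The risk-curve parameters
fitted to one n = 128 cohort are noisy; at n = 10⁵ they recover the
generating λ = 8.085, k = 2.871 to within ±0.3 (this is an invariant of
the test suite).

The fitted curve converts any score into an IOC probability:

```r
mean_risk(c(3, 6, 9), weibull_curve(8.085, 2.871))
#> [1] 0.05640525 0.34606004 0.74345334
```

so a score-6 (high-difficulty) resection carries a ~35% mean IOC risk.

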