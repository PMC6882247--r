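test_that("the risk curve is a valid Weibull CDF", {
  curve <- weibull_curve(8.085, 2.871)
  expect_equal(weibull_cdf(0, curve), 0)
  expect_equal(weibull_cdf(8.085, curve), 1 - exp(-1))
  # implementation (pweibull) against the closed-form expression
  x <- c(0.5, 2, 8.085, 16.17, 40)
  expect_equal(weibull_cdf(x, curve),
               1 - exp(-(x / 8.085)^2.871), tolerance = 1e-14)
  expect_equal(weibull_cdf(16.17, curve), 1 - exp(-2^2.871), tolerance = 1e-12)
  grid <- seq(0, 60, by = 0.1)
  expect_true(all(diff(weibull_cdf(grid, curve)) >= 0))
  expect_equal(weibull_cdf(1e4, curve), 1)
  expect_error(weibull_cdf(-1, curve), "non-negative")
  expect_error(weibull_curve(-1, 2), "positive")
  expect_error(weibull_curve(2, 0), "positive")
})

test_that("the published risk table expands to the 16 per-score points", {
  pts <- expand_risk_table(halls_risk_table())
  expect_identical(nrow(pts), 16L)
  expect_equal(pts$score, as.numeric(0:15))
  expect_equal(pts$risk, c(0, 0, 0, 0.07, 0.11, 0.13, 0.50, 0.57, 0.50, 0.67,
                           rep(1, 6)))
  expect_identical(pts$provenance,
                   c(rep("observed", 11), rep("assumed", 5)))
  expect_true(all(diff(pts$score) > 0))

  single <- expand_risk_table(data.frame(score_min = 0, score_max = 2, risk = 0),
                              assume_unity_above = NULL)
  expect_equal(single$risk, c(0, 0, 0))

  tab <- halls_risk_table()
  expect_identical(nrow(expand_risk_table(tab)),
                   as.integer(sum(tab$score_max - tab$score_min + 1)))
  gap <- data.frame(score_min = c(0, 4), score_max = c(2, 6), risk = c(0, 1))
  expect_error(expand_risk_table(gap), "contiguous")
  overlap <- data.frame(score_min = c(0, 2), score_max = c(2, 6), risk = c(0, 1))
  expect_error(expand_risk_table(overlap), "contiguous")
})

test_that("noise-free curve samples are recovered to 1e-6", {
  truth <- weibull_curve(8.085, 2.871)
  pts <- data.frame(score = 0:15, risk = weibull_cdf(0:15, truth))
  fit <- fit_weibull(pts)
  expect_equal(fit$scale_lambda, 8.085, tolerance = 1e-6)
  expect_equal(fit$shape_k, 2.871, tolerance = 1e-6)
  expect_lt(attr(fit, "objective"), 1e-12)
})

test_that("the fit is invariant to point order and duplication, and locally optimal", {
  pts <- expand_risk_table(halls_risk_table())
  fit <- fit_weibull(pts)
  shuffled <- pts[rev(seq_len(nrow(pts))), ]
  fit_r <- fit_weibull(shuffled)
  expect_equal(fit_r$scale_lambda, fit$scale_lambda, tolerance = 1e-7)
  expect_equal(fit_r$shape_k, fit$shape_k, tolerance = 1e-7)
  doubled <- rbind(pts, pts)
  fit_d <- fit_weibull(doubled)
  expect_equal(fit_d$scale_lambda, fit$scale_lambda, tolerance = 1e-6)
  expect_equal(attr(fit_d, "objective"), 2 * attr(fit, "objective"),
               tolerance = 1e-6)

  # +/- 1% perturbations never reduce the objective
  obj <- function(l, k) sum((pts$risk - (1 - exp(-(pts$score / l)^k)))^2)
  base <- obj(fit$scale_lambda, fit$shape_k)
  for (dl in c(0.99, 1, 1.01)) {
    for (dk in c(0.99, 1, 1.01)) {
      expect_gte(obj(fit$scale_lambda * dl, fit$shape_k * dk), base - 1e-12)
    }
  }
})

test_that("the fit agrees with an independent Levenberg-Marquardt optimizer", {
  pts <- expand_risk_table(halls_risk_table())
  fit <- fit_weibull(pts)
  lm_fit <- minpack.lm::nlsLM(
    risk ~ 1 - exp(-(score / l)^k), data = pts,
    start = list(l = 8, k = 2),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, maxiter = 500))
  expect_equal(fit$scale_lambda, unname(coef(lm_fit)["l"]), tolerance = 1e-5)
  expect_equal(fit$shape_k, unname(coef(lm_fit)["k"]), tolerance = 1e-5)
})

test_that("weighted fitting is available and responds to the weights", {
  pts <- expand_risk_table(halls_risk_table())
  w <- c(12, 12, 12, 30, 18, 15, 6, 7, 8, 6, 2, rep(1, 5))
  fit_w <- fit_weibull(pts, weights = w)
  fit_u <- fit_weibull(pts)
  expect_false(isTRUE(all.equal(fit_w$scale_lambda, fit_u$scale_lambda,
                                tolerance = 1e-3)))
  expect_error(fit_weibull(pts, weights = w[-1]), "one per point")
  expect_error(fit_weibull(pts[1:2, ]), ">= 3 points")
})

test_that("KS statistic is the exact supremum over the sample's jump points", {
  curve <- weibull_curve(8.085, 2.871)
  # near-perfect fit via mid-probability quantiles: D is exactly 1/(2n)
  n <- 100
  q <- 8.085 * (-log(1 - (seq_len(n) - 0.5) / n))^(1 / 2.871)
  gof <- ks_test_weibull(q, curve)
  expect_lte(gof$ks_statistic, 0.005 + 1e-12)

  # n copies of a single value: supremum is max(F(v), 1 - F(v))
  for (v in c(2, 6, 12)) {
    gof1 <- ks_test_weibull(rep(v, 7), curve)
    f <- weibull_cdf(v, curve)
    expect_equal(gof1$ks_statistic, max(f, 1 - f), tolerance = 1e-12)
  }

  # brute-force supremum over a dense grid augmented with the jump points
  set.seed(5)
  smp <- rweibull(37, shape = 2.5, scale = 7)
  gof2 <- ks_test_weibull(smp, curve)
  grid <- sort(c(seq(0, max(smp) * 1.1, length.out = 1e6),
                 smp, pmax(smp - 1e-9, 0)))
  fn <- ecdf(smp)
  d_grid <- max(abs(fn(grid) - weibull_cdf(grid, curve)))
  expect_equal(gof2$ks_statistic, d_grid, tolerance = 1e-6)

  # ties are permitted
  tied <- c(smp, smp[1:5])
  grid2 <- sort(c(seq(0, max(tied) * 1.1, length.out = 2e5), tied,
                  pmax(tied - 1e-9, 0)))
  fn2 <- ecdf(tied)
  expect_equal(ks_test_weibull(tied, curve)$ks_statistic,
               max(abs(fn2(grid2) - weibull_cdf(grid2, curve))),
               tolerance = 1e-6)
})

test_that("asymptotic p-value matches the Kolmogorov distribution", {
  curve <- weibull_curve(8, 2.5)
  set.seed(9)
  smp <- rweibull(200, 2.5, 8)
  gof <- ks_test_weibull(smp, curve)
  ref <- suppressWarnings(
    stats::ks.test(smp, function(x) weibull_cdf(x, curve), exact = FALSE))
  expect_equal(gof$ks_statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(gof$p_value, ref$p.value, tolerance = 1e-4)
  expect_error(ks_test_weibull(numeric(0), curve), "non-empty")
})

test_that("mean risk evaluates the curve and reports the level band", {
  curve <- weibull_curve(8.085, 2.871)
  expect_equal(mean_risk(0, curve), 0, ignore_attr = TRUE)
  expect_equal(mean_risk(8.085, curve), 1 - exp(-1), tolerance = 1e-12,
               ignore_attr = TRUE)
  risks <- mean_risk(0:15, curve)
  expect_true(all(diff(risks) >= 0))
  expect_identical(as.character(attr(risks, "level")[7]), "high")
  expect_warning(mean_risk(20, curve), "outside")
})
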