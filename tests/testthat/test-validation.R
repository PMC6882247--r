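test_that("percentages print at one decimal under the truncation convention", {
  expect_equal(format_percent(6, 63), 9.5)
  expect_equal(format_percent(15, 27), 55.5)     # 55.55... truncates, not rounds
  expect_equal(format_percent(23, 128), 17.9)
  expect_equal(format_percent(1, 2, "round_half_even"), 50.0)
  expect_equal(format_percent(15, 27, "round_half_even"), 55.6)
  expect_true(is.na(format_percent(1, 0)))
})

test_that("level summaries reproduce the study-structured shares and rates", {
  coh <- make_table3_cohort()
  sm <- summarize_levels(coh)
  expect_identical(sm$level,
                   c("overall", "low", "moderate", "high", "extremely_high"))
  expect_identical(sm$n, c(128L, 36L, 63L, 27L, 2L))
  # default truncation convention (27/128 = 21.09 -> 21.0, 2/128 = 1.56 -> 1.5)
  expect_equal(sm$share_pct[-1], c(28.1, 49.2, 21.0, 1.5))
  expect_equal(sm$ioc_rate_pct, c(17.9, 0, 9.5, 55.5, 100))
  # the published level shares follow half-even rounding instead
  expect_equal(format_percent(c(36, 63, 27, 2), 128, "round_half_even"),
               c(28.1, 49.2, 21.1, 1.6))
  # conservation: per-level counts and events sum to the overall row
  expect_identical(sum(sm$n[-1]), sm$n[1])
  expect_identical(sum(sm$ioc_events[-1]), sm$ioc_events[1])
})

test_that("a single-level cohort summarises to one row with a 0% rate", {
  coh <- as_cohort(make_level_block("s", 5, 0, "low"))
  sm <- summarize_levels(coh)
  expect_identical(sm$level, c("overall", "low"))
  expect_equal(sm$ioc_rate_pct, c(0, 0))
  expect_identical(nrow(summarize_levels(coh[0, ])), 0L)
})

test_that("risk_by_score tabulates empirical fractions and assumed points", {
  blocks <- rbind(
    make_level_block("a", 100, 7, "moderate"),   # score 4, risk 0.07
    make_level_block("b", 3, 2, "high")          # score 6, risk 2/3
  )
  rt <- risk_by_score(as_cohort(blocks))
  expect_equal(rt$risk[rt$score == 4], 0.07)
  expect_equal(rt$risk[rt$score == 6], 2 / 3)
  expect_true(all(rt$provenance == "observed"))

  rt2 <- risk_by_score(as_cohort(blocks), assume_unity_above = 10)
  assumed <- rt2[rt2$provenance == "assumed", ]
  expect_identical(assumed$score, as.numeric(11:15))
  expect_true(all(assumed$risk == 1))
  expect_true(all(assumed$n == 0))

  # invariant to record order
  shuffled <- as_cohort(blocks[sample.int(nrow(blocks)), ])
  expect_equal(risk_by_score(shuffled), rt)

  # all-IOC cohort maps every observed score to 1
  all_ioc <- as_cohort(make_level_block("c", 10, 10, "moderate"))
  expect_true(all(risk_by_score(all_ioc)$risk == 1))
})

test_that("chi-square matches the direct-summation oracle", {
  res <- chi_square_association(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  tab <- matrix(c(20, 5, 5, 20), 2)
  res2 <- chi_square_association(tab)
  expect_equal(res2$statistic, chisq_oracle(tab), tolerance = 1e-12)
  expect_equal(res2$statistic, 18)              # (7.5^2 / 12.5) * 4
  expect_identical(res2$df, 1L)

  # random tables agree with the oracle to 1e-10
  set.seed(31)
  for (i in 1:20) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    tab <- matrix(rpois(r * c, 12) + 1, r, c)
    res <- chi_square_association(tab)
    expect_equal(res$statistic, chisq_oracle(tab), tolerance = 1e-10)
    expect_equal(res$p_value,
                 pchisq(chisq_oracle(tab), (r - 1) * (c - 1), lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("group exclusion drops rows before testing and reports groups_used", {
  tab <- rbind(low = c(30, 0), moderate = c(57, 6), high = c(12, 15),
               extremely_high = c(0, 2))
  res <- chi_square_association(tab, exclude_groups = "extremely_high")
  expect_identical(res$groups_used, c("low", "moderate", "high"))
  expect_identical(res$df, 2L)                  # (3-1)(2-1)... columns = 2
  expect_error(
    chi_square_association(rbind(a = c(5, 0), b = c(7, 0)), exclude_groups = NULL),
    "degenerate")
})

test_that("one-way ANOVA matches the explicit sum-of-squares oracle", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  res <- one_way_anova(groups)
  orc <- anova_oracle(groups)
  expect_equal(res$statistic, orc$statistic, tolerance = 1e-12)
  expect_equal(res$statistic, 3)                # SSB/2 = 3, SSW/6 = 1
  expect_equal(res$df, orc$df)
  expect_equal(res$p_value, orc$p_value, tolerance = 1e-12)

  same <- one_way_anova(list(a = rep(2, 4), b = rep(2, 5), c = rep(2, 3)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  shifted <- one_way_anova(list(a = rnorm(10), b = rnorm(10) + 100))
  expect_lt(shifted$p_value, 0.001)

  set.seed(17)
  for (i in 1:10) {
    g <- lapply(1:3, function(j) rnorm(sample(3:8, 1), mean = j / 2))
    names(g) <- letters[1:3]
    expect_equal(one_way_anova(g)$statistic, anova_oracle(g)$statistic,
                 tolerance = 1e-10)
  }
})

test_that("per-factor association table mirrors the univariable analysis", {
  coh <- make_table3_cohort()
  fa <- factor_association_table(coh)
  expect_identical(nrow(fa), 9L)
  # lesion malignancy perfectly separates IOC here (moderate+ blocks are malignant)
  mal <- fa[fa$factor == "malignant_lesion", ]
  expect_true(mal$computable)
  expect_lt(mal$p_value, 0.001)
  # chemotherapy occurs only in the 2-patient extreme block: low count flag
  chemo <- fa[fa$factor == "neoadjuvant_chemotherapy", ]
  expect_match(chemo$flags, "low-count")
  # prior open resection: 2 patients, computable but low-count
  prior <- fa[fa$factor == "previous_open_liver_resection", ]
  expect_identical(prior$n_with_factor, 2L)
  expect_true(prior$computable)
  expect_match(prior$flags, "low-count")

  # a factor constant in the cohort is flagged, and the pipeline continues
  small <- as_cohort(make_level_block("s", 10, 2, "low"))  # all minor resections
  fa2 <- factor_association_table(small)
  tm <- fa2[fa2$factor == "resection_technically_major", ]
  expect_false(tm$computable)
  expect_match(tm$flags, "not-computable")
})

test_that("level outcome tests exclude the extreme group by default", {
  coh <- make_table3_cohort()
  tests <- level_outcome_tests(coh)
  expect_identical(tests$ioc$groups_used, c("low", "moderate", "high"))
  expect_lt(tests$ioc$p_value, 0.001)
  tests_all <- level_outcome_tests(coh, exclude_extreme_group = FALSE)
  expect_identical(tests_all$ioc$groups_used,
                   c("low", "moderate", "high", "extremely_high"))
})
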