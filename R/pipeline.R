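#' Pipeline run configuration
#'
#' @param thresholds An [ioc_thresholds()].
#' @param percent_convention Percentage convention, see [format_percent()].
#' @param exclude_extreme_group Exclude the extremely-high level from tests
#'   (default `TRUE`, the study's rule).
#' @param assume_unity_above Score above which unobserved risks are assumed 1
#'   in the risk table (default 10); `NULL` disables the assumption.
#' @param covariate_coding `"cm"` or `"category"`, see [encode_covariates()].
#' @param cae_width `"auto"` or a positive width for [fit_cae()].
#' @param seed Integer seed used when a cohort must be generated.
#' @return Object of class `run_config`.
#' @export
run_config <- function(thresholds = ioc_thresholds(),
                       percent_convention = c("truncate", "round_half_even"),
                       exclude_extreme_group = TRUE,
                       assume_unity_above = 10,
                       covariate_coding = c("cm", "category"),
                       cae_width = "auto",
                       seed = 1L) {
  structure(list(
    thresholds = thresholds,
    percent_convention = match.arg(percent_convention),
    exclude_extreme_group = isTRUE(exclude_extreme_group),
    assume_unity_above = assume_unity_above,
    covariate_coding = match.arg(covariate_coding),
    cae_width = cae_width,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full validation pipeline
#'
#' Executes the stages in fixed order — score, per-level summaries and tests,
#' per-factor associations, per-score risk table, linear and
#' conditional-average models with score comparisons, Weibull risk-curve fit
#' and Kolmogorov-Smirnov goodness of fit — and returns one consolidated
#' report.  With identical config and cohort (or spec seed) the report is
#' identical; provenance embeds the config and seed rather than a wall-clock
#' timestamp so serialized reports are byte-reproducible.
#'
#' The goodness-of-fit sample is the difficulty scores of the IOC patients,
#' tested against the fitted curve.
#'
#' @param config A [run_config()].
#' @param cohort An `llr_cohort`, or `NULL` to generate one from `spec`.
#' @param spec A [cohort_spec()] used when `cohort` is `NULL`.
#' @return List of class `validation_report` with elements
#'   `level_summaries`, `level_tests`, `factor_associations`, `risk_table`,
#'   `linear_model`, `linear_comparison`, `cae_width`, `cae_loo_mse`,
#'   `cae_comparison`, `curve`, `gof`, `warnings`, `provenance`.
#' @examples
#' rep <- run_pipeline(run_config(seed = 1), spec = cohort_spec(n = 128, seed = 1))
#' rep$curve
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL, spec = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- "input"
  notes <- character(0)
  result <- tryCatch({
    if (is.null(cohort)) {
      if (is.null(spec)) stop("supply a cohort or a cohort_spec")
      stage <- "simulate"
      cohort <- generate_cohort(spec, config$thresholds)
    }
    stage <- "score"
    cohort <- score_cohort(cohort)
    ioc <- derive_ioc(cohort, config$thresholds)
    if (any(is.na(cohort$blood_loss_ml))) {
      notes <- c(notes, sprintf("%d record(s) with missing blood loss treated as non-excessive",
                                sum(is.na(cohort$blood_loss_ml))))
    }

    stage <- "validate"
    summaries <- summarize_levels(cohort, config$thresholds,
                                  config$percent_convention)
    tests <- level_outcome_tests(cohort, config$thresholds,
                                 config$exclude_extreme_group)
    factors <- factor_association_table(cohort, config$thresholds)
    if (any(!factors$computable)) {
      notes <- c(notes, paste("factor(s) not computable:",
                              paste(factors$factor[!factors$computable],
                                    collapse = ", ")))
    }
    risk <- risk_by_score(cohort, config$thresholds,
                          config$assume_unity_above)
    if (any(risk$provenance == "assumed")) {
      notes <- c(notes, sprintf("%d assumed unit-risk score point(s) above %s",
                                sum(risk$provenance == "assumed"),
                                config$assume_unity_above))
    }

    stage <- "model"
    x <- encode_covariates(cohort, config$covariate_coding)
    y <- cohort$total_score
    lin <- fit_linear(x, y)
    lin_cmp <- compare_scores(predict_linear(lin, x), y)
    cae <- fit_cae(x, y, width = config$cae_width)
    cae_cmp <- compare_scores(predict_cae(cae, x), y)

    stage <- "fit-curve"
    curve <- fit_weibull(risk)
    gof_sample <- cohort$total_score[ioc]
    gof <- if (length(gof_sample) > 0) ks_test_weibull(gof_sample, curve) else NULL

    structure(list(
      level_summaries = summaries,
      level_tests = tests,
      factor_associations = factors,
      risk_table = risk,
      linear_model = lin,
      linear_comparison = lin_cmp,
      cae_width = cae$smoothing_width,
      cae_loo_mse = cae$loo_mse,
      cae_comparison = cae_cmp,
      curve = curve,
      gof = gof,
      warnings = notes,
      provenance = list(config = unclass_config(config),
                        seed = if (!is.null(spec)) spec$seed else attr(cohort, "seed"),
                        n = nrow(cohort),
                        cohort_provenance = attr(cohort, "provenance"))
    ), class = "validation_report")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  result
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$thresholds <- unclass(cfg$thresholds)
  cfg
}

#' Serialize a validation report to JSON
#'
#' @param report A `validation_report` from [run_pipeline()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  as_plain <- function(x) {
    if (inherits(x, "weibull_curve")) {
      list(lambda = x$scale_lambda, k = x$shape_k,
           objective = attr(x, "objective"), n_points = attr(x, "n_points"))
    } else if (inherits(x, c("llr_test", "llr_gof", "score_comparison",
                             "linear_score_model"))) {
      lapply(unclass(x), as_plain)
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, as_plain)
    } else if (is.factor(x)) as.character(x) else x
  }
  jsonlite::write_json(as_plain(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.validation_report <- function(x, ...) {
  cat("LLR difficulty-score validation report\n")
  cat(sprintf("  cohort: n = %d (%s)\n", x$provenance$n,
              x$provenance$cohort_provenance))
  cat(sprintf("  levels: %s\n",
              paste(sprintf("%s %d (%.1f%%)", x$level_summaries$level,
                            x$level_summaries$n, x$level_summaries$share_pct),
                    collapse = ", ")))
  print(x$curve)
  if (!is.null(x$gof)) print(x$gof)
  print(x$linear_comparison)
  print(x$cae_comparison)
  if (length(x$warnings)) cat("  notes:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}
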