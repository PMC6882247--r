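#' Format a percentage at one decimal place
#'
#' The validation tables report percentages at one decimal place obtained by
#' truncation toward zero (e.g. 15/27 prints as 55.5, not 55.6); half-even
#' rounding is available as an alternative convention.
#'
#' @param numerator,denominator Counts (vectorised).
#' @param convention `"truncate"` (default) or `"round_half_even"`.
#' @return Numeric percentage(s) with one decimal; `NA` where the denominator
#'   is zero.
#' @examples
#' format_percent(15, 27)             # 55.5
#' format_percent(6, 63)              # 9.5
#' @export
format_percent <- function(numerator, denominator,
                           convention = c("truncate", "round_half_even")) {
  convention <- match.arg(convention)
  pct <- 100 * numerator / denominator
  out <- if (convention == "truncate") trunc(pct * 10) / 10 else round(pct, 1)
  out[denominator == 0] <- NA_real_
  out
}

median_range <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(list(median = NA_real_, min = NA_real_, max = NA_real_))
  }
  list(median = stats::median(x), min = min(x), max = max(x))
}

#' Per-level outcome summary
#'
#' Groups a cohort by difficulty level and reports, per level and overall:
#' patient count and share, IOC events and rate, transfusion rate, operative
#' time (median and range), pedicle clamping rate and total clamping time
#' (median and range among clamped patients), and major-morbidity rate
#' (Clavien-Dindo 3a-4b).  Percentages use [format_percent()].
#'
#' @param cohort An `llr_cohort` (scored or not; scoring is applied
#'   internally when absent).
#' @param thresholds An [ioc_thresholds()].
#' @param convention Percentage convention, see [format_percent()].
#' @return data.frame with one row per level present (in level order) plus an
#'   `"overall"` row; zero rows for an empty cohort.  Records with missing
#'   blood loss are counted in `n_missing_blood_loss`.
#' @export
summarize_levels <- function(cohort, thresholds = ioc_thresholds(),
                             convention = c("truncate", "round_half_even")) {
  convention <- match.arg(convention)
  if (nrow(cohort) == 0) return(data.frame())
  if (!"total_score" %in% names(cohort)) cohort <- score_cohort(cohort)
  ioc <- derive_ioc(cohort, thresholds)
  level <- as.character(cohort$difficulty_level)
  major <- clavien_major(cohort$clavien_dindo)
  n_total <- nrow(cohort)

  one_group <- function(idx, label) {
    k <- sum(idx)
    ot <- median_range(cohort$operative_time_min[idx])
    cl_times <- cohort$clamping_total_min[idx & cohort$pedicle_clamping]
    ct <- median_range(cl_times)
    data.frame(
      level = label, n = k,
      share_pct = format_percent(k, n_total, convention),
      ioc_events = sum(ioc[idx]),
      ioc_rate_pct = format_percent(sum(ioc[idx]), k, convention),
      transfusion_rate_pct = format_percent(sum(cohort$transfusion[idx]), k, convention),
      operative_time_median = ot$median, operative_time_min = ot$min,
      operative_time_max = ot$max,
      clamping_rate_pct = format_percent(sum(cohort$pedicle_clamping[idx]), k, convention),
      clamping_total_median = ct$median, clamping_total_min = ct$min,
      clamping_total_max = ct$max,
      major_morbidity_rate_pct = format_percent(sum(major[idx], na.rm = TRUE), k, convention),
      n_missing_blood_loss = sum(is.na(cohort$blood_loss_ml[idx])),
      stringsAsFactors = FALSE
    )
  }
  present <- DIFFICULTY_LEVELS[DIFFICULTY_LEVELS %in% level]
  rows <- lapply(present, function(lv) one_group(level == lv, lv))
  rows <- c(list(one_group(rep(TRUE, n_total), "overall")), rows)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical IOC risk per difficulty score
#'
#' Tabulates the empirical IOC fraction at each observed total score.  When
#' `assume_unity_above` is given, unobserved scores strictly above it are
#' added with risk 1 and flagged `assumed` (the study's convention above a
#' score of 10); observed scores keep their empirical risk.  Scores never
#' observed and not covered by the assumption are absent.
#'
#' @param cohort An `llr_cohort`.
#' @param thresholds An [ioc_thresholds()].
#' @param assume_unity_above Integer or `NULL` (default).
#' @return data.frame `score`, `n`, `ioc_events`, `risk`, `provenance`;
#'   invariant to record order.
#' @export
risk_by_score <- function(cohort, thresholds = ioc_thresholds(),
                          assume_unity_above = NULL) {
  if (!"total_score" %in% names(cohort)) cohort <- score_cohort(cohort)
  ioc <- derive_ioc(cohort, thresholds)
  scores <- sort(unique(cohort$total_score))
  n <- vapply(scores, function(s) sum(cohort$total_score == s), integer(1))
  ev <- vapply(scores, function(s) sum(ioc[cohort$total_score == s]), integer(1))
  out <- data.frame(score = as.numeric(scores), n = n, ioc_events = ev,
                    risk = ifelse(n > 0, ev / n, NA_real_),
                    provenance = "observed", stringsAsFactors = FALSE)
  if (!is.null(assume_unity_above)) {
    missing_scores <- setdiff(seq(assume_unity_above + 1, 15), scores)
    if (assume_unity_above < 15 && length(missing_scores) > 0) {
      out <- rbind(out, data.frame(score = as.numeric(missing_scores),
                                   n = 0L, ioc_events = 0L, risk = 1,
                                   provenance = "assumed",
                                   stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$score), ]
  rownames(out) <- NULL
  out
}

new_test_result <- function(statistic, df, p_value, groups_used,
                            method, flags = character(0)) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), groups_used = groups_used,
                 method = method, flags = flags),
            class = "llr_test")
}

#' @export
print.llr_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(x$df, collapse = ","), x$p_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction, with optional group
#' (row) exclusion — the study excluded the 2-patient extremely-high group
#' from all tests.
#'
#' @param table Matrix of non-negative counts (groups in rows), with row
#'   names when `exclude_groups` is used.
#' @param exclude_groups Character vector of row names to drop before
#'   testing.
#' @return An `llr_test` with statistic, df = (r-1)(c-1), upper-tail p-value
#'   and `groups_used`.
#' @examples
#' chi_square_association(rbind(low = c(10, 2), moderate = c(8, 6)))
#' @export
chi_square_association <- function(table, exclude_groups = NULL) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.null(exclude_groups) && length(exclude_groups) > 0) {
    if (is.null(rownames(table))) {
      stop("`table` must have row names to exclude groups", call. = FALSE)
    }
    table <- table[!(rownames(table) %in% exclude_groups), , drop = FALSE]
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("table must be at least 2x2 after exclusion", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a row or column is all zero after exclusion",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  flags <- if (any(ct$expected < 5)) "low-count: expected cell below 5" else character(0)
  new_test_result(ct$statistic, ct$parameter, ct$p.value,
                  rownames(table) %||% paste0("group", seq_len(nrow(table))),
                  "Pearson chi-square", flags)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) across
#' groups, with optional group exclusion.  If every observation is identical
#' the F statistic is 0 with p = 1.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @param exclude_groups Character vector of group names to drop.
#' @return An `llr_test` with the F statistic, `df = c(df1, df2)` and
#'   upper-tail p-value.
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
#' @export
one_way_anova <- function(groups, exclude_groups = NULL) {
  if (!is.null(exclude_groups)) {
    groups <- groups[!(names(groups) %in% exclude_groups)]
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  k <- length(groups)
  if (k < 2) stop("need at least 2 retained non-empty groups", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  if (length(x) <= k) stop("total observations must exceed group count", call. = FALSE)
  if (stats::var(x) == 0) {
    return(new_test_result(0, c(k - 1, length(x) - k), 1, names(groups),
                           "One-way ANOVA"))
  }
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  new_test_result(ft$statistic, unname(ft$parameter), ft$p.value,
                  names(groups), "One-way ANOVA")
}

#' Per-factor association with the IOC
#'
#' One 2x2 Pearson chi-square per binary risk-factor indicator against the
#' IOC, mirroring the univariable analysis of the validation study:
#' chemotherapy, previous open resection, malignancy, each lesion-size
#' category, and each resection class.  A factor that is constant in the
#' cohort is flagged not-computable rather than failing the pipeline; a
#' computable factor with an expected cell below 5 is flagged low-count.
#'
#' @param cohort An `llr_cohort`.
#' @param thresholds An [ioc_thresholds()].
#' @return data.frame with `factor`, `n_with_factor`, `statistic`, `df`,
#'   `p_value`, `computable`, `flags`.
#' @export
factor_association_table <- function(cohort, thresholds = ioc_thresholds()) {
  ioc <- derive_ioc(cohort, thresholds)
  size <- cohort$lesion_size_cm
  indicators <- list(
    neoadjuvant_chemotherapy = as.logical(cohort$neoadjuvant_chemotherapy),
    previous_open_liver_resection = as.logical(cohort$previous_open_liver_resection),
    malignant_lesion = cohort$lesion_type == "malignant",
    lesion_size_lt3 = size < 3,
    lesion_size_3to5 = size >= 3 & size <= 5,
    lesion_size_gt5 = size > 5,
    resection_minor = cohort$resection_class == "minor",
    resection_technically_major = cohort$resection_class == "technically_major",
    resection_anatomically_major = cohort$resection_class == "anatomically_major"
  )
  rows <- lapply(names(indicators), function(nm) {
    f <- indicators[[nm]]
    base <- data.frame(factor = nm, n_with_factor = sum(f),
                       statistic = NA_real_, df = NA_integer_,
                       p_value = NA_real_, computable = FALSE, flags = "",
                       stringsAsFactors = FALSE)
    if (length(unique(f)) < 2 || length(unique(ioc)) < 2) {
      base$flags <- "not-computable: constant factor or outcome"
      return(base)
    }
    tab <- table(factor(f, levels = c(FALSE, TRUE)),
                 factor(ioc, levels = c(FALSE, TRUE)))
    res <- chi_square_association(unclass(tab))
    base$statistic <- res$statistic
    base$df <- res$df
    base$p_value <- res$p_value
    base$computable <- TRUE
    base$flags <- paste(res$flags, collapse = "; ")
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-level association and ANOVA tests for a cohort
#'
#' Runs the study's per-level tests: chi-square of level against IOC,
#' transfusion, pedicle clamping and major morbidity, and one-way ANOVA of
#' operative time and total clamping time across levels.  By default the
#' extremely-high group is excluded from all tests (the study's rule for its
#' 2-patient group) but retained in summaries.
#'
#' @param cohort An `llr_cohort`.
#' @param thresholds An [ioc_thresholds()].
#' @param exclude_extreme_group Exclude `extremely_high` from tests
#'   (default `TRUE`).
#' @return Named list of `llr_test` objects.
#' @export
level_outcome_tests <- function(cohort, thresholds = ioc_thresholds(),
                                exclude_extreme_group = TRUE) {
  if (!"total_score" %in% names(cohort)) cohort <- score_cohort(cohort)
  excl <- if (exclude_extreme_group) "extremely_high" else NULL
  level <- factor(as.character(cohort$difficulty_level),
                  levels = DIFFICULTY_LEVELS)
  level <- droplevels(level)
  ioc <- derive_ioc(cohort, thresholds)
  major <- clavien_major(cohort$clavien_dindo)

  chi_of <- function(outcome) {
    tab <- table(level, factor(outcome, levels = c(FALSE, TRUE)))
    tryCatch(chi_square_association(unclass(tab), exclude_groups = excl),
             error = function(e) NULL)
  }
  anova_of <- function(values) {
    groups <- split(values, level)
    tryCatch(one_way_anova(groups, exclude_groups = excl),
             error = function(e) NULL)
  }
  list(
    ioc = chi_of(ioc),
    transfusion = chi_of(as.logical(cohort$transfusion)),
    pedicle_clamping = chi_of(as.logical(cohort$pedicle_clamping)),
    major_morbidity = chi_of(major),
    operative_time = anova_of(cohort$operative_time_min),
    clamping_total = anova_of(ifelse(cohort$pedicle_clamping,
                                     cohort$clamping_total_min, NA_real_))
  )
}
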