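#' Difficulty-score points for each risk factor
#'
#' Applies the validated difficulty scoring system of Halls et al. for
#' laparoscopic liver resection.  Points: neoadjuvant chemotherapy received 1;
#' previous open liver resection 5; malignant lesion 2; lesion size < 3 cm 0,
#' 3-5 cm 2, > 5 cm 3 (sizes of exactly 3 or 5 cm fall in the middle
#' category); resection minor 0, technically major 2, anatomically major 4.
#' The total ranges 0-15 and maps onto four difficulty levels.
#'
#' @param cohort An `llr_cohort` or data.frame with the five risk-factor
#'   columns.
#' @return A data.frame with one row per record: `points_chemotherapy`,
#'   `points_prior_resection`, `points_lesion_type`, `points_lesion_size`,
#'   `points_resection_class`, `total`, `level` and the predicted IOC band
#'   bounds `band_lower`, `band_upper`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 3, seed = 1))
#' score_components(coh)
#' @export
score_components <- function(cohort) {
  needed <- c("neoadjuvant_chemotherapy", "previous_open_liver_resection",
              "lesion_type", "lesion_size_cm", "resection_class")
  if (!all(needed %in% names(cohort))) {
    stop("cohort must contain columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!all(cohort$lesion_type %in% LESION_TYPES)) {
    stop("field 'lesion_type': invalid value", call. = FALSE)
  }
  if (!all(cohort$resection_class %in% RESECTION_CLASSES)) {
    stop("field 'resection_class': invalid value", call. = FALSE)
  }
  size <- cohort$lesion_size_cm
  if (any(is.na(size) | size < 0)) {
    stop("field 'lesion_size_cm': must be non-negative and present", call. = FALSE)
  }
  out <- data.frame(
    points_chemotherapy = ifelse(as.logical(cohort$neoadjuvant_chemotherapy), 1L, 0L),
    points_prior_resection = ifelse(as.logical(cohort$previous_open_liver_resection), 5L, 0L),
    points_lesion_type = ifelse(cohort$lesion_type == "malignant", 2L, 0L),
    points_lesion_size = ifelse(size < 3, 0L, ifelse(size <= 5, 2L, 3L)),
    points_resection_class = c(minor = 0L, technically_major = 2L,
                               anatomically_major = 4L)[cohort$resection_class],
    stringsAsFactors = FALSE
  )
  out$total <- out$points_chemotherapy + out$points_prior_resection +
    out$points_lesion_type + out$points_lesion_size + out$points_resection_class
  out$level <- difficulty_level(out$total)
  band <- predicted_ioc_band(out$level)
  out$band_lower <- band$lower
  out$band_upper <- band$upper
  rownames(out) <- NULL
  out
}

#' Difficulty level for a total score
#'
#' Totals 0-2, 3-5, 6-9 and 10-15 map to low, moderate, high and extremely
#' high difficulty, respectively (both endpoints of each range inclusive).
#'
#' @param total Integer vector of totals in 0-15.
#' @return Factor with levels `low < moderate < high < extremely_high`.
#' @examples
#' difficulty_level(c(0, 2, 3, 9, 10, 15))
#' @export
difficulty_level <- function(total) {
  if (any(is.na(total)) || any(total < 0 | total > 15) ||
      any(total != round(total))) {
    stop("`total` must be integers in 0..15", call. = FALSE)
  }
  lv <- cut(total, breaks = c(-0.5, 2.5, 5.5, 9.5, 15.5),
            labels = DIFFICULTY_LEVELS)
  factor(as.character(lv), levels = DIFFICULTY_LEVELS, ordered = TRUE)
}

#' Predicted IOC probability band for a difficulty level
#'
#' The scoring system attaches a predicted probability band of intraoperative
#' complications to each level: < 10% (low), 10-20% (moderate), 20-50%
#' (high), > 50% (extremely high).  Adjacent bands share their printed
#' endpoints; the convention used here is \[0, 0.10) / \[0.10, 0.20\] /
#' (0.20, 0.50\] / (0.50, 1\].  The bands are reporting metadata only and
#' enter no computation.
#'
#' @param level Difficulty level(s) (character or factor).
#' @return data.frame with columns `level`, `lower`, `upper`, and the interval
#'   label `band`.
#' @export
predicted_ioc_band <- function(level) {
  level <- as.character(level)
  if (!all(level %in% DIFFICULTY_LEVELS)) {
    stop("invalid difficulty level", call. = FALSE)
  }
  lower <- c(low = 0, moderate = 0.10, high = 0.20, extremely_high = 0.50)[level]
  upper <- c(low = 0.10, moderate = 0.20, high = 0.50, extremely_high = 1)[level]
  band <- c(low = "<10%", moderate = "10-20%", high = "20-50%",
            extremely_high = ">50%")[level]
  data.frame(level = level, lower = unname(lower), upper = unname(upper),
             band = unname(band), stringsAsFactors = FALSE)
}

#' Score a cohort
#'
#' Appends `total_score`, `difficulty_level` and `predicted_band` columns.
#'
#' @inheritParams score_components
#' @return The cohort with the three scoring columns appended.
#' @export
score_cohort <- function(cohort) {
  sc <- score_components(cohort)
  cohort$total_score <- sc$total
  cohort$difficulty_level <- sc$level
  cohort$predicted_band <- predicted_ioc_band(sc$level)$band
  cohort
}
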