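#' @keywords internal
"_PACKAGE"

# Canonical factor levels used throughout the package.
LESION_TYPES <- c("benign", "malignant")
RESECTION_CLASSES <- c("minor", "technically_major", "anatomically_major")
CLAVIEN_GRADES <- c("none", "1", "2", "3a", "3b", "4a", "4b", "5")
DIFFICULTY_LEVELS <- c("low", "moderate", "high", "extremely_high")

# Column order of the cohort CSV schema (bit-exact contract).
COHORT_COLUMNS <- c(
  "patient_id", "neoadjuvant_chemotherapy", "previous_open_liver_resection",
  "lesion_type", "lesion_size_cm", "resection_class", "blood_loss_ml",
  "converted", "surrounding_damage", "transfusion", "operative_time_min",
  "pedicle_clamping", "clamping_total_min", "clavien_dindo"
)

BOOL_COLUMNS <- c(
  "neoadjuvant_chemotherapy", "previous_open_liver_resection", "converted",
  "surrounding_damage", "transfusion", "pedicle_clamping"
)

#' IOC thresholds
#'
#' Cut-offs used to derive the composite intraoperative-complication (IOC)
#' endpoint.  The blood-loss component is strictly greater-than: a loss equal
#' to the cut-off is not an excessive-loss event.
#'
#' @param blood_loss_cutoff_ml Positive blood-loss cut-off in mL.  The default
#'   775 mL is the threshold of the validated difficulty scoring system.
#' @return An object of class `ioc_thresholds`.
#' @examples
#' ioc_thresholds()
#' ioc_thresholds(blood_loss_cutoff_ml = 500)
#' @export
ioc_thresholds <- function(blood_loss_cutoff_ml = 775) {
  if (!is.numeric(blood_loss_cutoff_ml) || length(blood_loss_cutoff_ml) != 1 ||
      is.na(blood_loss_cutoff_ml) || blood_loss_cutoff_ml <= 0) {
    stop("`blood_loss_cutoff_ml` must be a single positive number", call. = FALSE)
  }
  structure(list(blood_loss_cutoff_ml = as.numeric(blood_loss_cutoff_ml)),
            class = "ioc_thresholds")
}

#' @export
print.ioc_thresholds <- function(x, ...) {
  cat("IOC thresholds: blood loss >", x$blood_loss_cutoff_ml, "mL\n")
  invisible(x)
}

# Validate one cohort data.frame; `where` labels error messages (e.g. a file).
# Returns the data.frame with canonicalised column types.
validate_cohort_frame <- function(df, where = "cohort") {
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing mandatory column(s): %s", where,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[COHORT_COLUMNS]
  df$patient_id <- as.character(df$patient_id)
  if (anyNA(df$patient_id) || any(df$patient_id == "")) {
    stop(sprintf("%s: patient_id must be non-missing for every row", where),
         call. = FALSE)
  }
  if (anyDuplicated(df$patient_id)) {
    dup <- df$patient_id[duplicated(df$patient_id)][1]
    stop(sprintf("%s: duplicate patient_id '%s'", where, dup), call. = FALSE)
  }
  for (col in BOOL_COLUMNS) {
    v <- df[[col]]
    if (is.logical(v)) {
      ok <- !is.na(v)
    } else {
      v <- suppressWarnings(as.numeric(as.character(v)))
      ok <- !is.na(v) & v %in% c(0, 1)
      v <- v == 1
    }
    if (!all(ok)) {
      stop(sprintf("%s: row %d, field '%s': booleans must be 0/1 and never missing",
                   where, which(!ok)[1], col), call. = FALSE)
    }
    df[[col]] <- v
  }
  check_enum <- function(col, levels, allow_na = FALSE) {
    v <- as.character(df[[col]])
    bad <- !(v %in% levels) & !(allow_na & is.na(df[[col]]))
    if (any(bad)) {
      stop(sprintf("%s: row %d, field '%s': invalid value '%s' (allowed: %s)",
                   where, which(bad)[1], col, v[which(bad)[1]],
                   paste(levels, collapse = ", ")), call. = FALSE)
    }
    v
  }
  df$lesion_type <- check_enum("lesion_type", LESION_TYPES)
  df$resection_class <- check_enum("resection_class", RESECTION_CLASSES)
  df$clavien_dindo <- check_enum("clavien_dindo", CLAVIEN_GRADES, allow_na = TRUE)

  check_nonneg <- function(col, allow_na = FALSE, strict_pos = FALSE) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad_na <- is.na(v) & !(allow_na & is.na(df[[col]]))
    lim <- if (strict_pos) v <= 0 else v < 0
    bad <- bad_na | (!is.na(v) & lim)
    if (any(bad)) {
      stop(sprintf("%s: row %d, field '%s': must be a %s number",
                   where, which(bad)[1], col,
                   if (strict_pos) "positive" else "non-negative"), call. = FALSE)
    }
    v
  }
  df$lesion_size_cm <- check_nonneg("lesion_size_cm")
  df$blood_loss_ml <- check_nonneg("blood_loss_ml", allow_na = TRUE)
  df$operative_time_min <- check_nonneg("operative_time_min", allow_na = TRUE,
                                        strict_pos = TRUE)
  df$clamping_total_min <- check_nonneg("clamping_total_min")

  # clamping_total_min = 0  <=>  pedicle_clamping = FALSE
  mismatch <- (df$clamping_total_min == 0) != (!df$pedicle_clamping)
  if (any(mismatch)) {
    stop(sprintf(paste0("%s: row %d: clamping_total_min must be 0 exactly when ",
                        "pedicle_clamping is 0"), where, which(mismatch)[1]),
         call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Construct a cohort
#'
#' A cohort is a `data.frame` with one validated patient record per row and
#' the CSV schema columns (see [read_cohort()]), carrying `provenance`
#' (`"synthetic"` or `"file"`) and optionally the generator `seed` as
#' attributes.
#'
#' @param records A data.frame with the cohort schema columns.
#' @param provenance `"synthetic"` or `"file"`.
#' @param seed Optional integer seed recorded for synthetic cohorts.
#' @return An object of class `llr_cohort` (a data.frame).
#' @export
as_cohort <- function(records, provenance = c("file", "synthetic"), seed = NULL) {
  provenance <- match.arg(provenance)
  df <- validate_cohort_frame(as.data.frame(records, stringsAsFactors = FALSE))
  structure(df, class = c("llr_cohort", "data.frame"),
            provenance = provenance, seed = seed)
}

#' @export
print.llr_cohort <- function(x, ...) {
  cat(sprintf("LLR cohort: %d patients (provenance: %s%s)\n", nrow(x),
              attr(x, "provenance"),
              if (!is.null(attr(x, "seed"))) paste0(", seed ", attr(x, "seed")) else ""))
  NextMethod()
}

#' Derive the intraoperative-complication indicator
#'
#' IOC is the composite endpoint of the validated scoring system: excessive
#' blood loss (strictly above the cut-off, 775 mL by default), conversion to
#' an open approach, or unintentional damage to surrounding structures.
#' A missing blood loss contributes `FALSE` to the excessive-loss marker
#' (events are observed, not imputed); conversion and damage still count.
#'
#' @param cohort An `llr_cohort` or data.frame with columns `blood_loss_ml`,
#'   `converted` and `surrounding_damage`.
#' @param thresholds An [ioc_thresholds()] object.
#' @return Logical vector, one element per record.
#' @examples
#' coh <- generate_cohort(cohort_spec(n = 5, seed = 1))
#' derive_ioc(coh)
#' @export
derive_ioc <- function(cohort, thresholds = ioc_thresholds()) {
  stopifnot(inherits(thresholds, "ioc_thresholds"))
  needed <- c("blood_loss_ml", "converted", "surrounding_damage")
  if (!all(needed %in% names(cohort))) {
    stop("cohort must contain columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  loss <- cohort$blood_loss_ml
  if (any(!is.na(loss) & loss < 0)) {
    stop("field 'blood_loss_ml': negative values are invalid", call. = FALSE)
  }
  excessive <- !is.na(loss) & loss > thresholds$blood_loss_cutoff_ml
  excessive | as.logical(cohort$converted) | as.logical(cohort$surrounding_damage)
}

#' Is a Clavien-Dindo grade a major complication?
#'
#' Grades 3a-4b are major complications (invasive intervention or organ
#' support); grade 5 (death) is reported separately and is not counted here.
#'
#' @param grade Character vector of grades (`"none"`, `"1"`, ..., `"5"`); `NA`
#'   allowed.
#' @return Logical vector (`NA` where the grade is missing).
#' @export
clavien_major <- function(grade) {
  ifelse(is.na(grade), NA, grade %in% c("3a", "3b", "4a", "4b"))
}

#' Read a cohort CSV
#'
#' The CSV dialect is comma-separated UTF-8 with `.` decimal separator,
#' an empty cell for a missing value, and booleans serialised as 0/1.
#' Column names (exact): `patient_id`, `neoadjuvant_chemotherapy`,
#' `previous_open_liver_resection`, `lesion_type`, `lesion_size_cm`,
#' `resection_class`, `blood_loss_ml`, `converted`, `surrounding_damage`,
#' `transfusion`, `operative_time_min`, `pedicle_clamping`,
#' `clamping_total_min`, `clavien_dindo`.
#'
#' @param path Path to a CSV file with a header row.
#' @return An `llr_cohort` with `provenance = "file"`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = "")
  if (nrow(df) == 0) {
    df <- empty_cohort_frame()
  }
  as_cohort(df, provenance = "file")
}

empty_cohort_frame <- function() {
  df <- data.frame(
    patient_id = character(0), neoadjuvant_chemotherapy = logical(0),
    previous_open_liver_resection = logical(0), lesion_type = character(0),
    lesion_size_cm = numeric(0), resection_class = character(0),
    blood_loss_ml = numeric(0), converted = logical(0),
    surrounding_damage = logical(0), transfusion = logical(0),
    operative_time_min = numeric(0), pedicle_clamping = logical(0),
    clamping_total_min = numeric(0), clavien_dindo = character(0),
    stringsAsFactors = FALSE
  )
  df
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(x, p))` reproduces
#' `x` field-for-field, including the missing-value pattern.
#'
#' @param cohort An `llr_cohort` (or validatable data.frame).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- validate_cohort_frame(as.data.frame(cohort, stringsAsFactors = FALSE))
  for (col in BOOL_COLUMNS) df[[col]] <- as.integer(df[[col]])
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
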