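# Quality control of ABP recordings and regression imputation of missing
# subject-level attributes.
#
# Editing rules follow standard ambulatory-monitoring practice: readings with
# physiologically impossible pressures are discarded, and subjects whose
# 24-hour recording retains fewer than 40 valid readings are excluded as
# technically inadequate.

#' Default reading-level plausibility bounds (mmHg)
#'
#' A systolic reading above 260 or below 70, or a diastolic reading above 150
#' or below 40, is treated as a device artifact. Bounds are strict: a reading
#' exactly at a bound is kept.
#' @return Named list with `sbp_lo`, `sbp_hi`, `dbp_lo`, `dbp_hi`.
#' @export
bp_outlier_bounds <- function() {
  list(sbp_lo = 70, sbp_hi = 260, dbp_lo = 40, dbp_hi = 150)
}

#' Discard physiologically impossible readings
#'
#' A reading is dropped when EITHER channel is out of range: systolic and
#' diastolic come from the same cuff inflation, so an impossible value on one
#' channel taints the whole reading. Surviving readings keep their original
#' times and order; the function is idempotent.
#'
#' @param rec an [abp_recording()].
#' @param bounds plausibility bounds, see [bp_outlier_bounds()].
#' @return The filtered recording, with attribute `n_discarded`.
#' @examples
#' rec <- abp_recording("S1", c(0, 22), c(265, 120), c(80, 75))
#' filter_readings(rec)   # first reading discarded
#' @export
filter_readings <- function(rec, bounds = bp_outlier_bounds()) {
  r <- rec$readings
  keep <- r$sbp <= bounds$sbp_hi & r$sbp >= bounds$sbp_lo &
    r$dbp <= bounds$dbp_hi & r$dbp >= bounds$dbp_lo
  keep[is.na(keep)] <- FALSE
  out <- rec
  out$readings <- r[keep, , drop = FALSE]
  rownames(out$readings) <- NULL
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Keep/exclude decision for a filtered recording
#'
#' Subjects with fewer than `min_readings` valid readings over the recording
#' period are excluded (strict `<`: exactly 40 readings is kept under the
#' default).
#'
#' @param rec a recording that has already passed [filter_readings()].
#' @param min_readings minimum valid reading count (default 40).
#' @return `TRUE` to keep, `FALSE` to exclude.
#' @export
qc_recording <- function(rec, min_readings = 40) {
  n_readings(rec) >= min_readings
}

#' Impute a missing attribute from sex and age
#'
#' Missing cells of `attribute` are replaced by the prediction of an ordinary
#' least squares fit of the attribute on sex (0/1) and age over the complete
#' cases. Observed cells are never modified, and no stochastic residual is
#' added, so imputation is deterministic.
#'
#' @param subjects subject data frame with complete `sex` and `age`.
#' @param attribute column name to impute (default `"cholesterol"`).
#' @param warn_min warn when fewer complete cases than this are available.
#' @return The data frame with missing cells filled; attribute `n_imputed`
#'   records how many cells were imputed.
#' @export
impute_missing <- function(subjects, attribute = "cholesterol",
                           warn_min = 10) {
  if (!attribute %in% names(subjects))
    stop_remed("no column '%s' to impute", attribute)
  if (anyNA(subjects$sex) || anyNA(subjects$age))
    stop_remed("sex and age must be complete to impute '%s'", attribute)
  y <- subjects[[attribute]]
  miss <- is.na(y)
  if (!any(miss)) {
    attr(subjects, "n_imputed") <- 0L
    return(subjects)
  }
  cc <- which(!miss)
  if (length(cc) < 4)  # predictors (sex, age) + 2
    stop_remed("too few complete cases (%d) to impute '%s'",
               length(cc), attribute, class = "remedbp_imputation_error")
  if (length(cc) < warn_min)
    warning(sprintf("only %d complete cases for '%s' imputation",
                    length(cc), attribute))
  fit <- stats::lm(y ~ sex + age, data = cbind(subjects, y = y)[cc, ])
  pred <- stats::predict(fit, newdata = subjects[miss, , drop = FALSE])
  subjects[[attribute]][miss] <- as.numeric(pred)
  attr(subjects, "n_imputed") <- sum(miss)
  subjects
}

#' Preprocess a cohort: filter readings, exclude short recordings, impute
#'
#' Applies [filter_readings()] to every recording, drops subjects failing
#' [qc_recording()] from both the recording list and the subject table, and
#' imputes missing cholesterol via [impute_missing()].
#'
#' @param recordings named list of [abp_recording()].
#' @param subjects subject data frame (see [read_bp_subjects()]).
#' @param min_readings minimum valid readings per subject.
#' @param bounds reading plausibility bounds.
#' @param impute attribute name to impute, or `NULL` to skip imputation.
#' @return List with `recordings`, `subjects`, and `qc` (a `qc_report`).
#' @export
preprocess_cohort <- function(recordings, subjects, min_readings = 40,
                              bounds = bp_outlier_bounds(),
                              impute = "cholesterol") {
  filt <- lapply(recordings, filter_readings, bounds = bounds)
  discarded <- sum(vapply(filt, function(r) attr(r, "n_discarded"), numeric(1)))
  keep <- vapply(filt, qc_recording, logical(1), min_readings = min_readings)
  kept_ids <- names(filt)[keep]
  subjects <- subjects[subjects$id %in% kept_ids, , drop = FALSE]
  rownames(subjects) <- NULL
  n_imputed <- 0L
  if (!is.null(impute) && impute %in% names(subjects)) {
    subjects <- impute_missing(subjects, impute)
    n_imputed <- attr(subjects, "n_imputed")
  }
  qc <- qc_report(
    subjects_in = length(recordings),
    subjects_excluded_low_readings = sum(!keep),
    readings_discarded_outlier = as.integer(discarded),
    missing_imputed = as.integer(n_imputed),
    n_attributes = max(1L, ncol(subjects) - 2L)  # excluding id and outcome
  )
  list(recordings = filt[keep], subjects = subjects, qc = qc)
}

#' Quality-control report
#'
#' Bookkeeping for a preprocessing pass. The missing-value percentage is
#' reported under two denominators because cohort descriptions are ambiguous
#' about it: all cells of the subjects-by-attributes grid
#' (`missing_pct_cells`) and the single imputed column (`missing_pct_column`).
#'
#' @param subjects_in number of subjects before QC.
#' @param subjects_excluded_low_readings subjects dropped for short recordings.
#' @param readings_discarded_outlier readings dropped as out of range.
#' @param missing_imputed imputed cell count.
#' @param n_attributes attribute count used for the all-cells denominator.
#' @return Object of class `qc_report`.
#' @export
qc_report <- function(subjects_in, subjects_excluded_low_readings = 0L,
                      readings_discarded_outlier = 0L, missing_imputed = 0L,
                      n_attributes = 7L) {
  counts <- c(subjects_in, subjects_excluded_low_readings,
              readings_discarded_outlier, missing_imputed)
  if (any(counts < 0)) stop_remed("qc_report counts must be non-negative")
  subjects_out <- subjects_in - subjects_excluded_low_readings
  structure(list(
    subjects_in = as.integer(subjects_in),
    subjects_excluded_low_readings = as.integer(subjects_excluded_low_readings),
    subjects_out = as.integer(subjects_out),
    readings_discarded_outlier = as.integer(readings_discarded_outlier),
    missing_imputed = as.integer(missing_imputed),
    missing_pct_cells = round(100 * missing_imputed /
                                (subjects_out * n_attributes), 1),
    missing_pct_column = round(100 * missing_imputed / subjects_out, 1)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("ABP preprocessing report\n")
  cat(sprintf("  subjects: %d in, %d excluded (<min readings), %d retained\n",
              x$subjects_in, x$subjects_excluded_low_readings, x$subjects_out))
  cat(sprintf("  readings discarded as outliers: %d\n",
              x$readings_discarded_outlier))
  cat(sprintf("  missing cells imputed: %d (%.1f%% of cells, %.1f%% of column)\n",
              x$missing_imputed, x$missing_pct_cells, x$missing_pct_column))
  invisible(x)
}
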