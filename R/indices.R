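# 24-hour blood pressure level and variability indices.
#
# Both indices weight by the elapsed time between successive valid readings,
# so irregular sampling (and gaps left by discarded artifacts) is handled
# without interpolation:
#
#   ARV = sum_k w_k |x_k - x_{k-1}| / sum_k w_k,   w_k = t_k - t_{k-1}
#   WBP = sum_k w_k (x_k + x_{k-1})/2 / sum_k w_k  (trapezoidal mean)
#
# Both are invariant to shifting or uniformly rescaling the time axis.

check_series <- function(values, times, what) {
  n <- length(values)
  if (length(times) != n)
    stop_remed("%s: values and times must have equal length", what)
  if (n < 2)
    stop_remed("%s is undefined for fewer than 2 readings", what,
               class = "remedbp_undefined_index")
  if (any(diff(times) <= 0))
    stop_remed("%s: times must be strictly increasing", what)
  if (anyNA(values) || anyNA(times))
    stop_remed("%s: missing values in series", what)
  invisible(n)
}

#' Average Real Variability (ARV)
#'
#' Time-interval-weighted mean of absolute differences between successive
#' readings of one channel. Unlike the within-subject standard deviation, ARV
#' measures reading-to-reading fluctuation and is sensitive to the ordering
#' of the series.
#'
#' @param values BP values (mmHg) of one channel, in time order.
#' @param times reading times in minutes, strictly increasing.
#' @return ARV in mmHg; `0` iff the series is constant.
#' @examples
#' compute_arv(c(120, 130, 110), c(0, 30, 60))   # 15
#' compute_arv(c(120, 130, 110), c(0, 10, 40))   # 17.5
#' @export
compute_arv <- function(values, times) {
  check_series(values, times, "ARV")
  w <- diff(times)
  sum(w * abs(diff(values))) / sum(w)
}

#' Time-weighted 24-hour BP level (WBP)
#'
#' Weighted mean of the readings using inter-reading intervals as weights.
#' Each interval contributes the midpoint of its two bounding readings
#' (trapezoidal convention, the standard time-weighted 24-h average). The
#' asymmetric alternative — weighting reading k by its preceding interval
#' alone — is available via `convention = "right"`.
#'
#' @param values BP values (mmHg) of one channel, in time order.
#' @param times reading times in minutes, strictly increasing.
#' @param convention `"trapezoid"` (default) or `"right"`.
#' @return WBP in mmHg, always within the range of `values`.
#' @examples
#' compute_wbp(c(120, 130, 110), c(0, 30, 60))   # 122.5
#' @export
compute_wbp <- function(values, times, convention = c("trapezoid", "right")) {
  convention <- match.arg(convention)
  n <- check_series(values, times, "WBP")
  w <- diff(times)
  if (convention == "trapezoid") {
    mid <- (values[-1] + values[-n]) / 2
    sum(w * mid) / sum(w)
  } else {
    sum(w * values[-1]) / sum(w)
  }
}

#' Per-channel 24-hour indices for one recording
#'
#' Computes systolic and diastolic WBP and ARV (plus the time-weighted heart
#' rate mean when heart rate was recorded).
#'
#' @param rec an [abp_recording()] that has passed quality control.
#' @param convention WBP weighting convention, see [compute_wbp()].
#' @return Named list: `sbp_wbp`, `sbp_arv`, `dbp_wbp`, `dbp_arv`, `hr_mean`
#'   (`NA` if absent), `n_readings`.
#' @export
compute_indices <- function(rec, convention = "trapezoid") {
  r <- rec$readings
  if (nrow(r) == 0) stop_remed("empty recording for '%s'", rec$subject_id)
  list(
    sbp_wbp = compute_wbp(r$sbp, r$time_min, convention),
    sbp_arv = compute_arv(r$sbp, r$time_min),
    dbp_wbp = compute_wbp(r$dbp, r$time_min, convention),
    dbp_arv = compute_arv(r$dbp, r$time_min),
    hr_mean = if (!is.null(r$hr)) compute_wbp(r$hr, r$time_min, convention)
              else NA_real_,
    n_readings = nrow(r)
  )
}

#' Index table for a list of recordings
#'
#' @param recordings named list of [abp_recording()].
#' @param convention WBP weighting convention.
#' @return data frame with columns `id, sbp_wbp, sbp_arv, dbp_wbp, dbp_arv,
#'   hr_mean, n_readings`, one row per recording.
#' @export
compute_indices_table <- function(recordings, convention = "trapezoid") {
  rows <- lapply(recordings, function(rec) {
    ix <- compute_indices(rec, convention)
    data.frame(id = rec$subject_id, ix, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Merge indices with subject attributes into the minable feature table
#'
#' Joins the per-subject index table onto the subject table and keeps only
#' continuous, changeable attributes: BMI, cholesterol, heart rate, and
#' systolic/diastolic WBP and ARV. Sex and age are kept out of the feature
#' set (non-changeable) but remain available for imputation upstream.
#'
#' @param indices output of [compute_indices_table()].
#' @param subjects subject data frame with `id` and `outcome`.
#' @return data frame with `id`, the seven feature columns, and `outcome`.
#' @export
build_feature_table <- function(indices, subjects) {
  merged <- merge(subjects, indices, by = "id", sort = FALSE)
  feats <- c("bmi", "cholesterol", "hr_mean", "sbp_wbp", "dbp_wbp",
             "sbp_arv", "dbp_arv")
  feats <- intersect(feats, names(merged))
  out <- merged[, c("id", feats, "outcome"), drop = FALSE]
  rownames(out) <- NULL
  out
}
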