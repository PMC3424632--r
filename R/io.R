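# Reading-level and subject-level data model and CSV I/O.
#
# On-disk dialect is header-ed delimited text:
#   readings: subject_id,time_min,sbp,dbp[,hr]
#   subjects: id,sex,age,bmi,cholesterol,outcome

#' Construct an ambulatory blood pressure recording
#'
#' An `abp_recording` holds one subject's ordered 24-h (or longer) sequence of
#' cuff readings: time in minutes since recording start, systolic and
#' diastolic pressure in mmHg, and optionally heart rate in beats/min.
#'
#' @param subject_id subject identifier (coerced to character).
#' @param time_min numeric vector, minutes since recording start; must be
#'   non-negative and strictly increasing after sorting, with no duplicates.
#' @param sbp,dbp numeric vectors of systolic / diastolic pressure (mmHg).
#' @param hr optional numeric vector of heart rate (beats/min).
#' @param max_duration_min maximum allowed recording span in minutes
#'   (default 26 h); ambulatory monitors are worn for about one day.
#' @return An object of class `abp_recording`: a list with `subject_id` and a
#'   data frame `readings` sorted by time.
#' @examples
#' rec <- abp_recording("S1", c(0, 30, 60), c(120, 130, 110), c(80, 85, 70))
#' rec
#' @export
abp_recording <- function(subject_id, time_min, sbp, dbp, hr = NULL,
                          max_duration_min = 26 * 60) {
  n <- length(time_min)
  if (length(sbp) != n || length(dbp) != n)
    stop_remed("time_min, sbp and dbp must have equal length")
  if (!is.null(hr) && length(hr) != n)
    stop_remed("hr must match the number of readings")
  if (any(time_min < 0, na.rm = TRUE))
    stop_remed("time_min must be non-negative (minutes since recording start)")
  if (anyDuplicated(time_min))
    stop_remed("subject '%s' has duplicate reading timestamps", subject_id,
               class = "remedbp_duplicate_time")
  o <- order(time_min)
  readings <- data.frame(
    time_min = as.numeric(time_min[o]),
    sbp = as.numeric(sbp[o]),
    dbp = as.numeric(dbp[o])
  )
  if (!is.null(hr)) readings$hr <- as.numeric(hr[o])
  if (n > 0 && diff(range(readings$time_min)) > max_duration_min)
    stop_remed("recording span for '%s' exceeds %.0f minutes",
               subject_id, max_duration_min)
  structure(list(subject_id = as.character(subject_id), readings = readings),
            class = "abp_recording")
}

#' @export
print.abp_recording <- function(x, ...) {
  r <- x$readings
  cat(sprintf("<abp_recording> subject %s: %d readings", x$subject_id, nrow(r)))
  if (nrow(r) > 1)
    cat(sprintf(" over %.1f h", diff(range(r$time_min)) / 60))
  cat("\n")
  invisible(x)
}

#' Number of readings in a recording
#' @param rec an [abp_recording()].
#' @return integer count.
#' @export
n_readings <- function(rec) nrow(rec$readings)

#' Read a reading-level CSV into a list of recordings
#'
#' Expects columns `subject_id,time_min,sbp,dbp` and optionally `hr`.
#' Rows may appear in any order; within each subject they are sorted by time.
#' Duplicate (subject, time) pairs are an error: monitors emit distinct
#' timestamps, so duplicates indicate a corrupted export.
#'
#' @param path CSV file path.
#' @param delim field delimiter (default comma).
#' @param max_duration_min maximum recording span, see [abp_recording()].
#' @return Named list of `abp_recording`, in order of first appearance.
#' @export
read_bp_readings <- function(path, delim = ",", max_duration_min = 26 * 60) {
  if (!file.exists(path)) stop_remed("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("subject_id", "time_min", "sbp", "dbp")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_remed("readings file %s is missing column '%s'", path, miss[1],
               class = "remedbp_format_error")
  for (col in c("time_min", "sbp", "dbp", intersect("hr", names(df))))
    df[[col]] <- assert_numeric_col(df, col, file = path)
  ids <- unique(df$subject_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$subject_id == id, , drop = FALSE]
    abp_recording(id, sub$time_min, sub$sbp, sub$dbp,
                  hr = if ("hr" %in% names(sub)) sub$hr else NULL,
                  max_duration_min = max_duration_min)
  })
  names(out) <- ids
  out
}

#' Write recordings to a reading-level CSV
#'
#' Inverse of [read_bp_readings()]: `read_bp_readings(write_bp_readings(x))`
#' reproduces `x` up to numeric round-trip.
#'
#' @param recs list of `abp_recording`.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_bp_readings <- function(recs, path, delim = ",") {
  if (inherits(recs, "abp_recording")) recs <- list(recs)
  rows <- lapply(recs, function(rec) {
    r <- rec$readings
    cbind(data.frame(subject_id = rep(rec$subject_id, nrow(r))), r)
  })
  df <- do.call(rbind, rows)
  if (is.null(df$hr)) df$hr <- NULL
  utils::write.table(df, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the subject-level feature table
#'
#' Expects columns `id,sex,age,bmi,cholesterol,outcome`. Blank cholesterol
#' cells become `NA` (to be imputed later); `outcome` must be 0/1
#' (1 = cardiovascular death during follow-up).
#'
#' @param path CSV file path.
#' @param delim field delimiter.
#' @return data frame with one row per subject, `id` as character.
#' @export
read_bp_subjects <- function(path, delim = ",") {
  if (!file.exists(path)) stop_remed("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  need <- c("id", "sex", "age", "bmi", "cholesterol", "outcome")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_remed("subjects file %s is missing column '%s'", path, miss[1],
               class = "remedbp_format_error")
  for (col in setdiff(names(df), "id"))
    df[[col]] <- assert_numeric_col(df, col, file = path)
  if (any(!df$outcome %in% c(0, 1)))
    stop_remed("outcome must be 0/1; found '%s'",
               df$outcome[which(!df$outcome %in% c(0, 1))[1]],
               class = "remedbp_validation_error")
  if (any(df$age <= 0, na.rm = TRUE))
    stop_remed("age must be positive", class = "remedbp_validation_error")
  df$id <- as.character(df$id)
  df
}

#' Write the subject-level feature table
#' @param subjects data frame as returned by [read_bp_subjects()].
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_bp_subjects <- function(subjects, path, delim = ",") {
  utils::write.table(subjects, path, sep = delim, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}
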