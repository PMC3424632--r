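# Shared in-code fixtures.

# Tiny two-subject reading table written to a temp CSV.
write_tiny_readings <- function(path = tempfile(fileext = ".csv")) {
  df <- data.frame(
    subject_id = c("A", "A", "A", "B", "B"),
    time_min = c(0, 30, 60, 0, 22),
    sbp = c(120, 130, 110, 140, 150),
    dbp = c(80, 85, 70, 90, 95),
    hr = c(70, 72, 68, 80, 82)
  )
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

write_tiny_subjects <- function(path = tempfile(fileext = ".csv"),
                                outcome = c(1, 0)) {
  df <- data.frame(id = c("A", "B"), sex = c(0, 1), age = c(70, 65),
                   bmi = c(27, 30), cholesterol = c(5.2, NA),
                   outcome = outcome)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  path
}

# Random small feature table for property tests: one or two attributes,
# imbalanced labels guaranteed to contain both classes.
random_small_table <- function(n, n_attr = 1) {
  repeat {
    y <- stats::rbinom(n, 1, 0.35)
    if (length(unique(y)) == 2) break
  }
  tb <- data.frame(outcome = y)
  for (j in seq_len(n_attr))
    tb[[paste0("x", j)]] <- round(stats::runif(n, 0, 10), 1)
  tb
}
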