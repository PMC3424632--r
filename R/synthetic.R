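# Seeded synthetic-cohort generator.
#
# The generator states a world with the shape of a ~551-subject ambulatory
# monitoring cohort followed for fatal cardiovascular outcomes: roughly 1:9
# positive:negative imbalance, about 65 readings per 24-h recording, and an
# outcome planted by a conjunctive threshold rule on the systolic indices
# (ARV >= 9.6 mmHg and WBP >= 137 mmHg) plus label noise. Subject-level
# marginals default to the published cohort description (age 67.1 +/- 8 y,
# BMI 27.1 +/- 5.6, cholesterol 5.5 +/- 1.3 mmol/L, systolic WBP
# 133.8 +/- 16.6 mmHg, heart rate 73.7 +/- 9.8 bpm); the systolic ARV
# marginal (9.8 +/- 3 mmHg) is a typical 24-h value from the ambulatory
# monitoring literature. Covariates are outcome-independent by default, a
# built-in negative control for the attribute screen.
#
# Within-subject dynamics are AR(1): ARV measures successive differences, so
# it is sensitive to autocorrelation, and white noise would reduce it to a
# multiple of the within-subject SD.

#' Configuration for the synthetic cohort generator
#'
#' @param n_subjects cohort size (default 551).
#' @param prevalence positive-class fraction (default 61/551).
#' @param readings_mean mean readings per 24-h recording (default 65).
#' @param readings_jitter SD of the per-subject reading count (default 5).
#' @param sampling_interval_min base sampling interval in minutes; `NULL`
#'   (default) derives it as `1440 / readings_mean` (about 22 min).
#' @param time_jitter fraction of the interval used as uniform timing jitter
#'   (default 0.3; keeps times strictly increasing).
#' @param true_rule planted outcome rule, a [remed_rule()] over feature
#'   names; default `sbp_arv >= 9.6 and sbp_wbp >= 137`.
#' @param label_noise probability an outcome label is flipped (default 0.05).
#' @param rule_margin half-width of an exclusion zone around each planted
#'   threshold (default 0: classes touch at the boundary). With a positive
#'   margin the classes are separated by `2 * rule_margin` in feature space,
#'   so a noiseless cohort is perfectly and stably separable.
#' @param between_subject_sd SD of the systolic WBP marginal (default 16.6
#'   mmHg).
#' @param within_subject_sd extra white measurement noise per reading, mmHg
#'   (default 0: the AR process already carries the calibrated
#'   within-subject variability).
#' @param arv_mean,arv_sd systolic ARV marginal (default 9.8 +/- 3 mmHg).
#' @param ar_phi lag-1 autocorrelation of the within-subject AR(1) process
#'   (default 0.5 at the ~22-min sampling step).
#' @param seed RNG seed (required).
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 551, prevalence = 61 / 551,
                       readings_mean = 65, readings_jitter = 5,
                       sampling_interval_min = NULL, time_jitter = 0.3,
                       true_rule = remed_rule(c("sbp_arv", "sbp_wbp"),
                                              c(">=", ">="), c(9.6, 137)),
                       label_noise = 0.05, rule_margin = 0,
                       between_subject_sd = 16.6,
                       within_subject_sd = 0, arv_mean = 9.8, arv_sd = 3,
                       ar_phi = 0.5, seed) {
  if (missing(seed)) stop_remed("sim_config requires a seed")
  if (prevalence < 0 || prevalence > 1)
    stop_remed("prevalence must be in [0, 1]")
  if (label_noise < 0 || label_noise > 0.5)
    stop_remed("label_noise must be in [0, 0.5]")
  if (readings_mean < 2) stop_remed("readings_mean must be at least 2")
  if (ar_phi < 0 || ar_phi >= 1) stop_remed("ar_phi must be in [0, 1)")
  if (time_jitter < 0 || time_jitter >= 0.5)
    stop_remed("time_jitter must be in [0, 0.5) to keep times increasing")
  if (!inherits(true_rule, "remed_rule"))
    stop_remed("true_rule must be a remed_rule")
  # an explicit sampling interval fixes the implied mean reading count
  if (!is.null(sampling_interval_min)) readings_mean <- 1440 / sampling_interval_min
  structure(list(
    n_subjects = as.integer(n_subjects), prevalence = prevalence,
    readings_mean = readings_mean, readings_jitter = readings_jitter,
    sampling_interval_min = sampling_interval_min %||% 1440 / readings_mean,
    time_jitter = time_jitter, true_rule = true_rule,
    label_noise = label_noise, rule_margin = rule_margin,
    between_subject_sd = between_subject_sd,
    within_subject_sd = within_subject_sd, arv_mean = arv_mean,
    arv_sd = arv_sd, ar_phi = ar_phi, seed = as.integer(seed)
  ), class = "sim_config")
}

# AR(1) innovation scale such that the expected mean absolute successive
# difference of the stationary process equals `arv_target`:
#   Var(x_k - x_{k-1}) = 2 sigma^2 (1 - phi),  E|d| = sqrt(2/pi) sd(d)
# => sigma^2 = pi arv_target^2 / (4 (1 - phi)).
ar1_scale_for_arv <- function(arv_target, phi) {
  sqrt(pi * arv_target^2 / (4 * (1 - phi)))
}

sim_ar1 <- function(n, sigma_stat, phi) {
  if (sigma_stat == 0) return(numeric(n))
  a <- numeric(n)
  a[1] <- stats::rnorm(1, 0, sigma_stat)
  eps <- stats::rnorm(n - 1, 0, sigma_stat * sqrt(1 - phi^2))
  for (k in seq_len(n - 1)) a[k + 1] <- phi * a[k] + eps[k]
  a
}

#' Simulate one 24-hour ABP recording
#'
#' Reading times sit on a jittered ~22-minute grid over 24 h. The systolic
#' series is a stationary AR(1) walk around `subject_mean_sbp` whose
#' innovation scale is calibrated in closed form so that the expected ARV of
#' the series equals `subject_arv_target`. Diastolic is an independent AR(1)
#' around `dbp_mean` calibrated to `dbp_arv_target`; heart rate is white
#' noise around `hr_mean`. All channels are clamped just inside the
#' plausibility bounds.
#'
#' @param subject_mean_sbp target time-weighted systolic level, mmHg.
#' @param subject_arv_target target systolic ARV, mmHg (must be attainable:
#'   positive and far smaller than the 190-mmHg systolic dynamic range).
#' @param cfg a [sim_config()].
#' @param seed RNG seed for this recording.
#' @param subject_id identifier for the resulting recording.
#' @param dbp_mean,dbp_arv_target,hr_mean diastolic and heart-rate targets.
#' @return An [abp_recording()].
#' @export
simulate_recording <- function(subject_mean_sbp, subject_arv_target, cfg,
                               seed, subject_id = "S1", dbp_mean = 76,
                               dbp_arv_target = 7, hr_mean = 74) {
  if (subject_mean_sbp <= 0 || subject_arv_target < 0)
    stop_remed("targets must be positive")
  if (subject_arv_target > 190 / 4)
    stop_remed("arv target %.1f mmHg exceeds the attainable dynamic range",
               subject_arv_target)
  with_local_seed(seed, {
    n <- max(2L, as.integer(round(
      stats::rnorm(1, cfg$readings_mean, cfg$readings_jitter))))
    interval <- 1440 / n  # the device spreads its readings over ~24 h
    jit <- stats::runif(n, -cfg$time_jitter, cfg$time_jitter) * interval
    times <- (seq_len(n) - 1) * interval + jit
    times <- times - min(times)  # start at (or just after) zero
    phi <- cfg$ar_phi
    sbp <- subject_mean_sbp +
      sim_ar1(n, ar1_scale_for_arv(subject_arv_target, phi), phi)
    dbp <- dbp_mean + sim_ar1(n, ar1_scale_for_arv(dbp_arv_target, phi), phi)
    if (cfg$within_subject_sd > 0) {
      sbp <- sbp + stats::rnorm(n, 0, cfg$within_subject_sd)
      dbp <- dbp + stats::rnorm(n, 0, cfg$within_subject_sd)
    }
    b <- bp_outlier_bounds()
    sbp <- pmin(pmax(sbp, b$sbp_lo + 0.5), b$sbp_hi - 0.5)
    dbp <- pmin(pmax(dbp, b$dbp_lo + 0.5), b$dbp_hi - 0.5)
    dbp <- pmin(dbp, sbp - 10)  # systolic exceeds diastolic physiologically
    hr <- hr_mean + stats::rnorm(n, 0, 3)
    abp_recording(subject_id, times, sbp, dbp, hr = hr)
  })
}

# Shift a rule's thresholds by +/- margin in the direction that tightens
# (for sampling positives) or loosens (for sampling negatives) the rule.
shift_rule <- function(rule, margin) {
  sgn <- ifelse(rule$conditions$relation == ">=", 1, -1)
  tight <- rule; tight$conditions$threshold <- rule$conditions$threshold + sgn * margin
  loose <- rule; loose$conditions$threshold <- rule$conditions$threshold - sgn * margin
  list(tight = tight, loose = loose)
}

# Draw feature vectors from the outcome-independent marginals, then keep the
# ones whose planted-rule prediction matches `target` (rejection sampling).
# Positives must satisfy the rule tightened by `rule_margin`; negatives must
# fail it loosened by `rule_margin`.
draw_conditional_features <- function(n, target, cfg) {
  if (n == 0) return(NULL)
  shifted <- shift_rule(cfg$true_rule, cfg$rule_margin %||% 0)
  gate <- if (target == 1L) shifted$tight else shifted$loose
  draw <- function(m) {
    df <- data.frame(
      bmi = stats::rnorm(m, 27.1, 5.6),
      cholesterol = stats::rnorm(m, 5.5, 1.3),
      hr_mean = stats::rnorm(m, 73.7, 9.8),
      sbp_wbp = stats::rnorm(m, 133.8, cfg$between_subject_sd),
      dbp_wbp = stats::rnorm(m, 76.1, 10),
      sbp_arv = pmax(stats::rnorm(m, cfg$arv_mean, cfg$arv_sd), 0.5),
      dbp_arv = pmax(stats::rnorm(m, 7, 2), 0.5)
    )
    df$bmi <- pmax(df$bmi, 14)
    df$cholesterol <- pmax(df$cholesterol, 2)
    df$hr_mean <- pmax(df$hr_mean, 35)
    df
  }
  out <- NULL
  for (i in 1:1000) {
    cand <- draw(max(4L * n, 64L))
    keep <- predict(gate, cand) == target
    out <- rbind(out, cand[keep, , drop = FALSE])
    if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
  }
  stop_remed("rejection sampling failed: planted rule class %d too rare",
             target)
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject true feature vectors conditional on a planted outcome
#' (positives satisfy every condition of `cfg$true_rule`, negatives fail at
#' least one), flips each observed label with probability `cfg$label_noise`,
#' draws demographics from outcome-independent marginals, and (optionally)
#' realises one 24-h recording per subject whose indices are calibrated to
#' the subject's true WBP/ARV.
#'
#' @param cfg a [sim_config()].
#' @param readings simulate reading-level recordings too (default TRUE);
#'   with `FALSE` only subject-level truth and features are generated, which
#'   is much faster for large cohorts.
#' @return Object of class `synthetic_cohort`: list with `recordings` (or
#'   `NULL`), `subjects` (id, sex, age, bmi, cholesterol, outcome), `truth`
#'   (per-subject noiseless label and true feature values), and `config`.
#'   Per-subject recording seeds are derived by hashing subject ids, so the
#'   cohort is reproducible under reordering.
#' @export
simulate_cohort <- function(cfg, readings = TRUE) {
  n <- cfg$n_subjects
  if (cfg$prevalence * n < 1)
    warning("prevalence * n_subjects < 1: expect no positive subjects")
  ids <- sprintf("S%05d", seq_len(n))
  cohort <- with_local_seed(cfg$seed, {
    true_label <- stats::rbinom(n, 1, cfg$prevalence)
    pos <- draw_conditional_features(sum(true_label == 1), 1L, cfg)
    neg <- draw_conditional_features(sum(true_label == 0), 0L, cfg)
    feat_df <- data.frame(matrix(NA_real_, n, ncol(neg %||% pos)))
    names(feat_df) <- names(neg %||% pos)
    if (!is.null(pos)) feat_df[true_label == 1, ] <- pos
    if (!is.null(neg)) feat_df[true_label == 0, ] <- neg
    outcome <- as.integer(xor(true_label == 1,
                              stats::rbinom(n, 1, cfg$label_noise) == 1))
    subjects <- data.frame(
      id = ids,
      sex = stats::rbinom(n, 1, 0.321),  # 1 = male
      age = pmax(stats::rnorm(n, 67.1, 8), 55),
      bmi = feat_df$bmi,
      cholesterol = feat_df$cholesterol,
      outcome = outcome,
      stringsAsFactors = FALSE
    )
    truth <- cbind(data.frame(id = ids, true_label = true_label,
                              stringsAsFactors = FALSE), feat_df)
    list(subjects = subjects, truth = truth)
  })
  recs <- NULL
  if (readings) {
    recs <- lapply(seq_len(n), function(i) {
      tr <- cohort$truth[i, ]
      simulate_recording(tr$sbp_wbp, tr$sbp_arv, cfg,
                         seed = derive_seed(cfg$seed, ids[i]),
                         subject_id = ids[i], dbp_mean = tr$dbp_wbp,
                         dbp_arv_target = tr$dbp_arv, hr_mean = tr$hr_mean)
    })
    names(recs) <- ids
  }
  structure(list(recordings = recs, subjects = cohort$subjects,
                 truth = cohort$truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, %d positive labels (%s readings)\n",
              nrow(x$subjects), sum(x$subjects$outcome == 1),
              if (is.null(x$recordings)) "no" else "with"))
  cat("planted rule:", format(x$config$true_rule), "\n")
  invisible(x)
}

#' Feature table from a cohort's true (noiseless) feature values
#'
#' Pairs each subject's true index values with the observed (possibly
#' noise-flipped) outcome — the minable table a perfect measurement pipeline
#' would produce.
#'
#' @param cohort a [simulate_cohort()] result.
#' @return data frame with `id`, the seven feature columns, and `outcome`.
#' @export
true_feature_table <- function(cohort) {
  feats <- c("bmi", "cholesterol", "hr_mean", "sbp_wbp", "dbp_wbp",
             "sbp_arv", "dbp_arv")
  out <- cbind(cohort$truth[, c("id", feats)],
               outcome = cohort$subjects$outcome)
  rownames(out) <- NULL
  out
}

#' Corrupt a cohort with measurement artifacts
#'
#' Replaces a random fraction of readings with out-of-range values (the kind
#' the outlier filter must remove) and blanks a random fraction of
#' cholesterol cells (the kind imputation must fill). Ground-truth lists of
#' corrupted items are attached so tests can verify that preprocessing
#' removes exactly the corrupted data.
#'
#' @param cohort a [simulate_cohort()] result with recordings.
#' @param outlier_rate per-reading corruption probability (default 0.02).
#' @param missing_chol_rate per-subject probability of a blank cholesterol
#'   cell (default 0.011).
#' @param seed RNG seed.
#' @return The corrupted cohort, with `corrupted_readings` (data frame of
#'   subject id and time) and `blanked_cholesterol` (ids) recorded.
#' @export
inject_artifacts <- function(cohort, outlier_rate = 0.02,
                             missing_chol_rate = 0.011, seed) {
  if (outlier_rate < 0 || outlier_rate > 1 ||
      missing_chol_rate < 0 || missing_chol_rate > 1)
    stop_remed("rates must be in [0, 1]")
  if (is.null(cohort$recordings) && outlier_rate > 0)
    stop_remed("cohort has no recordings to corrupt")
  with_local_seed(seed, {
    corrupted <- NULL
    if (outlier_rate > 0) {
      b <- bp_outlier_bounds()
      cohort$recordings <- lapply(cohort$recordings, function(rec) {
        r <- rec$readings
        hit <- which(stats::runif(nrow(r)) < outlier_rate)
        for (i in hit) {
          if (stats::runif(1) < 0.5) {
            r$sbp[i] <- if (stats::runif(1) < 0.5)
              stats::runif(1, b$sbp_hi + 1, b$sbp_hi + 60)
            else stats::runif(1, 20, b$sbp_lo - 1)
          } else {
            r$dbp[i] <- if (stats::runif(1) < 0.5)
              stats::runif(1, b$dbp_hi + 1, b$dbp_hi + 40)
            else stats::runif(1, 10, b$dbp_lo - 1)
          }
        }
        if (length(hit))
          corrupted <<- rbind(corrupted, data.frame(
            id = rec$subject_id, time_min = r$time_min[hit]))
        rec$readings <- r
        rec
      })
    }
    blank <- which(stats::runif(nrow(cohort$subjects)) < missing_chol_rate)
    cohort$subjects$cholesterol[blank] <- NA_real_
    cohort$corrupted_readings <- corrupted
    cohort$blanked_cholesterol <- cohort$subjects$id[blank]
  })
  cohort
}
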