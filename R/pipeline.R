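# Pipeline wiring: validated run configuration, staged execution with one
# machine-readable report, and a small CLI front end.

run_config_defaults <- function() {
  list(
    seed = NULL,                      # mandatory, no default
    out_dir = NULL,
    verbose = TRUE,
    readings = NULL,                  # path to readings CSV
    subjects = NULL,                  # path to subjects CSV
    simulate = list(enabled = FALSE, n_subjects = 551,
                    prevalence = 61 / 551, label_noise = 0.05,
                    outlier_rate = 0.02, missing_chol_rate = 0.011),
    preprocess = list(min_readings = 40, sbp_lo = 70, sbp_hi = 260,
                      dbp_lo = 40, dbp_hi = 150),
    indices = list(convention = "trapezoid"),
    fit = list(alpha = 0.01, epsilon = 0.01, joint = TRUE, force = NULL),
    evaluate = list(k = 10, baseline = TRUE)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop_remed("unknown config key '%s%s'", path, unknown[1])
  for (key in names(user)) {
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      paste0(path, key, "."))
    } else {
      defaults[key] <- list(user[[key]])  # keeps explicit NULLs in place
    }
  }
  defaults
}

#' Build a validated pipeline run configuration
#'
#' Defaults follow the published analysis settings: 40-reading QC floor,
#' 70-260 / 40-150 mmHg plausibility ranges, screening alpha 0.01, 10-fold
#' cross-validation. Unknown keys are rejected rather than ignored, and the
#' seed is mandatory.
#'
#' @param config named list of overrides, or a path to a YAML file of them.
#' @param ... further overrides applied after `config`.
#' @return Object of class `run_config` (a validated nested list).
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(run_config_defaults(), config)
  cfg <- merge_config(cfg, list(...))
  if (is.null(cfg$seed)) stop_remed("config must set a seed")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

say <- function(cfg, fmt, ...) {
  if (isTRUE(cfg$verbose)) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (optional) cohort simulation with artifact injection,
#' reading/subject ingestion, quality control and imputation, index
#' computation, attribute screening and rule induction, and cross-validated
#' evaluation with the naive Bayes baseline. Emits a single report holding
#' the QC counts, the screening table, the induced rule (as a
#' machine-readable condition list and as the `If ... then 1 Else 0`
#' string), the pooled confusion matrix and its metrics.
#'
#' @param cfg a [run_config()].
#' @return Invisible `remed_report` list; also written as `report.json` (and
#'   the effective config as `config.yaml`) under `cfg$out_dir` when set.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  if (isTRUE(cfg$simulate$enabled)) {
    say(cfg, "simulating cohort (n = %d, seed = %d)",
        cfg$simulate$n_subjects, cfg$seed)
    sim <- sim_config(n_subjects = cfg$simulate$n_subjects,
                      prevalence = cfg$simulate$prevalence,
                      label_noise = cfg$simulate$label_noise,
                      seed = cfg$seed)
    cohort <- simulate_cohort(sim)
    cohort <- inject_artifacts(cohort, cfg$simulate$outlier_rate,
                               cfg$simulate$missing_chol_rate,
                               seed = cfg$seed + 1L)
    recordings <- cohort$recordings
    subjects <- cohort$subjects
  } else {
    if (is.null(cfg$readings) || is.null(cfg$subjects))
      stop_remed("config must point at 'readings' and 'subjects' CSVs (or enable simulate)")
    say(cfg, "reading %s and %s", cfg$readings, cfg$subjects)
    recordings <- read_bp_readings(cfg$readings)
    subjects <- read_bp_subjects(cfg$subjects)
  }

  pp <- cfg$preprocess
  bounds <- list(sbp_lo = pp$sbp_lo, sbp_hi = pp$sbp_hi,
                 dbp_lo = pp$dbp_lo, dbp_hi = pp$dbp_hi)
  clean <- preprocess_cohort(recordings, subjects,
                             min_readings = pp$min_readings, bounds = bounds)
  say(cfg, "QC: %d/%d subjects kept, %d outlier readings discarded, %d cells imputed",
      clean$qc$subjects_out, clean$qc$subjects_in,
      clean$qc$readings_discarded_outlier, clean$qc$missing_imputed)

  idx <- compute_indices_table(clean$recordings, cfg$indices$convention)
  features <- build_feature_table(idx, clean$subjects)

  screen <- suppressWarnings(select_attributes(features, cfg$fit$alpha))
  say(cfg, "screening: %d of %d attributes selected at alpha = %g",
      sum(screen$selected), nrow(screen), cfg$fit$alpha)
  rule <- tryCatch(
    build_rule(features, screen, joint = cfg$fit$joint,
               epsilon = cfg$fit$epsilon, force = cfg$fit$force),
    remedbp_empty_selection = function(e) NULL)
  if (!is.null(rule)) say(cfg, "rule: %s", format(rule))

  cv <- cross_validate(features, k = cfg$evaluate$k, seed = cfg$seed,
                       fit_config = cfg$fit)
  nb <- if (isTRUE(cfg$evaluate$baseline))
    naive_bayes_baseline(features, k = cfg$evaluate$k, seed = cfg$seed)

  report <- list(
    seed = cfg$seed,
    qc = unclass(clean$qc),
    screening = as.data.frame(screen),
    rule = if (!is.null(rule)) list(conditions = rule$conditions,
                                    text = format(rule)),
    cv = list(confusion = unclass(cv$cm), metrics = cv$metrics),
    naive_bayes = if (!is.null(nb)) list(confusion = unclass(nb$cm),
                                         metrics = nb$metrics)
  )
  class(report) <- "remed_report"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    yaml::write_yaml(unclass(cfg), file.path(cfg$out_dir, "config.yaml"))
  }
  invisible(report)
}

#' @export
print.remed_report <- function(x, ...) {
  cat("remedbp pipeline report (seed", x$seed, ")\n")
  if (!is.null(x$rule)) cat("rule:", x$rule$text, "\n")
  m <- x$cv$metrics
  cat(sprintf("cross-validated: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              m$sensitivity, m$specificity, m$accuracy))
  if (!is.null(x$naive_bayes)) {
    m <- x$naive_bayes$metrics
    cat(sprintf("naive Bayes:     sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
                m$sensitivity, m$specificity, m$accuracy))
  }
  invisible(x)
}

#' Command-line entry point
#'
#' `Rscript -e 'remedbp::remed_cli()' pipeline --config run.yaml --seed 42
#' --out results/` runs the staged pipeline; the `simulate` subcommand
#' writes a synthetic cohort's readings/subjects CSVs plus `truth.json`.
#'
#' @param args character vector of CLI arguments (defaults to the process
#'   arguments).
#' @return exit status, invisibly.
#' @export
remed_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: remed_cli <simulate|pipeline> [--config F.yaml] [--seed N] [--out DIR] [--readings F] [--subjects F]"
  if (!length(args)) { message(usage); return(invisible(1L)) }
  sub <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest)) {
    if (!startsWith(rest[1], "--") || length(rest) < 2)
      stop_remed("malformed arguments; %s", usage)
    opts[[substring(rest[1], 3)]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  base <- if (!is.null(opts$config)) yaml::read_yaml(opts$config) else list()
  if (!is.null(opts$seed)) base$seed <- as.integer(opts$seed)
  if (!is.null(opts$out)) base$out_dir <- opts$out
  if (!is.null(opts$readings)) base$readings <- opts$readings
  if (!is.null(opts$subjects)) base$subjects <- opts$subjects
  if (sub == "simulate") {
    cfg <- run_config(base)
    out <- cfg$out_dir %||% "."
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    cohort <- simulate_cohort(sim_config(
      n_subjects = cfg$simulate$n_subjects,
      prevalence = cfg$simulate$prevalence,
      label_noise = cfg$simulate$label_noise, seed = cfg$seed))
    cohort <- inject_artifacts(cohort, cfg$simulate$outlier_rate,
                               cfg$simulate$missing_chol_rate,
                               seed = cfg$seed + 1L)
    write_bp_readings(cohort$recordings, file.path(out, "readings.csv"))
    write_bp_subjects(cohort$subjects, file.path(out, "subjects.csv"))
    jsonlite::write_json(cohort$truth, file.path(out, "truth.json"),
                         digits = NA)
    message("wrote readings.csv, subjects.csv, truth.json to ", out)
  } else if (sub == "pipeline") {
    rep <- run_pipeline(run_config(base))
    print(rep)
  } else {
    stop_remed("unknown subcommand '%s'; %s", sub, usage)
  }
  invisible(0L)
}
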