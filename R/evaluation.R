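# Confusion-matrix metrics, imbalance-preserving k-fold cross-validation,
# and a fold-paired Gaussian naive Bayes baseline.

#' Confusion matrix from predicted and actual labels
#'
#' @param predicted,actual equal-length 0/1 vectors.
#' @return Object of class `confusion_matrix` with counts `tp, fn, fp, tn`.
#' @export
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop_remed("predicted and actual must have equal length")
  if (!all(predicted %in% c(0, 1)) || !all(actual %in% c(0, 1)))
    stop_remed("labels must be 0/1")
  confusion_matrix(tp = sum(predicted == 1 & actual == 1),
                   fn = sum(predicted == 0 & actual == 1),
                   fp = sum(predicted == 1 & actual == 0),
                   tn = sum(predicted == 0 & actual == 0))
}

#' Construct a confusion matrix from counts
#' @param tp,fn,fp,tn non-negative counts (true/false positives/negatives).
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop_remed("confusion counts must be non-negative")
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Add two confusion matrices
#' @param e1,e2 `confusion_matrix` objects.
#' @export
"+.confusion_matrix" <- function(e1, e2) {
  confusion_matrix(e1$tp + e2$tp, e1$fn + e2$fn, e1$fp + e2$fp, e1$tn + e2$tn)
}

#' Sensitivity, specificity and accuracy of a confusion matrix
#'
#' All three are percentages rounded to one decimal:
#' sensitivity = tp/(tp+fn), specificity = tn/(fp+tn),
#' accuracy = (tp+tn)/total.
#'
#' @param cm a `confusion_matrix`; both actual classes must be non-empty.
#' @return Named list `sensitivity`, `specificity`, `accuracy` (percent).
#' @examples
#' cm_metrics(confusion_matrix(tp = 22, fn = 39, fp = 98, tn = 392))
#' @export
cm_metrics <- function(cm) {
  pos <- cm$tp + cm$fn
  neg <- cm$fp + cm$tn
  if (pos == 0 || neg == 0)
    stop_remed("metrics undefined: an actual class is empty",
               class = "remedbp_undefined_metric")
  list(sensitivity = round(100 * cm$tp / pos, 1),
       specificity = round(100 * cm$tn / neg, 1),
       accuracy = round(100 * (cm$tp + cm$tn) / (pos + neg), 1))
}

#' Stratified fold assignment preserving class imbalance
#'
#' Rows are shuffled under `seed` and dealt to folds class by class in one
#' continuous round-robin, so per-fold positive counts differ by at most one
#' and per-fold sizes differ by at most one — each fold keeps approximately
#' the full table's imbalance ratio.
#'
#' @param labels 0/1 outcome vector (one entry per row).
#' @param k number of folds (default 10).
#' @param seed RNG seed (required, for reproducible plans).
#' @return Object of class `fold_plan`: list with `k`, `seed`, and
#'   `assignments` (integer fold id per row).
#' @export
stratified_kfold <- function(labels, k = 10, seed) {
  n <- length(labels)
  if (k < 2) stop_remed("k must be at least 2")
  if (k > n) stop_remed("k = %d exceeds the number of rows (%d)", k, n)
  if (missing(seed)) stop_remed("a seed is required for a reproducible plan")
  n_pos <- sum(labels == 1)
  if (n_pos < k)
    warning(sprintf("only %d positives for %d folds; some folds get none",
                    n_pos, k))
  assignments <- integer(n)
  with_local_seed(seed, {
    pos <- sample(which(labels == 1))
    neg <- sample(which(labels == 0))
    deal <- c(pos, neg)  # continuous deal keeps totals balanced too
    assignments[deal] <- rep_len(seq_len(k), n)
  })
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignments = assignments), class = "fold_plan")
}

# Default rule-fitting step used inside cross_validate: screen then build.
# If nothing is significant on a training split and nothing is forced, the
# fold's rule degenerates to the always-negative prediction (with a warning
# from select_attributes).
fit_remed_step <- function(train, fit_config) {
  alpha <- fit_config$alpha %||% 0.01
  epsilon <- fit_config$epsilon %||% 0.01
  joint <- fit_config$joint %||% TRUE
  force <- fit_config$force %||% NULL
  screen <- suppressWarnings(select_attributes(train, alpha = alpha))
  if (!any(screen$selected) && is.null(force)) return(NULL)
  build_rule(train, screen, joint = joint, epsilon = epsilon, force = force)
}

#' Cross-validated evaluation of the threshold rule
#'
#' For each fold the rule is fitted on the other `k - 1` folds and applied to
#' the held-out fold; the `k` held-out confusion matrices are pooled by
#' summation, so the pooled matrix totals the full table (like a single
#' confusion matrix over the whole cohort). The rule refitted on all rows is
#' reported alongside.
#'
#' @param table feature table with `outcome` (and optionally `id`).
#' @param k folds (default 10).
#' @param seed RNG seed for the fold plan.
#' @param fit_config list of fitting options: `alpha`, `epsilon`, `joint`,
#'   `force` (see [build_rule()]).
#' @return Object of class `remed_cv`: list with `cm` (pooled
#'   `confusion_matrix`), `metrics`, `fold_rules`, `full_rule`, `plan`.
#' @export
cross_validate <- function(table, k = 10, seed, fit_config = list()) {
  plan <- stratified_kfold(table$outcome, k = k, seed = seed)
  pooled <- confusion_matrix(0, 0, 0, 0)
  fold_rules <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- plan$assignments == f
    train <- table[!test_idx, , drop = FALSE]
    test <- table[test_idx, , drop = FALSE]
    if (!any(test$outcome == 1))
      warning(sprintf("fold %d holds no positives; scored anyway", f))
    rule <- fit_remed_step(train, fit_config)
    pred <- if (is.null(rule)) rep(0L, nrow(test)) else predict(rule, test)
    pooled <- pooled + confusion(pred, test$outcome)
    fold_rules[[f]] <- rule
  }
  full_rule <- fit_remed_step(table, fit_config)
  structure(list(cm = pooled, metrics = cm_metrics(pooled),
                 fold_rules = fold_rules, full_rule = full_rule, plan = plan),
            class = "remed_cv")
}

#' @export
print.remed_cv <- function(x, ...) {
  cat("Pooled cross-validated confusion matrix:\n")
  print(x$cm)
  m <- x$metrics
  cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              m$sensitivity, m$specificity, m$accuracy))
  if (!is.null(x$full_rule)) cat("All-data rule:", format(x$full_rule), "\n")
  invisible(x)
}

# Gaussian naive Bayes fitted on train, applied to test. Implemented
# directly (it is a page of arithmetic) so the comparison can share the
# rule's fold plan exactly.
nb_fit_predict <- function(train, test, var_floor = 1e-9) {
  feats <- setdiff(names(train), c("id", "outcome"))
  feats <- feats[vapply(train[feats], is.numeric, logical(1))]
  prior <- c(`0` = mean(train$outcome == 0), `1` = mean(train$outcome == 1))
  score <- matrix(0, nrow(test), 2, dimnames = list(NULL, c("0", "1")))
  for (cl in c("0", "1")) {
    rows <- train$outcome == as.integer(cl)
    lp <- log(prior[[cl]])
    for (ft in feats) {
      mu <- mean(train[[ft]][rows])
      s2 <- stats::var(train[[ft]][rows])
      if (!is.finite(s2) || s2 < 1e-9) {
        warning(sprintf("class %s has ~zero variance in '%s'; floored", cl, ft))
        s2 <- max(s2, var_floor, na.rm = TRUE)
      }
      score[, cl] <- score[, cl] +
        stats::dnorm(test[[ft]], mu, sqrt(s2), log = TRUE)
    }
    score[, cl] <- score[, cl] + lp
  }
  as.integer(score[, "1"] > score[, "0"])
}

#' Gaussian naive Bayes baseline under the same fold plan
#'
#' Class-conditional independent Gaussians with training-fold priors and
#' maximum-posterior decisions, cross-validated with exactly the fold plan a
#' rule fit would use for the same `(k, seed)` — so the comparison is paired.
#'
#' @param table feature table with `outcome`.
#' @param k folds.
#' @param seed RNG seed for the fold plan.
#' @return list with pooled `cm` and `metrics`.
#' @export
naive_bayes_baseline <- function(table, k = 10, seed) {
  plan <- stratified_kfold(table$outcome, k = k, seed = seed)
  pooled <- confusion_matrix(0, 0, 0, 0)
  for (f in seq_len(k)) {
    test_idx <- plan$assignments == f
    pred <- nb_fit_predict(table[!test_idx, , drop = FALSE],
                           table[test_idx, , drop = FALSE])
    pooled <- pooled + confusion(pred, table$outcome[test_idx])
  }
  list(cm = pooled, metrics = cm_metrics(pooled), plan = plan)
}
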