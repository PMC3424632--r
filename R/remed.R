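# Symbolic threshold-rule induction for imbalanced binary outcomes.
#
# The classifier is a single conjunctive rule
#
#   If  x_1 <rel_1> p_1  and ... and  x_m <rel_m> p_m  then 1  Else 0
#
# with one condition per attribute that survives univariate logistic
# screening. <rel> is ">=" when the attribute is positively associated with
# the positive class, "<=" otherwise, and relations are inclusive.
#
# Partition (threshold) search is sensitivity-first: starting from the
# positive-class mean, the threshold walks through candidate cut-points
# (midpoints of consecutive distinct values) in the direction that can only
# increase sensitivity, and the walk is stopped as soon as overall accuracy
# falls more than `epsilon` below the best accuracy seen on the walk. The
# returned threshold is the accepted candidate with the best accuracy
# (ties: higher sensitivity, then nearest the start). This concrete
# procedure is this package's documented stand-in for the original
# algorithm's unpublished partition search; see the methods vignette.

#' Univariate logistic screening of one attribute
#'
#' Fits `logit P(y = 1) = b0 + b1 x` by maximum likelihood (IRLS, tolerance
#' 1e-8, at most 100 iterations) and tests the slope with a two-sided Wald
#' test. Under (near-)separation or non-convergence the Wald statistic is
#' unreliable, so the p-value falls back to the likelihood-ratio test and the
#' association is flagged.
#'
#' @param values numeric attribute column.
#' @param labels 0/1 outcome column.
#' @param attribute attribute name carried into the result.
#' @param alpha significance level used for the `selected` flag.
#' @return Object of class `remed_association`: a list with `attribute`,
#'   `coefficient` (log-odds per unit), `odds_ratio`, `p_value`, `test`
#'   (`"wald"` or `"lrt"`), `direction` (`">="` iff the slope is positive),
#'   `selected`, and `degenerate` (zero-variance attribute, never selected).
#' @export
fit_univariate_logistic <- function(values, labels, attribute = "x",
                                    alpha = 0.01) {
  if (length(values) != length(labels))
    stop_remed("values and labels must have equal length")
  if (anyNA(values) || anyNA(labels))
    stop_remed("screening requires complete data; impute first")
  if (!all(labels %in% c(0, 1)))
    stop_remed("labels must be 0/1")
  if (length(unique(labels)) < 2)
    stop_remed("both outcome classes must be present to screen '%s'",
               attribute)
  out <- list(attribute = attribute, n = length(values), alpha = alpha)
  if (stats::var(values) == 0) {
    out <- c(out, list(coefficient = NA_real_, odds_ratio = NA_real_,
                       p_value = NA_real_, test = "none", direction = NA,
                       selected = FALSE, degenerate = TRUE))
    return(structure(out, class = "remed_association"))
  }
  fit <- suppressWarnings(stats::glm(
    labels ~ values, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)
  ))
  b1 <- stats::coef(fit)[["values"]]
  se <- sqrt(diag(stats::vcov(fit)))[["values"]]
  wald_p <- 2 * stats::pnorm(-abs(b1 / se))
  # (near-)separation: fitted probabilities pinned at 0/1 collapse the Wald
  # statistic (Hauck-Donner effect), so fall back to the likelihood ratio
  unstable <- !fit$converged || fit$boundary || !is.finite(wald_p) ||
    se > 100 || any(fit$fitted.values > 1 - 1e-7) ||
    any(fit$fitted.values < 1e-7)
  if (unstable) {
    p <- stats::pchisq(fit$null.deviance - fit$deviance, df = 1,
                       lower.tail = FALSE)
    test <- "lrt"
  } else {
    p <- wald_p
    test <- "wald"
  }
  out <- c(out, list(
    coefficient = unname(b1), intercept = unname(stats::coef(fit)[1]),
    odds_ratio = unname(exp(b1)), p_value = unname(p), test = test,
    direction = if (b1 > 0) ">=" else "<=",
    selected = is.finite(p) && p < alpha, degenerate = FALSE
  ))
  structure(out, class = "remed_association")
}

#' @export
print.remed_association <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("%s: degenerate (zero variance), skipped\n", x$attribute))
  } else {
    cat(sprintf("%s: OR=%.3f per unit, P=%.4g (%s)%s\n", x$attribute,
                x$odds_ratio, x$p_value, x$test,
                if (x$selected) " *selected*" else ""))
  }
  invisible(x)
}

#' Screen every attribute of a feature table
#'
#' Runs [fit_univariate_logistic()] independently on each attribute column
#' and selects those with `P < alpha`. Zero-variance attributes are skipped.
#'
#' @param table feature table: data frame with an `outcome` column (0/1),
#'   optionally an `id` column, and numeric attribute columns.
#' @param alpha significance level (default 0.01).
#' @param exclude column names never screened (besides `id`/`outcome`).
#' @return Object of class `remed_screen`: a data frame with one row per
#'   screened attribute, ordered by ascending p-value, with columns
#'   `attribute, coefficient, odds_ratio, p_value, test, direction, selected`.
#'   If nothing is selected a warning is emitted; callers may then force
#'   attributes into [build_rule()].
#' @export
select_attributes <- function(table, alpha = 0.01, exclude = character()) {
  labels <- table$outcome
  if (is.null(labels)) stop_remed("feature table must have an 'outcome' column")
  if (length(unique(labels)) < 2)
    stop_remed("outcome is constant; cannot screen attributes")
  cols <- setdiff(names(table), c("id", "outcome", exclude))
  cols <- cols[vapply(table[cols], is.numeric, logical(1))]
  if (!length(cols)) stop_remed("no numeric attribute columns to screen")
  assoc <- lapply(cols, function(cl)
    fit_univariate_logistic(table[[cl]], labels, attribute = cl,
                            alpha = alpha))
  keep <- !vapply(assoc, `[[`, logical(1), "degenerate")
  assoc <- assoc[keep]
  if (!length(assoc)) stop_remed("all attributes are degenerate")
  df <- do.call(rbind, lapply(assoc, function(a)
    data.frame(attribute = a$attribute, coefficient = a$coefficient,
               odds_ratio = a$odds_ratio, p_value = a$p_value, test = a$test,
               direction = a$direction, selected = a$selected,
               stringsAsFactors = FALSE)))
  df <- df[order(df$p_value), , drop = FALSE]
  rownames(df) <- NULL
  if (!any(df$selected))
    warning(sprintf("no attribute significant at alpha = %g", alpha))
  structure(df, class = c("remed_screen", "data.frame"), alpha = alpha)
}

#' Initial partition: the positive-class mean
#'
#' The threshold walk starts at the attribute's mean over positive-class
#' rows: every refinement step from there can only increase sensitivity.
#'
#' @param values attribute column.
#' @param labels 0/1 outcome column.
#' @param direction `">="` or `"<="` (unused by the mean start, kept for
#'   interface symmetry with [refine_partition()]).
#' @return numeric starting threshold.
#' @export
initial_partition <- function(values, labels, direction = ">=") {
  if (!any(labels == 1)) stop_remed("no positive rows: no initial partition")
  mean(values[labels == 1])
}

# Confusion counts along all suffix thresholds of a ">=" condition.
# xm/ym are the attribute and label restricted to rows where every OTHER
# rule condition already holds; rows failing those conditions are predicted
# negative regardless, contributing fn_fixed/tn_fixed.
# Returns candidates in walk order (decreasing threshold, i.e. increasing
# sensitivity), each with tp/fp/fn/tn of the full rule.
scan_ge <- function(xm, ym, fn_fixed, tn_fixed) {
  v <- sort(unique(xm))
  m <- length(v)
  # suffix counts: rows with x >= v[i], via per-value tallies and reverse cumsum
  idx <- match(xm, v)
  posv <- rev(cumsum(rev(tabulate(idx[ym == 1], nbins = m))))
  negv <- rev(cumsum(rev(tabulate(idx[ym == 0], nbins = m))))
  # candidate i (i = m..2): midpoint below v[i]; candidate 1: v[1] itself
  cand <- c(if (m > 1) (v[-1] + v[-m]) / 2, v[1])
  idx <- c(if (m > 1) seq(2, m), 1L)
  o <- order(cand, decreasing = TRUE)
  data.frame(threshold = cand[o], tp = posv[idx][o], fp = negv[idx][o],
             fn = sum(ym == 1) - posv[idx][o] + fn_fixed,
             tn = sum(ym == 0) - negv[idx][o] + tn_fixed)
}

cm_at_threshold <- function(xm, ym, threshold, fn_fixed, tn_fixed) {
  pred <- xm >= threshold
  data.frame(threshold = threshold,
             tp = sum(ym == 1 & pred), fp = sum(ym == 0 & pred),
             fn = sum(ym == 1 & !pred) + fn_fixed,
             tn = sum(ym == 0 & !pred) + tn_fixed)
}

#' Refine a partition threshold, sensitivity first
#'
#' Starting from `start`, the threshold moves through candidate cut-points
#' (midpoints of consecutive distinct values, plus the extreme value so the
#' all-positive prediction is reachable) in the direction that increases
#' sensitivity — downwards for a `">="` condition, upwards for `"<="`. The
#' walk stops as soon as overall accuracy drops `epsilon` or more below the
#' best accuracy seen so far (including the start), so a bounded accuracy
#' sacrifice is allowed but unbounded drift is not. Among the accepted
#' candidates the one with the best accuracy is returned; ties are broken
#' towards higher sensitivity and then towards the candidate nearest the
#' start.
#'
#' @param values attribute column.
#' @param labels 0/1 outcome column.
#' @param direction `">="` or `"<="`.
#' @param start starting threshold, usually [initial_partition()].
#' @param epsilon accuracy slack per walk (fraction, default 0.01).
#' @param mask optional logical vector: rows where the rule's other
#'   conditions hold. Rows with `mask = FALSE` are predicted negative
#'   whatever the threshold, which is how conjunctions are refined jointly.
#' @return numeric threshold, with the rule's confusion counts at that
#'   threshold in attribute `"cm"` (a list `tp, fp, fn, tn`).
#' @examples
#' refine_partition(1:6, c(0, 0, 0, 1, 1, 1), ">=", start = 5)  # 3.5
#' @export
refine_partition <- function(values, labels, direction = ">=", start,
                             epsilon = 0.01, mask = NULL) {
  if (!is.finite(start)) stop_remed("start threshold must be finite")
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  flip <- identical(direction, "<=")
  x <- if (flip) -values else values
  s <- if (flip) -start else start
  xm <- x[mask]; ym <- labels[mask]
  fn_fixed <- sum(labels == 1 & !mask)
  tn_fixed <- sum(labels == 0 & !mask)
  n_total <- length(values)
  if (!length(xm)) {
    cm0 <- cm_at_threshold(numeric(0), numeric(0), s, fn_fixed, tn_fixed)
    res <- start
    attr(res, "cm") <- as.list(cm0[-1])
    return(res)
  }
  sc <- scan_ge(xm, ym, fn_fixed, tn_fixed)
  walk <- rbind(cm_at_threshold(xm, ym, s, fn_fixed, tn_fixed),
                sc[sc$threshold < s, , drop = FALSE])
  acc <- (walk$tp + walk$tn) / n_total
  sens <- ifelse(walk$tp + walk$fn > 0, walk$tp / (walk$tp + walk$fn), 0)
  # stop at the first candidate whose accuracy is epsilon or more below the
  # running best (best over start and all earlier accepted candidates)
  best_before <- cummax(c(acc[1], acc))[seq_along(acc)]
  viol <- which(best_before - acc >= epsilon - 1e-12)
  last <- if (length(viol)) viol[1] - 1L else nrow(walk)
  walk <- walk[seq_len(last), , drop = FALSE]
  acc <- acc[seq_len(last)]; sens <- sens[seq_len(last)]
  sel <- which(acc >= max(acc) - 1e-12)
  sel <- sel[sens[sel] >= max(sens[sel]) - 1e-12]
  pick <- sel[1]
  thr <- walk$threshold[pick]
  res <- if (flip) -thr else thr
  attr(res, "cm") <- list(tp = walk$tp[pick], fp = walk$fp[pick],
                          fn = walk$fn[pick], tn = walk$tn[pick])
  res
}

#' Construct a threshold rule explicitly
#'
#' @param attributes character vector of attribute names.
#' @param relations `">="` / `"<="` per attribute.
#' @param thresholds numeric thresholds (stored unrounded; printed to one
#'   decimal).
#' @return Object of class `remed_rule`.
#' @examples
#' remed_rule(c("sbp_arv", "sbp_wbp"), c(">=", ">="), c(9.6, 137))
#' @export
remed_rule <- function(attributes, relations, thresholds) {
  if (length(attributes) < 1) stop_remed("a rule needs at least one condition")
  if (anyDuplicated(attributes))
    stop_remed("one condition per attribute: duplicates not allowed")
  if (length(relations) != length(attributes) ||
      length(thresholds) != length(attributes))
    stop_remed("attributes, relations and thresholds must align")
  if (!all(relations %in% c(">=", "<=")))
    stop_remed("relations must be '>=' or '<='")
  if (any(!is.finite(thresholds))) stop_remed("thresholds must be finite")
  structure(list(conditions = data.frame(
    attribute = as.character(attributes), relation = as.character(relations),
    threshold = as.numeric(thresholds), stringsAsFactors = FALSE
  )), class = "remed_rule")
}

#' Induce a conjunctive threshold rule from screened attributes
#'
#' For each selected attribute (in ascending p-value order) the threshold is
#' initialised at the positive-class mean and refined marginally with
#' [refine_partition()]. With `joint = TRUE` (default) a greedy coordinate
#' pass then re-refines each threshold against the conjunction's confusion
#' matrix — rows failing the other conditions are fixed negatives — and the
#' passes repeat until no threshold changes. Loosening a condition can only
#' grow the predicted-positive set, so the joint pass never lowers the
#' conjunction's sensitivity below its value at entry.
#'
#' @param table feature table (see [select_attributes()]).
#' @param screen a `remed_screen` from [select_attributes()].
#' @param joint refine thresholds against the conjunction (default TRUE).
#' @param epsilon accuracy slack for each refinement walk.
#' @param force character vector of attributes to include even if not
#'   significant (mirrors adding well-known risk factors by hand).
#' @param max_passes safety cap on joint coordinate passes.
#' @return A `remed_rule`; attribute `"screen"` carries the screening table.
#' @export
build_rule <- function(table, screen, joint = TRUE, epsilon = 0.01,
                       force = NULL, max_passes = 25L) {
  use <- screen$attribute[screen$selected]
  if (!is.null(force)) {
    bad <- setdiff(force, screen$attribute)
    if (length(bad)) stop_remed("forced attribute '%s' was not screened", bad[1])
    use <- c(use, setdiff(force, use))
  }
  use <- screen$attribute[screen$attribute %in% use]  # ascending p order
  if (!length(use))
    stop_remed("no attribute selected and none forced; cannot build a rule",
               class = "remedbp_empty_selection")
  labels <- table$outcome
  rel <- stats::setNames(screen$direction[match(use, screen$attribute)], use)
  starts <- vapply(use, function(a)
    initial_partition(table[[a]], labels, rel[[a]]), numeric(1))
  thr <- vapply(use, function(a)
    as.numeric(refine_partition(table[[a]], labels, rel[[a]],
                                start = starts[[a]], epsilon = epsilon)),
    numeric(1))
  if (joint && length(use) > 1) {
    holds <- function(a, t) {
      if (rel[[a]] == ">=") table[[a]] >= t else table[[a]] <= t
    }
    for (pass in seq_len(max_passes)) {
      prev <- thr
      for (a in use) {
        others <- setdiff(use, a)
        mask <- Reduce(`&`, lapply(others, function(b) holds(b, thr[[b]])),
                       rep(TRUE, nrow(table)))
        thr[[a]] <- as.numeric(refine_partition(
          table[[a]], labels, rel[[a]], start = starts[[a]],
          epsilon = epsilon, mask = mask))
      }
      if (identical(thr, prev)) break
      if (pass == max_passes)
        warning("joint refinement did not stabilise; returning last pass")
    }
  }
  rule <- remed_rule(use, unname(rel[use]), unname(thr[use]))
  attr(rule, "screen") <- screen
  rule
}

#' Predict with a threshold rule
#'
#' A row is classed 1 iff every condition holds; relations are inclusive, so
#' a value exactly at the threshold satisfies its condition. Unrounded
#' thresholds are applied even though printing rounds to one decimal.
#'
#' @param object a `remed_rule`.
#' @param newdata data frame containing every attribute the rule names.
#' @param ... unused.
#' @return integer vector of 0/1 predictions.
#' @export
predict.remed_rule <- function(object, newdata, ...) {
  cond <- object$conditions
  miss <- setdiff(cond$attribute, names(newdata))
  if (length(miss))
    stop_remed("newdata lacks attribute '%s' required by the rule", miss[1])
  ok <- rep(TRUE, nrow(newdata))
  for (i in seq_len(nrow(cond))) {
    v <- newdata[[cond$attribute[i]]]
    ok <- ok & if (cond$relation[i] == ">=") v >= cond$threshold[i]
               else v <= cond$threshold[i]
  }
  as.integer(ok)
}

#' @export
format.remed_rule <- function(x, digits = 1, ...) {
  cond <- x$conditions
  body <- paste(sprintf("%s %s %s", cond$attribute, cond$relation,
                        formatC(round(cond$threshold, digits),
                                format = "fg")),
                collapse = " and ")
  sprintf("If %s then 1 Else 0", body)
}

#' @export
print.remed_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
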