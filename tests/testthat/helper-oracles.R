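# Independent oracles: deliberately naive re-implementations used to
# cross-check the package's optimized code paths. Nothing here calls the
# functions it is used to verify.

# --- logistic regression by hand-rolled Newton-Raphson (IRLS) ---------------
oracle_logistic <- function(x, y, tol = 1e-10, maxit = 200) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    score <- t(X) %*% (y - mu)
    info <- t(X) %*% (X * W)
    step <- solve(info, score)
    beta <- beta + as.vector(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.vector(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  info <- t(X) %*% (X * (mu * (1 - mu)))
  se <- sqrt(diag(solve(info)))
  z <- unname(beta[2] / se[2])
  list(b0 = unname(beta[1]), b1 = unname(beta[2]), se_b1 = unname(se[2]),
       p_wald = 2 * stats::pnorm(-abs(z)))
}

# --- confusion counting by explicit loops -----------------------------------
oracle_confusion <- function(pred, actual) {
  tp <- fn <- fp <- tn <- 0
  for (i in seq_along(pred)) {
    if (actual[i] == 1) {
      if (pred[i] == 1) tp <- tp + 1 else fn <- fn + 1
    } else {
      if (pred[i] == 1) fp <- fp + 1 else tn <- tn + 1
    }
  }
  c(tp = tp, fn = fn, fp = fp, tn = tn)
}

# Rule prediction by explicit row loops.
oracle_rule_predict <- function(conds, df) {
  out <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in seq_len(nrow(conds))) {
      v <- df[[conds$attribute[j]]][i]
      ok <- ok && if (conds$relation[j] == ">=") v >= conds$threshold[j]
                  else v <= conds$threshold[j]
    }
    out[i] <- as.integer(ok)
  }
  out
}

# --- partition walk, recomputed from its definition -------------------------
# Candidates: midpoints of consecutive distinct sorted values plus the
# extreme value; walk from `start` in the sensitivity-increasing direction;
# stop at the first candidate whose accuracy is >= epsilon below the running
# best; return the accepted candidate with maximal accuracy, ties to higher
# sensitivity, then nearest the start. Confusions are computed by brute
# force at each candidate (no incremental updates).
oracle_refine <- function(values, labels, direction, start, epsilon = 0.01,
                          mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  holds <- function(t) {
    if (direction == ">=") values >= t else values <= t
  }
  cm_at <- function(t) {
    pred <- as.integer(holds(t) & mask)
    oracle_confusion(pred, labels)
  }
  v <- sort(unique(values[mask]))
  cand <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  cand <- if (direction == ">=") c(sort(cand, decreasing = TRUE), v[1])
          else c(sort(cand), v[length(v)])
  cand <- if (direction == ">=") cand[cand < start] else cand[cand > start]
  walk_t <- c(start, cand)
  cms <- t(vapply(walk_t, cm_at, numeric(4)))
  acc <- (cms[, "tp"] + cms[, "tn"]) / length(values)
  sens <- ifelse(cms[, "tp"] + cms[, "fn"] > 0,
                 cms[, "tp"] / (cms[, "tp"] + cms[, "fn"]), 0)
  best <- acc[1]
  last <- length(walk_t)
  for (i in seq_along(walk_t)[-1]) {
    if (best - acc[i] >= epsilon - 1e-12) { last <- i - 1; break }
    best <- max(best, acc[i])
  }
  acc <- acc[1:last]; sens <- sens[1:last]; walk_t <- walk_t[1:last]
  sel <- which(acc >= max(acc) - 1e-12)
  sel <- sel[sens[sel] >= max(sens[sel]) - 1e-12]
  list(threshold = walk_t[sel[1]], cm = cms[sel[1], ])
}

# Full rule induction, recomputed naively: marginal refinement per selected
# attribute then coordinate passes against the conjunction, all confusions
# by brute force.
oracle_build_rule <- function(table, attrs, directions, epsilon = 0.01,
                              joint = TRUE, max_passes = 25) {
  labels <- table$outcome
  starts <- vapply(attrs, function(a) mean(table[[a]][labels == 1]),
                   numeric(1))
  thr <- mapply(function(a, d) {
    oracle_refine(table[[a]], labels, d, starts[[a]], epsilon)$threshold
  }, attrs, directions)
  if (joint && length(attrs) > 1) {
    for (pass in seq_len(max_passes)) {
      prev <- thr
      for (j in seq_along(attrs)) {
        others <- setdiff(seq_along(attrs), j)
        mask <- rep(TRUE, nrow(table))
        for (o in others) {
          v <- table[[attrs[o]]]
          mask <- mask & if (directions[o] == ">=") v >= thr[o]
                         else v <= thr[o]
        }
        thr[j] <- oracle_refine(table[[attrs[j]]], labels, directions[j],
                                starts[[j]], epsilon, mask)$threshold
      }
      if (identical(thr, prev)) break
    }
  }
  conds <- data.frame(attribute = attrs, relation = directions,
                      threshold = as.numeric(thr), stringsAsFactors = FALSE)
  pred <- oracle_rule_predict(conds, table)
  list(conditions = conds, cm = oracle_confusion(pred, labels))
}

# --- time-weighted indices by direct summation ------------------------------
oracle_arv <- function(values, times) {
  num <- den <- 0
  for (k in 2:length(values)) {
    w <- times[k] - times[k - 1]
    num <- num + w * abs(values[k] - values[k - 1])
    den <- den + w
  }
  num / den
}

oracle_wbp <- function(values, times) {
  num <- den <- 0
  for (k in 2:length(values)) {
    w <- times[k] - times[k - 1]
    num <- num + w * (values[k] + values[k - 1]) / 2
    den <- den + w
  }
  num / den
}
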