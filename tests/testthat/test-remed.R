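test_that("univariate logistic fit matches an independent IRLS oracle", {
  set.seed(501)
  x <- c(rnorm(160, 0, 1), rnorm(40, 2, 1))
  y <- rep(c(0, 1), c(160, 40))
  a <- fit_univariate_logistic(x, y, "x")
  o <- oracle_logistic(x, y)
  expect_equal(a$coefficient, o$b1, tolerance = 1e-6)
  expect_equal(a$intercept, o$b0, tolerance = 1e-6)
  expect_equal(a$p_value, o$p_wald, tolerance = 1e-6)
  expect_equal(a$odds_ratio, exp(o$b1), tolerance = 1e-6)
  expect_identical(a$direction, ">=")
  expect_identical(a$test, "wald")
  expect_true(a$selected)  # shifted-mean case is detected at alpha 0.01
})

test_that("degenerate and separated attributes are handled", {
  y <- rep(c(0, 1), c(30, 10))
  const <- fit_univariate_logistic(rep(3, 40), y, "flat")
  expect_true(const$degenerate)
  expect_false(const$selected)

  # complete separation: Wald collapses, LRT fallback kicks in
  x <- c(seq_len(30), 100 + seq_len(10))
  sep <- fit_univariate_logistic(x, y, "sep")
  expect_identical(sep$test, "lrt")
  expect_lt(sep$p_value, 0.01)
})

test_that("screening p-values are uniform under the null", {
  # permuted labels => p ~ U(0,1); Kolmogorov-Smirnov at level 0.01
  set.seed(502)
  x <- rnorm(200)
  y <- rep(c(0, 1), each = 100)
  pvals <- replicate(1000, {
    fit_univariate_logistic(x, sample(y), "x")$p_value
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("select_attributes recovers exactly the planted signal attributes", {
  # outcome driven by x1 and x2 only (log-odds 1.0 each), two pure-noise
  # covariates; exact-recovery rate over 50 replicates must be >= 95%
  set.seed(503)
  hits <- replicate(50, {
    n <- 2000
    tb <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                     x4 = rnorm(n))
    eta <- -2.6 + tb$x1 + tb$x2
    tb$outcome <- rbinom(n, 1, stats::plogis(eta))
    sc <- suppressWarnings(select_attributes(tb))
    setequal(sc$attribute[sc$selected], c("x1", "x2"))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("select_attributes orders by p, honours alpha, rejects bad input", {
  set.seed(504)
  tb <- data.frame(a = rnorm(100), b = rnorm(100), flat = 1,
                   outcome = rbinom(100, 1, 0.3))
  sc <- suppressWarnings(select_attributes(tb, alpha = 1.0))
  expect_false("flat" %in% sc$attribute)     # degenerate skipped
  expect_true(all(sc$selected))              # vacuous cutoff selects the rest
  expect_true(!is.unsorted(sc$p_value))
  tb$outcome <- 0
  expect_error(select_attributes(tb), "constant")
})

test_that("initial partition is the positive-class mean", {
  expect_equal(initial_partition(c(1, 4, 2, 5, 3, 6),
                                 c(0, 1, 0, 1, 0, 1)), 5)
  expect_equal(initial_partition(9.6, 1), 9.6)
  expect_equal(initial_partition(c(2, 4, 9), c(1, 1, 1)), 5)
})

test_that("refine_partition solves the worked example and degenerate cases", {
  thr <- refine_partition(1:6, c(0, 0, 0, 1, 1, 1), ">=", start = 5)
  expect_equal(as.numeric(thr), 3.5)
  cm <- attr(thr, "cm")
  expect_equal(unlist(cm), c(tp = 3, fp = 0, fn = 0, tn = 3))

  # all labels positive: everything ends up predicted positive
  allpos <- refine_partition(c(2, 5, 9), c(1, 1, 1), ">=", start = 16 / 3)
  expect_equal(as.numeric(allpos), 2)
  allpos2 <- refine_partition(c(2, 5, 9), c(1, 1, 1), "<=", start = 16 / 3)
  expect_equal(as.numeric(allpos2), 9)
})

test_that("refine_partition equals its brute-force oracle on small instances", {
  set.seed(505)
  for (i in 1:200) {
    tb <- random_small_table(sample(4:12, 1))
    dir <- sample(c(">=", "<="), 1)
    start <- initial_partition(tb$x1, tb$outcome, dir)
    got <- refine_partition(tb$x1, tb$outcome, dir, start = start)
    want <- oracle_refine(tb$x1, tb$outcome, dir, start = start)
    expect_equal(as.numeric(got), want$threshold)
    expect_equal(unlist(attr(got, "cm"))[c("tp", "fn", "fp", "tn")],
                 want$cm[c("tp", "fn", "fp", "tn")])
  }
})

test_that("the published rule form is representable and reprintable", {
  rule <- remed_rule(c("sbp_arv", "sbp_wbp"), c(">=", ">="), c(9.6, 137))
  expect_equal(format(rule),
               "If sbp_arv >= 9.6 and sbp_wbp >= 137 then 1 Else 0")
  row <- data.frame(sbp_arv = 10, sbp_wbp = 140)
  expect_equal(predict(rule, row), 1L)
  # inclusive relations: exactly at both thresholds is positive
  expect_equal(predict(rule, data.frame(sbp_arv = 9.6, sbp_wbp = 137)), 1L)
  expect_equal(predict(rule, data.frame(sbp_arv = 9.5, sbp_wbp = 200)), 0L)
  expect_error(predict(rule, data.frame(sbp_arv = 10)), "sbp_wbp")
})

test_that("thresholds print rounded but classify unrounded", {
  rule <- remed_rule("x", ">=", 9.649)
  expect_match(format(rule), "9.6", fixed = TRUE)
  expect_equal(predict(rule, data.frame(x = 9.62)), 0L)  # 9.62 < 9.649
})

test_that("single-attribute build_rule reduces to one refined partition", {
  set.seed(506)
  tb <- data.frame(x1 = c(rnorm(45, 5), rnorm(15, 8)),
                   outcome = rep(c(0, 1), c(45, 15)))
  sc <- suppressWarnings(select_attributes(tb))
  rule <- build_rule(tb, sc)
  direct <- refine_partition(tb$x1, tb$outcome, sc$direction[1],
                             start = initial_partition(tb$x1, tb$outcome))
  expect_equal(rule$conditions$threshold, as.numeric(direct))
})

test_that("build_rule matches the brute-force oracle on two-attribute instances", {
  set.seed(507)
  for (i in 1:60) {
    tb <- random_small_table(sample(6:12, 1), n_attr = 2)
    sc <- suppressWarnings(select_attributes(tb, alpha = 1.0))
    rule <- build_rule(tb, sc)
    want <- oracle_build_rule(tb, sc$attribute, sc$direction)
    got_cm <- oracle_confusion(predict(rule, tb), tb$outcome)
    expect_equal(got_cm, want$cm)
  }
})

test_that("joint refinement never lowers sensitivity below entry", {
  set.seed(508)
  for (i in 1:40) {
    tb <- random_small_table(sample(8:40, 1), n_attr = 2)
    sc <- suppressWarnings(select_attributes(tb, alpha = 1.0))
    marginal <- build_rule(tb, sc, joint = FALSE)
    joint <- build_rule(tb, sc, joint = TRUE)
    sens <- function(r) {
      cm <- confusion(predict(r, tb), tb$outcome)
      cm$tp / (cm$tp + cm$fn)
    }
    expect_gte(sens(joint), sens(marginal) - 1e-12)
  }
})

test_that("forcing attributes adds conditions; empty selection errors", {
  set.seed(509)
  tb <- data.frame(x1 = c(rnorm(60, 5), rnorm(20, 9)),
                   noise = rnorm(80),
                   outcome = rep(c(0, 1), c(60, 20)))
  sc <- suppressWarnings(select_attributes(tb))
  forced <- build_rule(tb, sc, force = "noise")
  expect_setequal(forced$conditions$attribute, c("x1", "noise"))
  expect_error(build_rule(tb, sc, force = "absent"), "absent")

  none <- suppressWarnings(select_attributes(tb, alpha = 0))
  expect_error(build_rule(tb, none), class = "remedbp_empty_selection")
})

test_that("rule induction is deterministic", {
  set.seed(510)
  tb <- random_small_table(60, n_attr = 2)
  sc1 <- suppressWarnings(select_attributes(tb, alpha = 1.0))
  sc2 <- suppressWarnings(select_attributes(tb, alpha = 1.0))
  expect_identical(build_rule(tb, sc1), build_rule(tb, sc2))
})

test_that("threshold monotonicity: sens and spec move oppositely", {
  set.seed(511)
  for (i in 1:20) {
    tb <- random_small_table(50)
    grid <- sort(unique(tb$x1))
    stats_at <- t(vapply(grid, function(t) {
      cm <- confusion(as.integer(tb$x1 >= t), tb$outcome)
      c(sens = cm$tp / (cm$tp + cm$fn), spec = cm$tn / (cm$fp + cm$tn))
    }, numeric(2)))
    expect_true(all(diff(stats_at[, "sens"]) <= 1e-12))
    expect_true(all(diff(stats_at[, "spec"]) >= -1e-12))
  }
})
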