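test_that("AUC matches worked examples and edge conventions", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "habitat_degenerate_error")
})

test_that("AUC equals brute-force all-pairs concordance on random instances", {
  set.seed(17)
  for (r in 1:50) {
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    s <- round(runif(n), 2)  # ties likely
    expect_identical(roc_auc(s, y)$auc, brute_auc(s, y))
  }
})

test_that("AUC and its DeLong CI agree with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- rbinom(80, 1, 0.3); y[1:2] <- c(0, 1)
  s <- rnorm(80, y)
  ours <- roc_auc(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci, ci[c(1, 3)], tolerance = 1e-6)
})

test_that("DeLong test: identical models, antisymmetry, reference agreement", {
  set.seed(31)
  y <- rbinom(60, 1, 0.4); y[1:2] <- c(0, 1)
  a <- rnorm(60, 1.2 * y); b <- rnorm(60, 0.8 * y)
  same <- delong_test(a, a, y)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  ab <- delong_test(a, b, y)
  ba <- delong_test(b, a, y)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(ab$p, ref$p.value, tolerance = 1e-9)
})

test_that("Brier and calibration behave on oracle, constant and simulated probs", {
  y <- rep(c(0, 1), 25)
  expect_equal(calibration_brier(as.numeric(y), y)$brier, 0)
  expect_equal(calibration_brier(rep(0.5, 50), y)$brier, 0.25)
  set.seed(41)
  p <- runif(2000)
  yy <- rbinom(2000, 1, p)
  cal <- calibration_brier(p, yy, n_bins = 10)
  expect_true(all(abs(cal$bins$mean_predicted - cal$bins$observed_rate) < 0.1))
})

test_that("decision curves obey the net-benefit identities", {
  set.seed(6)
  y <- rbinom(200, 1, 0.2)
  dc <- decision_curve(runif(200), y)
  expect_true(all(dc$treat_none == 0))
  dc2 <- decision_curve(as.numeric(y), y, thresholds = c(0.25, 0.5, 0.75))
  prev <- mean(y)
  expect_equal(dc2$net_benefit, rep(prev, 3), tolerance = 1e-12)  # perfect model
  # treat-all closed form at prevalence 0.2 and pt = 0.5
  y5 <- rep(c(1, 0, 0, 0, 0), 20)
  ta <- decision_curve(runif(100), y5, thresholds = 0.5)$treat_all
  expect_equal(ta, 0.2 - 0.8 * 1, tolerance = 1e-12)
  expect_error(decision_curve(runif(10), rep(c(0, 1), 5), thresholds = c(0, 0.5)),
               class = "habitat_parameter_error")
})

test_that("size subgroups partition the cohort at the 20/30 mm boundaries", {
  d <- c(15, 20, 25, 30, 35)
  strata <- cut(d, c(-Inf, 20, 30, Inf), labels = c("<=20mm", ">20-30mm", ">30mm"))
  expect_identical(as.integer(table(strata)), c(2L, 2L, 1L))
  set.seed(2)
  probs <- runif(40)
  y <- rbinom(40, 1, 0.4); y[1:2] <- c(0, 1)
  diam <- runif(40, 8, 40)
  sg <- subgroup_eval(probs, y, diam)
  expect_identical(length(sg$strata), 40L)
  expect_false(any(is.na(sg$strata)))            # partition: no loss
  # single-class and empty strata are flagged, not errors
  sg2 <- subgroup_eval(probs, rep(c(0, 1), 20), rep(10, 40))
  expect_true(">20-30mm" %in% names(sg2$flagged))
  expect_false(">20-30mm" %in% names(sg2$reports))
})

test_that("sample-size formula reproduces its worked values", {
  expect_identical(unname(required_sample_size(c(x = 0.80))$n), 97)
  ss <- required_sample_size()
  expect_identical(ss$total, 224)
  # P = 0.5 maximizes the requirement
  ns <- vapply(seq(0.05, 0.95, by = 0.05),
               function(p) required_sample_size(c(p = p))$n, numeric(1))
  expect_identical(unname(which.max(ns)), 10L)
  deg <- required_sample_size(c(p = 1))
  expect_identical(unname(deg$n), 0)
  expect_true(deg$degenerate)
})

test_that("cohort summaries route variables through the right tests", {
  set.seed(10)
  base <- rnorm(40, 10, 2)
  d <- data.frame(g = rep(c("a", "b"), each = 40),
                  same = c(base, base),
                  skew = exp(rnorm(80, 0, 1)),
                  cat = rep(rep(c("x", "y"), c(30, 10)), 2)[c(1:40, 51:80, 41:50)])
  # identical groups: t-test p = 1
  s <- cohort_summary(d, "g", "same")
  expect_equal(s$p, 1, tolerance = 1e-9)
  expect_identical(s$test, "t-test")
  # log-normal variable routed to the rank test by the KS gate
  s2 <- cohort_summary(d, "g", "skew")
  expect_identical(s2$test, "mann-whitney")
  # 2x2 chi-square without continuity correction: hand-computed statistic 20
  d2 <- data.frame(g = rep(c("a", "b"), each = 40),
                   v = c(rep(c("x", "y"), c(30, 10)), rep(c("x", "y"), c(10, 30))))
  tb <- table(d2$v, d2$g)
  expect_equal(unname(chisq.test(tb, correct = FALSE)$statistic), 20)
  s3 <- cohort_summary(d2, "g", "v")
  expect_equal(s3$p[1], unname(chisq.test(tb, correct = FALSE)$p.value))
  expect_false(is.na(s3$p_corrected[1]))
})
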