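check_binary_labels <- function(labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  u <- unique(y)
  if (!all(u %in% c(0L, 1L)))
    stop_habitat("labels must be binary 0/1", "habitat_parameter_error")
  y
}

delong_placements <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  m <- length(pos); n <- length(neg)
  v10 <- vapply(pos, function(p) mean((p > neg) + 0.5 * (p == neg)), 0)
  v01 <- vapply(neg, function(q) mean((pos > q) + 0.5 * (pos == q)), 0)
  # rank-sum AUC: the tied-rank sum moves in exact 0.5 steps, so this equals
  # the all-pairs concordance count to the last bit
  auc <- (sum(rank(scores)[y == 1]) - m * (m + 1) / 2) / (m * n)
  list(v10 = v10, v01 = v01, auc = auc)
}

#' ROC AUC with a DeLong confidence interval
#'
#' AUC via the rank (concordance) formulation with ties counted 1/2; the 95%
#' confidence interval uses the DeLong placement-value variance, clipped to
#' \[0, 1\].
#'
#' @param scores numeric predictions (higher = more likely positive).
#' @param labels binary 0/1 (or 2-level factor, second level = positive).
#' @param conf_level confidence level (default 0.95).
#' @return list with `auc`, `se`, `ci` (length 2).
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95) {
  y <- check_binary_labels(labels)
  if (length(unique(y)) < 2)
    stop_habitat("AUC undefined: both classes must be present", "habitat_degenerate_error")
  pl <- delong_placements(scores, y)
  m <- length(pl$v10); n <- length(pl$v01)
  v <- (if (m > 1) var(pl$v10) else 0) / m + (if (n > 1) var(pl$v01) else 0) / n
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(max(v, 0))
  list(auc = pl$auc, se = se,
       ci = c(max(0, pl$auc - z * se), min(1, pl$auc + z * se)))
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two models scored on the same cases using the
#' covariance of paired placement values; returns the two-sided p-value. A
#' degenerate variance (e.g. identical score vectors) yields z = 0, p = 1,
#' flagged.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary labels shared by both models.
#' @return list with `auc_a`, `auc_b`, `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  y <- check_binary_labels(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y))
    stop_habitat("scores must be paired on identical cases", "habitat_parameter_error")
  if (length(unique(y)) < 2)
    stop_habitat("both classes must be present", "habitat_degenerate_error")
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- if (m > 1) cov(cbind(pa$v10, pb$v10)) else matrix(0, 2, 2)
  s01 <- if (n > 1) cov(cbind(pa$v01, pb$v01)) else matrix(0, 2, 2)
  vdiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
           (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(vdiff) || vdiff < 1e-12)
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1, degenerate = TRUE))
  z <- (pa$auc - pb$auc) / sqrt(vdiff)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = 2 * pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Calibration table and Brier score
#'
#' @param probs predicted probabilities in \[0, 1\].
#' @param labels binary labels.
#' @param n_bins number of quantile bins (default 10).
#' @return list with `brier` and a `bins` data.frame (`n`, `mean_predicted`,
#'   `observed_rate` per bin).
#' @export
calibration_brier <- function(probs, labels, n_bins = 10) {
  y <- check_binary_labels(labels)
  if (any(probs < -1e-9 | probs > 1 + 1e-9))
    stop_habitat("probabilities must lie in [0, 1]", "habitat_parameter_error")
  brier <- mean((probs - y)^2)
  br <- unique(quantile(probs, seq(0, 1, length.out = n_bins + 1)))
  bin <- if (length(br) > 2) cut(probs, br, include.lowest = TRUE) else factor(rep(1, length(probs)))
  bins <- data.frame(bin = levels(bin),
                     n = as.integer(table(bin)),
                     mean_predicted = as.numeric(tapply(probs, bin, mean)),
                     observed_rate = as.numeric(tapply(y, bin, mean)))
  list(brier = brier, bins = bins)
}

#' Decision curve analysis (net benefit)
#'
#' Net benefit at threshold probability `pt` is `TP/n - FP/n * pt/(1-pt)`.
#' The treat-all reference equals `prev - (1-prev) * pt/(1-pt)`; treat-none
#' is identically zero.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param thresholds threshold probabilities in (0, 1).
#' @return data.frame with `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(probs, labels, thresholds = seq(0.05, 0.95, by = 0.05)) {
  y <- check_binary_labels(labels)
  if (any(thresholds <= 0 | thresholds >= 1))
    stop_habitat("thresholds must lie strictly in (0, 1)", "habitat_parameter_error")
  n <- length(y)
  prev <- mean(y)
  nb <- vapply(thresholds, function(pt) {
    tp <- sum(probs >= pt & y == 1)
    fp <- sum(probs >= pt & y == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, 0)
  ta <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit = nb, treat_all = ta,
             treat_none = 0)
}

wilson_ci <- function(x, n, conf_level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Youden-optimal probability threshold
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @return The threshold maximizing sensitivity + specificity - 1 (midpoint
#'   between the optimal score and its successor).
#' @export
youden_threshold <- function(probs, labels) {
  y <- check_binary_labels(labels)
  cand <- sort(unique(probs))
  if (length(cand) == 1) return(cand)
  cuts <- c(cand[1] - 1e-9, (head(cand, -1) + tail(cand, -1)) / 2)
  j <- vapply(cuts, function(t) {
    sens <- mean(probs[y == 1] >= t)
    spec <- mean(probs[y == 0] < t)
    sens + spec - 1
  }, 0)
  cuts[which.max(j)]
}

#' Full evaluation report for one cohort
#'
#' AUC with a DeLong CI, plus accuracy, sensitivity, specificity, PPV and NPV
#' (Wilson CIs) at the supplied probability threshold, Brier score and
#' calibration bins.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param threshold classification cut-point.
#' @param cohort cohort identifier stored in the report.
#' @return An object of class `eval_report` (a list).
#' @export
eval_report <- function(probs, labels, threshold = 0.5, cohort = NA_character_) {
  y <- check_binary_labels(labels)
  a <- roc_auc(probs, y)
  pred <- as.integer(probs >= threshold)
  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  n <- length(y)
  mk <- function(x, d) list(value = if (d > 0) x / d else NA_real_, ci = wilson_ci(x, d))
  cal <- calibration_brier(probs, y)
  structure(list(cohort = cohort, n = n, threshold = threshold,
                 auc = a$auc, auc_ci = a$ci,
                 accuracy = mk(tp + tn, n), sensitivity = mk(tp, tp + fn),
                 specificity = mk(tn, tn + fp), ppv = mk(tp, tp + fp),
                 npv = mk(tn, tn + fn), brier = cal$brier,
                 calibration = cal$bins),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> cohort %s (n = %d), threshold %.3f\n",
              x$cohort, x$n, x$threshold))
  cat(sprintf("  AUC %.3f (%.3f-%.3f)  Brier %.3f\n", x$auc, x$auc_ci[1],
              x$auc_ci[2], x$brier))
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
    cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", nm, x[[nm]]$value,
                x[[nm]]$ci[1], x[[nm]]$ci[2]))
  invisible(x)
}

#' Tumor-size subgroup evaluation
#'
#' Strata follow TNM-style cut points: diameter <= 20 mm, > 20 to <= 30 mm,
#' and > 30 mm. Strata with a single outcome class (or no cases) are flagged
#' and omitted from the report rather than raising an error.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param diameter_mm per-case tumor diameter.
#' @param threshold classification cut-point for the per-stratum reports.
#' @return list with `reports` (named `eval_report`s) and `flagged` (strata
#'   skipped, with reason).
#' @export
subgroup_eval <- function(probs, labels, diameter_mm, threshold = 0.5) {
  y <- check_binary_labels(labels)
  strata <- cut(diameter_mm, c(-Inf, 20, 30, Inf),
                labels = c("<=20mm", ">20-30mm", ">30mm"), right = TRUE)
  reports <- list()
  flagged <- character()
  for (s in levels(strata)) {
    i <- which(strata == s)
    if (length(i) == 0) { flagged[s] <- "empty stratum"; next }
    if (length(unique(y[i])) < 2) { flagged[s] <- "single outcome class"; next }
    reports[[s]] <- eval_report(probs[i], y[i], threshold, cohort = s)
  }
  list(reports = reports, flagged = flagged, strata = strata)
}

#' Required sample size for estimating a diagnostic proportion
#'
#' `n(P) = ceiling(Z^2 * P * (1 - P) / delta^2)` for each expected proportion
#' (e.g. sensitivity and specificity); the total is their sum. `P` of 0 or 1
#' gives n = 0 and is flagged degenerate.
#'
#' @param p named numeric vector of expected proportions in \[0, 1\]
#'   (default `c(sensitivity = 0.80, specificity = 0.70)`).
#' @param delta allowable error (default 0.08).
#' @param alpha two-sided significance level (default 0.05, Z = 1.96).
#' @return list with per-proportion `n`, `total`, `z`, and `degenerate` flags.
#' @export
required_sample_size <- function(p = c(sensitivity = 0.80, specificity = 0.70),
                                 delta = 0.08, alpha = 0.05) {
  if (delta <= 0) stop_habitat("delta must be positive", "habitat_parameter_error")
  if (any(p < 0 | p > 1)) stop_habitat("proportions must lie in [0, 1]", "habitat_parameter_error")
  z <- qnorm(1 - alpha / 2)
  n <- ceiling(z^2 * p * (1 - p) / delta^2)
  list(n = n, total = sum(n), z = z, degenerate = p %in% c(0, 1))
}

#' Baseline-table style cohort summary
#'
#' Continuous variables are routed by a Kolmogorov-Smirnov normality gate (at
#' 0.05, per group): normal variables are summarized as mean (sd) and
#' compared by the two-sample t-test; non-normal as median \[Q1, Q3\] with the
#' Mann-Whitney U test. Categorical variables are summarized as n (%) and
#' compared by the chi-square test without continuity correction (the
#' corrected p-value is also exported).
#'
#' @param table data.frame of covariates.
#' @param group name of the (2-level) grouping column.
#' @param variables columns to summarize (default: all but `group`).
#' @return data.frame with one row per variable: summaries per group, the
#'   test used and its p-value.
#' @export
cohort_summary <- function(table, group, variables = setdiff(names(table), group)) {
  g <- factor(table[[group]])
  if (nlevels(g) != 2) stop_habitat("group must have two levels", "habitat_parameter_error")
  rows <- lapply(variables, function(v) {
    x <- table[[v]]
    if (is.numeric(x)) {
      norm_p <- vapply(levels(g), function(l) {
        xi <- x[g == l]
        if (length(xi) < 3 || sd(xi) == 0) return(0)
        suppressWarnings(ks.test(xi, "pnorm", mean(xi), sd(xi))$p.value)
      }, 0)
      if (all(norm_p > 0.05)) {
        p <- tryCatch(t.test(x ~ g)$p.value, error = function(e) NA_real_)
        s <- vapply(levels(g), function(l)
          sprintf("%.2f (%.2f)", mean(x[g == l]), sd(x[g == l])), "")
        test <- "t-test"
      } else {
        p <- suppressWarnings(wilcox.test(x ~ g)$p.value)
        s <- vapply(levels(g), function(l) {
          q <- quantile(x[g == l], c(0.5, 0.25, 0.75))
          sprintf("%.2f [%.2f, %.2f]", q[1], q[2], q[3])
        }, "")
        test <- "mann-whitney"
      }
      data.frame(variable = v, level = NA_character_,
                 g1 = s[1], g2 = s[2], test = test, p = p,
                 p_corrected = NA_real_)
    } else {
      tb <- table(x, g)
      p <- tryCatch(suppressWarnings(chisq.test(tb, correct = FALSE)$p.value),
                    error = function(e) NA_real_)
      pc <- tryCatch(suppressWarnings(chisq.test(tb, correct = TRUE)$p.value),
                     error = function(e) NA_real_)
      s <- apply(tb, 2, function(cnt)
        sprintf("%d (%.1f%%)", cnt, 100 * cnt / sum(cnt)))
      data.frame(variable = v, level = rownames(tb),
                 g1 = s[, 1], g2 = s[, 2], test = "chi-square",
                 p = p, p_corrected = pc)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[3:4] <- levels(g)
  rownames(out) <- NULL
  out
}
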