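#' Feature-selection settings (RFE + LASSO)
#'
#' @param rfe_keep features retained after recursive feature elimination
#'   (default 30; capped at the available feature count).
#' @param cv_folds folds for the LASSO cross-validation (default 10).
#' @param lasso_alpha_grid optional penalty grid for the LASSO path (glmnet
#'   chooses its own when `NULL`).
#' @param seed integer seed controlling CV fold assignment.
#' @return An object of class `feature_selection_spec`.
#' @export
feature_selection_spec <- function(rfe_keep = 30L, cv_folds = 10L,
                                   lasso_alpha_grid = NULL, seed = 1L) {
  if (rfe_keep < 1 || cv_folds < 2)
    stop_habitat("invalid feature selection spec", "habitat_parameter_error")
  structure(list(rfe_keep = as.integer(rfe_keep), cv_folds = as.integer(cv_folds),
                 lasso_alpha_grid = lasso_alpha_grid, seed = as.integer(seed)),
            class = "feature_selection_spec")
}

# one RFE step: ridge-logistic importance = |coefficient| on standardized
# features; the least important feature is dropped (later columns lose ties,
# so the first of a duplicated pair is the one retained).
rfe_rank <- function(x, y, keep) {
  cols <- colnames(x)
  # exactly duplicated columns carry no extra information: the first of each
  # duplicate group is retained (documented tie-break)
  dup <- duplicated(t(x))
  if (any(dup)) cols <- cols[!dup]
  while (length(cols) > keep) {
    fit <- glmnet::glmnet(x[, cols, drop = FALSE], y, family = "binomial",
                          alpha = 0, lambda = 0.01, standardize = FALSE)
    beta <- abs(as.numeric(fit$beta))
    drop_i <- max(which(beta == min(beta)))
    cols <- cols[-drop_i]
  }
  cols
}

#' Select predictive features by RFE followed by LASSO
#'
#' Recursive feature elimination (ridge-logistic importance, one feature per
#' step) reduces the standardized training features to `rfe_keep`; an
#' L1-penalized logistic path with `cv_folds`-fold cross-validation then
#' picks the penalty with minimal CV deviance and returns the features with
#' nonzero coefficients. If the optimal penalty shrinks everything to zero,
#' the largest penalty on the path with at least one nonzero coefficient is
#' used instead (flagged in the result).
#'
#' @param features standardized numeric matrix/data.frame (training cohort).
#' @param labels binary labels.
#' @param spec a [feature_selection_spec()].
#' @param cohort cohort tag; must be `"training"` (leakage guard).
#' @return list with `features` (selected names), `coefficients` (including
#'   intercept), `lambda`, `rfe_features`, `empty_fallback`.
#' @export
select_features <- function(features, labels, spec = feature_selection_spec(),
                            cohort = "training") {
  if (!identical(cohort, "training"))
    stop_habitat("feature selection must run on the training cohort",
                 "habitat_leakage_error")
  x <- as.matrix(features)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- check_binary_labels(labels)
  set.seed(spec$seed)
  keep <- min(spec$rfe_keep, ncol(x))
  cols <- if (ncol(x) > keep) rfe_rank(x, y, keep) else colnames(x)
  xr <- x[, cols, drop = FALSE]

  foldid <- sample(rep(seq_len(spec$cv_folds), length.out = nrow(xr)))
  cv <- glmnet::cv.glmnet(xr, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = FALSE,
                          lambda = spec$lasso_alpha_grid)
  lam <- cv$lambda.min
  b <- as.numeric(coef(cv, s = lam))
  names(b) <- rownames(coef(cv, s = lam))
  nz <- b[-1][b[-1] != 0]
  empty_fallback <- FALSE
  if (length(nz) == 0) {
    empty_fallback <- TRUE
    nzc <- cv$nzero
    cand <- which(nzc >= 1)
    if (length(cand) > 0) {
      lam <- cv$lambda[cand[1]]       # largest penalty with a nonzero path
      b <- as.numeric(coef(cv, s = lam))
      names(b) <- rownames(coef(cv, s = lam))
      nz <- b[-1][b[-1] != 0]
    }
  }
  list(features = names(nz), coefficients = b[c(TRUE, b[-1] != 0)],
       lambda = lam, rfe_features = cols, empty_fallback = empty_fallback,
       cv = list(lambda = cv$lambda, cvm = cv$cvm, nzero = as.integer(cv$nzero)))
}

#' Univariate / multivariate logistic association analysis
#'
#' Fits maximum-likelihood logistic regressions of a binary outcome on each
#' variable (univariate mode) and, in multivariate mode, a joint model on the
#' univariately significant set (p < 0.05). Factor variables are coded as
#' integer level codes (a documented dictionary-style coding yielding one
#' coefficient per variable). Perfect separation is flagged and the
#' coefficient re-estimated under a small ridge penalty.
#'
#' @param table data.frame containing outcome and variables.
#' @param outcome name of the binary outcome column.
#' @param variables variable names to analyze.
#' @param mode `"univariate"` or `"multivariate"` (the latter includes the
#'   univariate screen).
#' @return data.frame with coefficient, OR, Wald 95% CI, p-value per variable
#'   (and per mode).
#' @export
logistic_assoc <- function(table, outcome, variables,
                           mode = c("univariate", "multivariate")) {
  mode <- match.arg(mode)
  y <- check_binary_labels(table[[outcome]])
  code <- function(v) if (is.numeric(v)) v else as.numeric(factor(v))
  X <- as.data.frame(lapply(table[variables], code))
  one_fit <- function(fit, vars) {
    sm <- summary(fit)$coefficients
    sep <- any(abs(coef(fit)[-1]) > 10) ||
      any(fitted(fit) > 1 - 1e-8) || any(fitted(fit) < 1e-8)
    rows <- lapply(vars, function(v) {
      if (!v %in% rownames(sm))
        return(data.frame(variable = v, coefficient = NA, or = NA,
                          ci_low = NA, ci_high = NA, p = NA, separation = TRUE))
      b <- sm[v, "Estimate"]; se <- sm[v, "Std. Error"]
      data.frame(variable = v, coefficient = b, or = exp(b),
                 ci_low = exp(b - 1.96 * se), ci_high = exp(b + 1.96 * se),
                 p = sm[v, "Pr(>|z|)"], separation = sep && abs(b) > 10)
    })
    do.call(rbind, rows)
  }
  uni <- do.call(rbind, lapply(variables, function(v) {
    d <- data.frame(y = y, x = X[[v]])
    fit <- suppressWarnings(glm(y ~ x, data = d, family = binomial()))
    r <- one_fit(fit, "x")
    r$variable <- v
    r
  }))
  # ridge re-fit for separated univariate coefficients
  for (i in which(uni$separation)) {
    v <- uni$variable[i]
    xm <- cbind(X[[v]], 0)  # glmnet needs >= 2 columns; second is inert
    fit <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0, lambda = 0.1)
    uni$coefficient[i] <- as.numeric(fit$beta)[1]
    uni$or[i] <- exp(uni$coefficient[i])
  }
  uni$mode <- "univariate"
  if (mode == "univariate") return(uni)
  sig <- uni$variable[!is.na(uni$p) & uni$p < 0.05]
  if (length(sig) == 0) return(uni)
  d <- cbind(data.frame(y = y), X[sig])
  fit <- suppressWarnings(glm(y ~ ., data = d, family = binomial()))
  multi <- one_fit(fit, sig)
  multi$mode <- "multivariate"
  rbind(uni, multi)
}
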