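## ---- feature preprocessors (fitted on training data only) ----------------

boxcox_loglik <- function(x, lambda) {
  n <- length(x)
  y <- if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
  -n / 2 * log(var(y) * (n - 1) / n + 1e-300) + (lambda - 1) * sum(log(x))
}

yj_transform <- function(x, lambda) {
  y <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) < 1e-8) y[pos] <- log1p(x[pos])
  else y[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  if (abs(lambda - 2) < 1e-8) y[!pos] <- -log1p(-x[!pos])
  else y[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  y
}

yj_loglik <- function(x, lambda) {
  n <- length(x)
  y <- yj_transform(x, lambda)
  -n / 2 * log(var(y) * (n - 1) / n + 1e-300) +
    (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Fit a feature preprocessor on training data
#'
#' Four sklearn-style transformers, fitted column-wise on the training cohort
#' and applied unchanged elsewhere: `box_cox` (per-feature positivity shift by
#' the minimum plus a small epsilon, maximum-likelihood lambda, then
#' standardization), `maxabs` (division by the maximum absolute value),
#' `quantile` (empirical-CDF mapping to \[0, 1\]), and `yeo_johnson`
#' (maximum-likelihood lambda, standardization).
#'
#' @param x numeric training matrix.
#' @param method one of `"box_cox"`, `"maxabs"`, `"quantile"`, `"yeo_johnson"`.
#' @param cohort cohort tag; must be `"training"` (leakage guard).
#' @return An object of class `preprocessor` (parameters + method).
#' @export
fit_preprocessor <- function(x, method = c("box_cox", "maxabs", "quantile",
                                           "yeo_johnson"),
                             cohort = "training") {
  method <- match.arg(method)
  if (!identical(cohort, "training"))
    stop_habitat("preprocessors must be fitted on the training cohort",
                 "habitat_leakage_error")
  x <- as.matrix(x)
  params <- switch(method,
    box_cox = lapply(seq_len(ncol(x)), function(j) {
      v <- x[, j]
      shift <- -min(v) + 1e-6 + 0.001 * max(diff(range(v)), 1e-6)
      vs <- v + shift
      lam <- if (sd(vs) < 1e-12) 1 else
        optimize(function(l) boxcox_loglik(vs, l), c(-2, 2), maximum = TRUE)$maximum
      tv <- if (abs(lam) < 1e-8) log(vs) else (vs^lam - 1) / lam
      list(shift = shift, lambda = lam, center = mean(tv), scale = max(sd(tv), 1e-12))
    }),
    maxabs = lapply(seq_len(ncol(x)), function(j)
      list(scale = max(max(abs(x[, j])), 1e-12))),
    quantile = lapply(seq_len(ncol(x)), function(j)
      list(sorted = sort(x[, j]))),
    yeo_johnson = lapply(seq_len(ncol(x)), function(j) {
      v <- x[, j]
      lam <- if (sd(v) < 1e-12) 1 else
        optimize(function(l) yj_loglik(v, l), c(-2, 2), maximum = TRUE)$maximum
      tv <- yj_transform(v, lam)
      list(lambda = lam, center = mean(tv), scale = max(sd(tv), 1e-12))
    }))
  structure(list(method = method, params = params, columns = colnames(x)),
            class = "preprocessor")
}

#' Apply a fitted preprocessor
#'
#' @param prep a fitted `preprocessor`.
#' @param x numeric matrix with the same columns as the training data.
#' @return Transformed matrix.
#' @export
apply_preprocessor <- function(prep, x) {
  stopifnot(inherits(prep, "preprocessor"))
  x <- as.matrix(x)
  out <- x
  for (j in seq_len(ncol(x))) {
    p <- prep$params[[j]]
    v <- x[, j]
    out[, j] <- switch(prep$method,
      box_cox = {
        vs <- pmax(v + p$shift, 1e-12)
        tv <- if (abs(p$lambda) < 1e-8) log(vs) else (vs^p$lambda - 1) / p$lambda
        (tv - p$center) / p$scale
      },
      maxabs = v / p$scale,
      quantile = {
        n <- length(p$sorted)
        if (n == 1 || p$sorted[n] == p$sorted[1]) rep(0.5, length(v))
        else approx(p$sorted, seq(0, 1, length.out = n), xout = v, rule = 2,
                    ties = "ordered")$y
      },
      yeo_johnson = (yj_transform(v, p$lambda) - p$center) / p$scale)
  }
  out
}

## ---- classifiers ---------------------------------------------------------

classifier_names <- c("random_forest", "logistic", "qda", "svm", "decision_tree")

fit_classifier <- function(name, x, y, seed = 1L) {
  set.seed(seed)
  yf <- factor(y, levels = c(0, 1))
  d <- data.frame(x, check.names = FALSE)
  switch(name,
    random_forest = randomForest::randomForest(x, yf, ntree = 500),
    logistic = suppressWarnings(glm(yf ~ ., data = cbind(d, yf = yf),
                                    family = binomial())),
    qda = MASS::qda(x, grouping = yf),
    svm = e1071::svm(x, yf, probability = TRUE, kernel = "radial"),
    decision_tree = rpart::rpart(yf ~ ., data = cbind(d, yf = yf),
                                 method = "class"),
    stop_habitat(paste("unknown classifier", name), "habitat_parameter_error"))
}

predict_prob <- function(name, fit, x) {
  d <- data.frame(x, check.names = FALSE)
  switch(name,
    random_forest = as.numeric(predict(fit, x, type = "prob")[, "1"]),
    logistic = as.numeric(predict(fit, newdata = d, type = "response")),
    qda = as.numeric(predict(fit, x)$posterior[, "1"]),
    svm = {
      pr <- predict(fit, x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    decision_tree = as.numeric(predict(fit, d, type = "prob")[, "1"]))
}

#' Preprocessor-by-classifier grid specification
#'
#' The full default grid crosses four preprocessors (Box-Cox, MaxAbs,
#' Quantile, Yeo-Johnson) with five classifiers (random forest, logistic
#' regression, QDA, SVM, decision tree): 20 candidates.
#'
#' @param preprocessors subset of the four preprocessor names.
#' @param classifiers subset of the five classifier names.
#' @param seed integer seed for classifier fitting.
#' @return An object of class `model_grid_spec`.
#' @export
model_grid_spec <- function(preprocessors = c("box_cox", "maxabs", "quantile",
                                              "yeo_johnson"),
                            classifiers = classifier_names, seed = 1L) {
  preprocessors <- match.arg(preprocessors, several.ok = TRUE)
  classifiers <- match.arg(classifiers, classifier_names, several.ok = TRUE)
  if (length(preprocessors) == 0 || length(classifiers) == 0)
    stop_habitat("empty model grid", "habitat_parameter_error")
  structure(list(preprocessors = preprocessors, classifiers = classifiers,
                 seed = as.integer(seed)), class = "model_grid_spec")
}

#' Train the model grid and select the best candidate on validation AUC
#'
#' Fits every preprocessor-classifier pair on the training cohort
#' (preprocessors fitted on training data only), scores the validation
#' cohort, and returns the candidate with the highest validation AUC (ties:
#' higher validation accuracy at 0.5, then grid order). The operating
#' threshold is chosen by Youden's J on the training cohort. Candidates whose
#' fit fails (e.g. a degenerate covariance in QDA) are ranked last and
#' flagged rather than aborting the grid.
#'
#' @param train_x,train_y training features (already selected) and labels.
#' @param val_x,val_y validation features and labels (disjoint from training).
#' @param grid a [model_grid_spec()].
#' @return An object of class `grade_model`: the fitted best candidate, the
#'   ranked candidate table, the operating threshold and feature names.
#' @export
grid_train <- function(train_x, train_y, val_x, val_y, grid = model_grid_spec()) {
  tx <- as.matrix(train_x); vx <- as.matrix(val_x)
  ty <- check_binary_labels(train_y); vy <- check_binary_labels(val_y)
  if (length(unique(vy)) < 2)
    stop_habitat("validation AUC undefined: single-class validation cohort",
                 "habitat_degenerate_error")
  cand <- expand.grid(preprocessor = grid$preprocessors,
                      classifier = grid$classifiers,
                      stringsAsFactors = FALSE)
  # grid order: preprocessors vary fastest within each classifier
  fits <- vector("list", nrow(cand))
  cand$val_auc <- NA_real_
  cand$val_accuracy <- NA_real_
  cand$failed <- FALSE
  for (i in seq_len(nrow(cand))) {
    res <- tryCatch({
      prep <- fit_preprocessor(tx, cand$preprocessor[i])
      txt <- apply_preprocessor(prep, tx)
      vxt <- apply_preprocessor(prep, vx)
      fit <- fit_classifier(cand$classifier[i], txt, ty, seed = grid$seed)
      pv <- predict_prob(cand$classifier[i], fit, vxt)
      list(prep = prep, fit = fit,
           auc = roc_auc(pv, vy)$auc, acc = mean((pv >= 0.5) == (vy == 1)))
    }, error = function(e) NULL)
    if (is.null(res)) { cand$failed[i] <- TRUE; next }
    fits[[i]] <- res
    cand$val_auc[i] <- res$auc
    cand$val_accuracy[i] <- res$acc
  }
  if (all(cand$failed))
    stop_habitat("every grid candidate failed to fit", "habitat_degenerate_error")
  ord <- order(-replace(cand$val_auc, is.na(cand$val_auc), -Inf),
               -replace(cand$val_accuracy, is.na(cand$val_accuracy), -Inf),
               seq_len(nrow(cand)))
  best_i <- ord[1]
  best <- fits[[best_i]]
  pt <- predict_prob(cand$classifier[best_i], best$fit,
                     apply_preprocessor(best$prep, tx))
  structure(list(preprocessor = best$prep,
                 classifier = cand$classifier[best_i],
                 fit = best$fit,
                 threshold = youden_threshold(pt, ty),
                 features = colnames(tx),
                 ranking = cand[ord, c("preprocessor", "classifier", "val_auc",
                                       "val_accuracy", "failed")],
                 val_auc = cand$val_auc[best_i],
                 seed = grid$seed),
            class = "grade_model")
}

#' Fit the grade-prediction model (formula-free front end)
#'
#' Convenience wrapper over [grid_train()] taking feature data.frames with a
#' label column.
#'
#' @param train,val data.frames holding the feature columns and `label`.
#' @param features feature column names.
#' @param label label column name.
#' @param grid a [model_grid_spec()].
#' @return A `grade_model`.
#' @export
fit_grade_model <- function(train, val, features, label = "label",
                            grid = model_grid_spec()) {
  grid_train(train[features], train[[label]], val[features], val[[label]],
             grid = grid)
}

#' @export
predict.grade_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as.matrix(as.data.frame(newdata)[object$features])
  p <- predict_prob(object$classifier, object$fit,
                    apply_preprocessor(object$preprocessor, x))
  if (type == "prob") p else as.integer(p >= object$threshold)
}

#' @export
print.grade_model <- function(x, ...) {
  cat(sprintf("<grade_model> %s + %s (validation AUC %.3f, threshold %.3f)\n",
              x$preprocessor$method, x$classifier, x$val_auc, x$threshold))
  cat(sprintf("  %d features: %s\n", length(x$features),
              paste(head(x$features, 6), collapse = ", ")))
  invisible(x)
}

#' @export
summary.grade_model <- function(object, ...) {
  cat(sprintf("Grade-prediction model: %s preprocessing + %s classifier\n",
              object$preprocessor$method, object$classifier))
  cat(sprintf("Operating threshold (Youden on training): %.3f\n", object$threshold))
  cat("\nCandidate ranking (validation AUC):\n")
  print(object$ranking, row.names = FALSE)
  invisible(object$ranking)
}

#' @export
coef.grade_model <- function(object, ...) {
  if (object$classifier == "logistic") coef(object$fit) else NULL
}
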