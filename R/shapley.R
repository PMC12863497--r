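#' Exact interventional Shapley attributions for a tabular model
#'
#' Enumerates all 2^d feature subsets (d <= 15). For a subset S, the value
#' v(S) is the model's mean prediction over the background sample with the
#' features in S replaced by the case's values (absent features are
#' marginalized by background substitution). Attributions are the
#' Shapley-weighted average marginal contributions; the efficiency identity
#' `sum(attributions) = f(case) - mean f(background)` holds exactly up to
#' floating point.
#'
#' @param model a `grade_model`, or a function mapping a feature matrix to a
#'   numeric prediction vector.
#' @param case_features single-row data.frame / named numeric vector.
#' @param background_features background sample (matrix/data.frame).
#' @return list with `attributions` (named), `base_value` (mean background
#'   prediction) and `prediction` (f(case)).
#' @export
shapley_attribution <- function(model, case_features, background_features) {
  f <- if (is.function(model)) model
       else function(x) predict(model, x, type = "prob")
  bg <- as.matrix(as.data.frame(background_features))
  case <- unlist(as.data.frame(case_features)[1, , drop = TRUE])
  if (!is.null(colnames(bg))) case <- case[colnames(bg)]
  d <- ncol(bg)
  if (d > 15)
    stop_habitat("exact Shapley enumeration supports at most 15 features",
                 "habitat_parameter_error")
  nbg <- nrow(bg)
  nsub <- bitwShiftL(1L, d)

  # v(S) for every subset bitmask
  v <- numeric(nsub)
  for (s in 0:(nsub - 1L)) {
    x <- bg
    for (j in seq_len(d))
      if (bitwAnd(s, bitwShiftL(1L, j - 1L)) != 0L) x[, j] <- case[j]
    v[s + 1L] <- mean(f(x))
  }

  fact <- factorial(0:d)
  w <- fact[1:d] * fact[d:1] / fact[d + 1]   # w[k+1] = k! (d-k-1)! / d!
  phi <- numeric(d)
  sizes <- vapply(0:(nsub - 1L), function(s) sum(bitwAnd(s, bitwShiftL(1L, 0:(d - 1L))) != 0L), 0L)
  for (j in seq_len(d)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(nsub - 1L), bit) == 0L) - 1L
    phi[j] <- sum(w[sizes[without + 1L] + 1L] * (v[without + bit + 1L] - v[without + 1L]))
  }
  names(phi) <- colnames(bg) %||% paste0("f", seq_len(d))
  list(attributions = phi, base_value = v[1], prediction = v[nsub])
}

#' Mean-|attribution| feature ranking over a cohort
#'
#' @param model passed to [shapley_attribution()].
#' @param cases feature table (one row per case).
#' @param background_features background sample.
#' @return data.frame `feature`, `mean_abs_attribution`, sorted descending.
#' @export
shapley_importance <- function(model, cases, background_features) {
  cases <- as.data.frame(cases)
  mat <- t(vapply(seq_len(nrow(cases)), function(i)
    shapley_attribution(model, cases[i, , drop = FALSE],
                        background_features)$attributions,
    numeric(ncol(as.data.frame(background_features)))))
  imp <- colMeans(abs(mat))
  data.frame(feature = names(imp)[order(-imp)],
             mean_abs_attribution = sort(imp, decreasing = TRUE),
             row.names = NULL)
}
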