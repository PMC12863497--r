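#' SMOTE rebalancing settings
#'
#' Semantics follow the perc.over / perc.under convention: each minority case
#' spawns `floor(perc_over/100)` synthetic cases by convex interpolation
#' toward one of its `k_neighbors` nearest minority neighbors, and the
#' majority class is down-sampled to `round(perc_under/100 * n_synthetic)`.
#' Defaults are perc.over = 200, perc.under = 155.
#'
#' @param perc_over oversampling percentage (>= 0).
#' @param perc_under majority retention percentage of the synthetic count.
#' @param k_neighbors nearest minority neighbors considered (>= 1).
#' @param seed integer seed.
#' @return An object of class `resample_spec`.
#' @export
resample_spec <- function(perc_over = 200, perc_under = 155, k_neighbors = 5L,
                          seed = 1L) {
  if (perc_over < 0 || perc_under < 0 || k_neighbors < 1)
    stop_habitat("invalid resample spec", "habitat_parameter_error")
  structure(list(perc_over = perc_over, perc_under = perc_under,
                 k_neighbors = as.integer(k_neighbors), seed = as.integer(seed)),
            class = "resample_spec")
}

#' SMOTE oversampling with majority down-sampling
#'
#' Only ever applies to the training cohort: passing any other cohort tag is
#' a hard error (leakage guard).
#'
#' @param features numeric matrix or data.frame (rows = cases).
#' @param labels binary labels (0/1 or 2-level factor).
#' @param spec a [resample_spec()].
#' @param cohort cohort tag of the data; must be `"training"`.
#' @return list with rebalanced `features` (matrix), `labels` (integer 0/1),
#'   `synthetic` (logical flag per returned row) and an `info` list.
#' @export
smote_resample <- function(features, labels, spec = resample_spec(),
                           cohort = "training") {
  if (!identical(cohort, "training"))
    stop_habitat("SMOTE may only be applied to the training cohort",
                 "habitat_leakage_error")
  x <- as.matrix(features)
  y <- check_binary_labels(labels)
  minority <- as.integer(names(which.min(table(y))))
  mi <- which(y == minority); ma <- which(y != minority)
  if (length(mi) < spec$k_neighbors + 1)
    stop_habitat("minority class smaller than k_neighbors + 1", "habitat_parameter_error")
  set.seed(spec$seed)
  n_per <- floor(spec$perc_over / 100)
  xm <- x[mi, , drop = FALSE]
  dm <- as.matrix(dist(xm))
  diag(dm) <- Inf
  synth <- vector("list", length(mi) * n_per)
  s <- 0L
  for (i in seq_along(mi)) {
    nn <- order(dm[i, ])[seq_len(spec$k_neighbors)]
    for (r in seq_len(n_per)) {
      nb <- nn[sample.int(length(nn), 1L)]
      u <- runif(1)
      s <- s + 1L
      synth[[s]] <- xm[i, ] + u * (xm[nb, ] - xm[i, ])
    }
  }
  n_syn <- s
  keep_ma <- round(spec$perc_under / 100 * n_syn)
  capped <- keep_ma > length(ma)
  keep_ma <- min(keep_ma, length(ma))
  ma_keep <- if (keep_ma > 0) sample(ma, keep_ma) else integer(0)

  xs <- if (n_syn > 0) do.call(rbind, synth[seq_len(n_syn)]) else NULL
  out_x <- rbind(x[mi, , drop = FALSE], xs, x[ma_keep, , drop = FALSE])
  out_y <- c(rep(minority, length(mi) + n_syn), y[ma_keep])
  rownames(out_x) <- NULL
  list(features = out_x, labels = out_y,
       synthetic = c(rep(FALSE, length(mi)), rep(TRUE, n_syn),
                     rep(FALSE, length(ma_keep))),
       info = list(minority_class = minority, n_minority = length(mi),
                   n_synthetic = n_syn, n_majority_kept = length(ma_keep),
                   majority_capped = capped, cohort = cohort))
}

#' Z-score standardization fitted on training data only
#'
#' Column means and standard deviations are estimated on the training table
#' and applied unchanged to every other cohort (leakage guard). Zero-variance
#' columns are flagged and passed through centered.
#'
#' @param train numeric matrix/data.frame (training cohort).
#' @param ... further cohorts to transform with the training parameters
#'   (named arguments recommended).
#' @param cohort cohort tag of `train`; must be `"training"`.
#' @return list with `train`, `others` (list of transformed tables),
#'   `center`, `scale`, `constant_columns`.
#' @export
zscore_fit_apply <- function(train, ..., cohort = "training") {
  if (!identical(cohort, "training"))
    stop_habitat("Z-score parameters must be fitted on the training cohort",
                 "habitat_leakage_error")
  xt <- as.matrix(train)
  ctr <- colMeans(xt)
  scl <- apply(xt, 2, sd)
  const <- !is.finite(scl) | scl < 1e-12
  scl[const] <- 1
  tf <- function(m) {
    m <- as.matrix(m)
    sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
  }
  others <- lapply(list(...), tf)
  list(train = tf(xt), others = others, center = ctr, scale = scl,
       constant_columns = names(ctr)[const] %||% which(const))
}
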