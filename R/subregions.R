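#' Supervoxel oversegmentation settings
#'
#' @param n_segments target supervoxel count per lesion (default 100).
#' @param compactness spatial-regularization weight on the unit-intensity
#'   scale (default 0.1): larger values give more compact, more spatial
#'   supervoxels; smaller values track intensity more closely.
#' @param max_iter SLIC iterations.
#' @return An object of class `supervoxel_spec`.
#' @export
supervoxel_spec <- function(n_segments = 100L, compactness = 0.1, max_iter = 10L) {
  if (n_segments < 1) stop_habitat("n_segments must be >= 1", "habitat_parameter_error")
  if (compactness <= 0) stop_habitat("compactness must be positive", "habitat_parameter_error")
  structure(list(n_segments = as.integer(n_segments), compactness = compactness,
                 max_iter = as.integer(max_iter)), class = "supervoxel_spec")
}

#' SLIC-style supervoxels within a lesion mask
#'
#' Runs simple linear iterative clustering on the window-normalized
#' intensities restricted to the mask. The result partitions the mask exactly
#' into at most `n_segments` spatially connected supervoxels, each summarized
#' by its phenotype: mean normalized intensity and voxel count.
#'
#' @param voi a `ct_volume` in unit domain.
#' @param mask a `lesion_mask` aligned to `voi`.
#' @param spec a [supervoxel_spec()].
#' @return An object of class `supervoxel_map`: `labels` (3D integer array, 0
#'   outside the mask), `phenotypes` (data.frame: `supervoxel`,
#'   `mean_intensity`, `n_voxels`), `spacing`.
#' @export
compute_supervoxels <- function(voi, mask, spec = supervoxel_spec()) {
  stopifnot(inherits(voi, "ct_volume"), inherits(mask, "lesion_mask"))
  if (voi$domain != "unit")
    stop_habitat("supervoxels expect a window-normalized (unit) volume", "habitat_parameter_error")
  check_aligned(voi, mask)
  if (!any(mask$voxels)) stop_habitat("mask is empty", "habitat_empty_mask_error")
  dims <- dim(voi$voxels)
  lab <- .slic3d(as.numeric(voi$voxels), as.logical(mask$voxels),
                 as.integer(dims), as.numeric(voi$spacing),
                 spec$n_segments, spec$compactness, spec$max_iter)
  labels <- array(lab, dim = dims)
  idx <- labels[labels > 0L]
  vals <- voi$voxels[labels > 0L]
  ph <- data.frame(supervoxel = sort(unique(idx)))
  ph$mean_intensity <- as.numeric(tapply(vals, idx, mean))
  ph$n_voxels <- as.integer(tapply(vals, idx, length))
  structure(list(labels = labels, phenotypes = ph, spacing = voi$spacing),
            class = "supervoxel_map")
}

#' @export
print.supervoxel_map <- function(x, ...) {
  cat(sprintf("<supervoxel_map> %d supervoxels over %d voxels\n",
              nrow(x$phenotypes), sum(x$phenotypes$n_voxels)))
  invisible(x)
}

#' Elbow selection of the cluster count from an SSE curve
#'
#' The elbow is the candidate maximizing the curvature (second difference) of
#' the SSE profile on the log scale; relative drops, not absolute ones, locate
#' the point where adding a cluster stops paying. Ties break toward the
#' smaller k. A flat (all-zero) curve returns the smallest candidate.
#'
#' @param sse_curve numeric vector of within-cluster SSE values, one per
#'   candidate, non-increasing (tolerance 1e-9 relative).
#' @param k_candidates integer candidates matching `sse_curve` (default
#'   `seq_along(sse_curve)`).
#' @return The selected k.
#' @export
select_k_elbow <- function(sse_curve, k_candidates = seq_along(sse_curve)) {
  n <- length(sse_curve)
  if (n < 3) stop_habitat("sse curve needs at least 3 points", "habitat_parameter_error")
  tol <- 1e-9 * max(abs(sse_curve), 1)
  if (any(diff(sse_curve) > tol))
    stop_habitat("sse curve must be non-increasing", "habitat_invalid_curve_error")
  if (max(sse_curve) <= tol) return(k_candidates[1])
  floor_val <- max(sse_curve) * 1e-12
  l <- log(pmax(sse_curve, floor_val))
  interior <- 2:(n - 1)
  d2 <- l[interior - 1] - 2 * l[interior] + l[interior + 1]
  k_candidates[interior[which.max(d2)]]
}

canonical_label_order <- function(means) {
  # canonical semantics: label 1 = highest attenuation, 2 = lowest,
  # 3..k = remaining in descending attenuation
  k <- length(means)
  ord <- order(means, decreasing = TRUE)    # component indices, high -> low
  canon <- integer(k)
  canon[ord[1]] <- 1L
  if (k >= 2) canon[ord[k]] <- 2L
  if (k >= 3) canon[ord[2:(k - 1)]] <- seq(3L, k)
  canon
}

#' Fit the cohort-level subregion mixture model
#'
#' Pools training-cohort supervoxel phenotypes (mean normalized intensity)
#' and fits one-dimensional Gaussian mixtures with unequal variances for each
#' candidate k. The within-cluster SSE under hard maximum-posterior
#' assignment is recorded per candidate (monotonized by a running minimum)
#' and the subregion count is chosen by [select_k_elbow()]. Mixture
#' components are mapped to canonical subregion labels by attenuation:
#' 1 = highest, 2 = lowest, 3..k = remaining in descending order.
#'
#' @param phenotypes data.frame with a `mean_intensity` column (pooled
#'   training supervoxels), or a numeric vector.
#' @param k_candidates integer candidates (default 1:6).
#' @param seed fit seed.
#' @return An object of class `subregion_model` with elements `k`, `weights`,
#'   `means`, `variances`, `label_order`, `sse_curve`, `k_candidates`,
#'   `fit_seed`.
#' @export
fit_subregion_model <- function(phenotypes, k_candidates = 1:6, seed = 1L) {
  x <- if (is.data.frame(phenotypes)) phenotypes$mean_intensity else as.numeric(phenotypes)
  if (length(k_candidates) == 0) stop_habitat("no candidate k", "habitat_parameter_error")
  k_candidates <- sort(unique(as.integer(k_candidates)))
  if (length(x) < max(k_candidates))
    stop_habitat("fewer phenotype rows than the largest candidate k", "habitat_degenerate_fit_error")
  set.seed(as.integer(seed))

  degenerate <- var(x) < 1e-12
  fits <- vector("list", length(k_candidates))
  sse <- numeric(length(k_candidates))
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    if (degenerate || k == 1L) {
      mu <- if (degenerate) rep(mean(x), k) else mean(x)
      fits[[i]] <- list(weights = rep(1 / k, k), means = mu,
                        variances = rep(max(var(x), 0), k))
      sse[i] <- if (degenerate) 0 else sum((x - mean(x))^2)
      next
    }
    fit <- fit_gmm_1d(x, k, restarts = 10L, seed = as.integer(seed) + 97L * k)
    if (is.null(fit)) {
      fits[i] <- list(NULL)
      sse[i] <- NA_real_
      next
    }
    fits[[i]] <- fit
    hard <- fit$means[apply_posterior(x, fit)]
    sse[i] <- sum((x - hard)^2)
  }
  ok <- !is.na(sse)
  if (sum(ok) < 3 && length(k_candidates) >= 3)
    stop_habitat("too many mixture fits failed", "habitat_degenerate_fit_error")
  sse[ok] <- cummin(sse[ok])

  k_sel <- if (degenerate) k_candidates[1]
           else if (sum(ok) >= 3) select_k_elbow(sse[ok], k_candidates[ok])
           else k_candidates[ok][1]
  best <- fits[[match(k_sel, k_candidates)]]
  structure(list(k = k_sel, weights = best$weights, means = best$means,
                 variances = best$variances,
                 label_order = canonical_label_order(best$means),
                 sse_curve = sse, k_candidates = k_candidates,
                 fit_seed = as.integer(seed)),
            class = "subregion_model")
}

# EM fit of a 1-D unequal-variance Gaussian mixture with multiple k-means
# initializations; the restart with the best log-likelihood wins. Returns
# NULL when every restart fails.
fit_gmm_1d <- function(x, k, restarts = 10L, seed = 1L) {
  xm <- matrix(x, ncol = 1)
  best <- NULL
  best_ll <- -Inf
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    fit <- tryCatch({
      km <- suppressWarnings(stats::kmeans(x, centers = k, nstart = 1,
                                           iter.max = 50))
      z0 <- mclust::unmap(km$cluster, groups = seq_len(k))
      mclust::meV(data = xm, z = z0,
                  control = mclust::emControl(tol = 1e-6, itmax = 500))
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$loglik %||% NA_real_)) next
    p <- fit$parameters
    if (any(!is.finite(p$mean)) || any(!is.finite(p$pro))) next
    if (fit$loglik > best_ll) {
      vars <- p$variance$sigmasq
      if (length(vars) == 1L) vars <- rep(vars, k)
      best <- list(weights = as.numeric(p$pro), means = as.numeric(p$mean),
                   variances = as.numeric(vars))
      best_ll <- fit$loglik
    }
  }
  best
}

# max-posterior component index for values x under a fitted 1-D mixture
apply_posterior <- function(x, fit) {
  k <- length(fit$means)
  if (k == 1L) return(rep(1L, length(x)))
  dens <- sapply(seq_len(k), function(j)
    fit$weights[j] * dnorm(x, fit$means[j], sqrt(pmax(fit$variances[j], 1e-12))))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(x))
  max.col(dens, ties.method = "first")
}

#' @export
print.subregion_model <- function(x, ...) {
  cat(sprintf("<subregion_model> k = %d subregions (candidates %s)\n", x$k,
              paste(range(x$k_candidates), collapse = "..")))
  ord <- order(x$label_order)
  cat("  canonical label: mean intensity (weight)\n")
  for (j in ord)
    cat(sprintf("    %d: %.4f (%.3f)\n", x$label_order[j], x$means[j], x$weights[j]))
  invisible(x)
}

#' Assign canonical subregion labels to a supervoxel map
#'
#' Each supervoxel takes the maximum-posterior mixture component of its mean
#' intensity, mapped through the model's canonical label order; every in-mask
#' voxel inherits its supervoxel's subregion label.
#'
#' @param svmap a `supervoxel_map`.
#' @param model a fitted `subregion_model`.
#' @return An object of class `subregion_labelmap`: integer 3D `labels`
#'   (0 = background, 1..k = subregions), `k`, `spacing`.
#' @export
assign_subregions <- function(svmap, model) {
  stopifnot(inherits(svmap, "supervoxel_map"))
  if (!inherits(model, "subregion_model") || is.null(model$means))
    stop_habitat("model is not a fitted subregion_model", "habitat_state_error")
  comp <- apply_posterior(svmap$phenotypes$mean_intensity, model)
  canon <- model$label_order[comp]
  lut <- integer(max(svmap$phenotypes$supervoxel))
  lut[svmap$phenotypes$supervoxel] <- canon
  labels <- array(0L, dim = dim(svmap$labels))
  inm <- svmap$labels > 0L
  labels[inm] <- lut[svmap$labels[inm]]
  structure(list(labels = labels, k = model$k, spacing = svmap$spacing),
            class = "subregion_labelmap")
}

#' @export
predict.subregion_model <- function(object, svmap, ...) assign_subregions(svmap, object)

#' Per-subregion attenuation and volume statistics
#'
#' @param labelmap a `subregion_labelmap`.
#' @param hu_vol the aligned `ct_volume` in HU domain.
#' @return data.frame with one row per subregion 1..k: `n_voxels`,
#'   `proportion` (of mask volume), `mean_hu` (NA when the label is absent,
#'   with `degenerate = TRUE`).
#' @export
subregion_stats <- function(labelmap, hu_vol) {
  stopifnot(inherits(labelmap, "subregion_labelmap"), inherits(hu_vol, "ct_volume"))
  if (!identical(dim(labelmap$labels), dim(hu_vol$voxels)))
    stop_habitat("grids are not aligned", "habitat_alignment_error")
  k <- labelmap$k
  lab <- labelmap$labels
  inm <- lab > 0L
  total <- sum(inm)
  out <- data.frame(subregion = seq_len(k), n_voxels = 0L, proportion = 0,
                    mean_hu = NA_real_, degenerate = TRUE)
  for (j in seq_len(k)) {
    sel <- lab == j
    n <- sum(sel)
    out$n_voxels[j] <- n
    out$proportion[j] <- n / total
    if (n > 0) {
      out$mean_hu[j] <- mean(hu_vol$voxels[sel])
      out$degenerate[j] <- FALSE
    }
  }
  out
}

#' Serialize / restore a subregion model as JSON
#'
#' @param model a `subregion_model`.
#' @param path file path.
#' @return `write_subregion_model` returns `path` invisibly;
#'   `read_subregion_model` the restored model.
#' @export
write_subregion_model <- function(model, path) {
  stopifnot(inherits(model, "subregion_model"))
  doc <- unclass(model)
  doc$format_version <- 1L
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subregion_model
#' @export
read_subregion_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$format_version <- NULL
  doc$k <- as.integer(doc$k)
  doc$label_order <- as.integer(doc$label_order)
  doc$k_candidates <- as.integer(doc$k_candidates)
  structure(doc, class = "subregion_model")
}
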