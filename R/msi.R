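neighbor_offsets <- function(connectivity) {
  if (connectivity == 6) {
    list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (connectivity == 26) {
    offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
    # one representative per unordered direction pair
    keep <- offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 | (offs$dy == 0 & offs$dx > 0)))
    lapply(which(keep), function(i) as.numeric(offs[i, ]))
  } else stop_habitat("connectivity must be 6 or 26", "habitat_parameter_error")
}

#' Multi-regional Spatial Interaction (MSI) matrix
#'
#' Counts co-occurrences of subregion labels over neighboring voxel pairs.
#' For every unordered pair of neighbors (face adjacency by default) with at
#' least one voxel inside the mask, the count `N(a, b)` of the two labels is
#' incremented once; the matrix is stored symmetrically (`N(i, j) = N(j, i)`
#' for `i != j`). Pairs lying wholly in the background are excluded, so
#' `N(0, 0) = 0` by construction: the matrix describes the lesion and its
#' immediate interface, not the surrounding lung. Diagonal entries reflect
#' subregion volume; off-diagonal entries quantify inter-subregion adjacency.
#'
#' @param labelmap a `subregion_labelmap` (or 3D integer array with 0 =
#'   background and labels 1..k).
#' @param connectivity 6 (face neighbors, default) or 26.
#' @param k number of subregions; taken from the labelmap when available.
#' @return A `(k+1) x (k+1)` integer matrix of class `msi_matrix` with
#'   dimnames `0..k` and attributes `connectivity` and `voxel_counts` (in-mask
#'   voxel count per label 1..k).
#' @export
build_msi_matrix <- function(labelmap, connectivity = 6, k = NULL) {
  if (inherits(labelmap, "subregion_labelmap")) {
    if (is.null(k)) k <- labelmap$k
    lab <- labelmap$labels
  } else lab <- labelmap
  if (length(dim(lab)) != 3L) stop_habitat("label map must be 3D", "habitat_parameter_error")
  if (is.null(k)) k <- max(lab)
  if (k < 1) stop_habitat("label map needs at least one subregion", "habitat_parameter_error")
  if (any(lab < 0L) || any(lab > k))
    stop_habitat("labels outside {0..k}", "habitat_label_domain_error")
  if (!any(lab > 0L)) stop_habitat("no in-mask voxel", "habitat_empty_mask_error")

  d <- dim(lab)
  s <- k + 1L
  counts <- matrix(0, s, s)
  for (off in neighbor_offsets(connectivity)) {
    ar <- br <- vector("list", 3)
    skip <- FALSE
    for (ax in 1:3) {
      o <- off[ax]
      if (d[ax] <= abs(o)) { skip <- TRUE; break }
      ar[[ax]] <- if (o >= 0) seq_len(d[ax] - o) else seq.int(1 - o, d[ax])
      br[[ax]] <- ar[[ax]] + o
    }
    if (skip) next
    a <- lab[ar[[1]], ar[[2]], ar[[3]], drop = FALSE]
    b <- lab[br[[1]], br[[2]], br[[3]], drop = FALSE]
    keep <- a > 0L | b > 0L
    if (!any(keep)) next
    av <- a[keep]; bv <- b[keep]
    idx <- av * s + bv + 1L
    counts <- counts + matrix(tabulate(idx, nbins = s * s), s, s, byrow = TRUE)
  }
  m <- counts + t(counts)
  diag(m) <- diag(counts)
  dimnames(m) <- list(0:k, 0:k)
  structure(m, class = c("msi_matrix", "matrix"),
            connectivity = connectivity,
            voxel_counts = tabulate(lab[lab > 0L], nbins = k))
}

#' @export
print.msi_matrix <- function(x, ...) {
  cat(sprintf("<msi_matrix> %dx%d, connectivity %d\n", nrow(x), ncol(x),
              attr(x, "connectivity") %||% NA))
  print(unclass(x)[,])
  invisible(x)
}

ratio0 <- function(num, den) ifelse(den > 0, num / den, 0)

#' First-order MSI features
#'
#' The canonical 33-feature enumeration over a 4x4 MSI matrix (three
#' subregions plus background). With `B` the total inter-region border count
#' (sum of the upper off-diagonal triangle) and `V_i` the in-mask voxel count
#' of subregion `i`: volume proportions (3), background interface fraction
#' (1), border proportions for the 6 unordered label pairs (6), conditional
#' border proportions for the 12 ordered pairs (12), per-region boundary
#' shares (4), interior ratios (3), present-pair count (1), pair entropy (1),
#' and max/min volume proportion (2). Ratios with zero denominators follow
#' the 0/0 = 0 convention; affected features are flagged in the `degenerate`
#' attribute.
#'
#' @param m an `msi_matrix` with k = 3.
#' @param voxel_counts in-mask voxel counts of labels 1..3; defaults to the
#'   counts recorded by [build_msi_matrix()].
#' @return Named numeric vector of length 33 with a logical `degenerate`
#'   attribute.
#' @export
first_order_features <- function(m, voxel_counts = attr(m, "voxel_counts")) {
  if (!is.matrix(m) || nrow(m) != 4L || ncol(m) != 4L)
    stop_habitat("first-order features are defined for a 4x4 MSI matrix (k = 3)",
                 "habitat_parameter_error")
  if (is.null(voxel_counts))
    stop_habitat("voxel_counts missing: build the matrix with build_msi_matrix()",
                 "habitat_parameter_error")
  N <- unclass(m)
  labs <- 0:3
  B <- sum(N[upper.tri(N)])
  V <- as.numeric(voxel_counts)
  out <- c()
  deg <- c()
  push <- function(name, value, flag = FALSE) {
    out[[name]] <<- value
    deg[[name]] <<- flag
  }
  for (i in 1:3)
    push(paste0("volume_proportion_", i), ratio0(V[i], sum(V)), sum(V) == 0)
  push("background_interface_fraction", ratio0(sum(N[1, 2:4]), B), B == 0)
  pairs <- list(c(0, 1), c(0, 2), c(0, 3), c(1, 2), c(1, 3), c(2, 3))
  for (p in pairs)
    push(sprintf("MSI_border_proportion_%d_%d", p[1], p[2]),
         ratio0(N[p[1] + 1, p[2] + 1], B), B == 0)
  for (i in labs) for (j in labs) {
    if (i == j) next
    den <- sum(N[i + 1, setdiff(labs, i) + 1])
    push(sprintf("MSI_cond_border_proportion_%d_%d", i, j),
         ratio0(N[i + 1, j + 1], den), den == 0)
  }
  for (i in labs)
    push(paste0("region_boundary_share_", i),
         ratio0(sum(N[i + 1, setdiff(labs, i) + 1]), B), B == 0)
  for (i in 1:3) {
    den <- N[i + 1, i + 1] + sum(N[i + 1, setdiff(labs, i) + 1])
    push(paste0("interior_ratio_", i), ratio0(N[i + 1, i + 1], den), den == 0)
  }
  offd <- N[upper.tri(N)]
  push("present_pair_count", sum(offd > 0))
  p <- offd[offd > 0] / B
  push("pair_entropy", if (B > 0) -sum(p * log2(p)) else 0, B == 0)
  vp <- if (sum(V) > 0) V / sum(V) else rep(0, 3)
  push("max_volume_proportion", max(vp), sum(V) == 0)
  push("min_volume_proportion", min(vp), sum(V) == 0)
  res <- unlist(out)
  attr(res, "degenerate") <- unlist(deg)
  res
}

#' Second-order MSI features
#'
#' Co-occurrence statistics over the normalized matrix `P = N / sum(N)` with
#' integer labels 0..k used as gray levels: contrast, correlation, energy,
#' homogeneity and entropy. A degenerate marginal (zero row/column standard
#' deviation) defines correlation as 0 and is flagged.
#'
#' @param m an `msi_matrix`.
#' @return Named numeric vector of length 5 with a logical `degenerate`
#'   attribute.
#' @export
second_order_features <- function(m) {
  N <- unclass(m)
  tot <- sum(N)
  if (tot <= 0) stop_habitat("empty MSI matrix", "habitat_parameter_error")
  P <- N / tot
  k1 <- nrow(P)
  i <- matrix(0:(k1 - 1), k1, k1)
  j <- t(i)
  mu_r <- sum(i * P); mu_c <- sum(j * P)
  sd_r <- sqrt(sum((i - mu_r)^2 * P)); sd_c <- sqrt(sum((j - mu_c)^2 * P))
  degenerate_corr <- sd_r * sd_c <= 0
  corr <- if (degenerate_corr) 0 else sum((i - mu_r) * (j - mu_c) * P) / (sd_r * sd_c)
  pn0 <- P[P > 0]
  res <- c(MSI_contrast = sum((i - j)^2 * P),
           MSI_correlation = corr,
           MSI_energy = sum(P^2),
           MSI_homogeneity = sum(P / (1 + abs(i - j))),
           MSI_entropy = -sum(pn0 * log2(pn0)))
  attr(res, "degenerate") <- c(MSI_contrast = FALSE,
                               MSI_correlation = degenerate_corr,
                               MSI_energy = FALSE, MSI_homogeneity = FALSE,
                               MSI_entropy = FALSE)
  res
}

#' Full 38-entry MSI feature vector for one lesion
#'
#' Composes [build_msi_matrix()], [first_order_features()] and
#' [second_order_features()] into a single named vector with a stable name
#' ordering (33 first-order followed by 5 second-order features).
#'
#' @inheritParams build_msi_matrix
#' @return Named numeric vector of length 38 (attribute `degenerate` carries
#'   per-feature 0/0 flags).
#' @export
msi_feature_vector <- function(labelmap, connectivity = 6, k = NULL) {
  m <- build_msi_matrix(labelmap, connectivity = connectivity, k = k)
  f1 <- first_order_features(m)
  f2 <- second_order_features(m)
  res <- c(f1, f2)
  attr(res, "degenerate") <- c(attr(f1, "degenerate"), attr(f2, "degenerate"))
  res
}

#' MSI feature table for a list of label maps
#'
#' @param labelmaps named list of `subregion_labelmap`s (one per lesion).
#' @param connectivity 6 or 26.
#' @param k number of subregions shared by all label maps (default: from each
#'   labelmap).
#' @return data.frame, one row per lesion, 38 `MSI`/feature columns plus
#'   `case_id`.
#' @export
msi_feature_table <- function(labelmaps, connectivity = 6, k = NULL) {
  rows <- lapply(labelmaps, function(lm) msi_feature_vector(lm, connectivity, k = k))
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- cbind(case_id = names(labelmaps) %||% sprintf("case_%03d", seq_along(labelmaps)),
               tab)
  rownames(tab) <- NULL
  tab
}
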