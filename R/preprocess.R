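#' CT display-window specification
#'
#' Defaults follow the standard lung window used for nodule analysis:
#' width 1500 HU, level -600 HU, i.e. the interval \[-1350, 150\] HU.
#'
#' @param width window width in HU (> 0).
#' @param level window level (centre) in HU.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width = 1500, level = -600) {
  if (!is.numeric(width) || width <= 0)
    stop_habitat("window width must be positive", "habitat_parameter_error")
  structure(list(width = width, level = level), class = "window_spec")
}

#' Window/level normalization of a CT volume
#'
#' Clips HU values to the window \[level - width/2, level + width/2\] and maps
#' them affinely onto \[0, 1\] (min-max normalization with saturation). The
#' window centre maps to 0.5.
#'
#' @param vol a `ct_volume` in HU domain.
#' @param w a [window_spec()].
#' @return A `ct_volume` with `domain = "unit"`.
#' @export
window_normalize <- function(vol, w = window_spec()) {
  stopifnot(inherits(vol, "ct_volume"))
  if (vol$domain != "HU")
    stop_habitat("window_normalize expects an HU-domain volume", "habitat_parameter_error")
  lo <- w$level - w$width / 2
  u <- (pmin(pmax(vol$voxels, lo), lo + w$width) - lo) / w$width
  ct_volume(array(u, dim = dim(vol$voxels)), vol$spacing, vol$origin, domain = "unit")
}

#' Resample a volume or mask to a target spacing
#'
#' Output dimensions are `round(dim * spacing / target)` per axis. Intensities
#' are interpolated trilinearly; masks (and label maps) must use
#' `method = "nearest"`, which preserves the label set.
#'
#' @param vol a `ct_volume` or `lesion_mask`.
#' @param target_mm numeric length 1 or 3; target spacing in mm.
#' @param method `"linear"` (intensities) or `"nearest"` (labels/masks).
#' @return Object of the same class on the new grid.
#' @export
resample_isotropic <- function(vol, target_mm = 1,
                               method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (length(target_mm) == 1L) target_mm <- rep(target_mm, 3L)
  if (any(target_mm <= 0))
    stop_habitat("target spacing must be positive", "habitat_parameter_error")
  arr <- vol$voxels
  is_mask <- inherits(vol, "lesion_mask")
  if (is_mask) method <- "nearest"
  d <- dim(arr)
  sp <- vol$spacing
  nd <- pmax(1L, as.integer(round(d * sp / target_mm)))
  if (all(nd == d) && all(abs(sp - target_mm) < 1e-12)) return(vol)

  # world coordinates of output voxel centres expressed in input voxel index
  # space (1-based); grids share the corner of voxel (1,1,1).
  src <- lapply(1:3, function(a) ((seq_len(nd[a]) - 1) * target_mm[a]) / sp[a] + 1)
  if (method == "nearest") {
    idx <- lapply(1:3, function(a) pmin(pmax(round(src[[a]]), 1L), d[a]))
    out <- (if (is_mask) arr * 1 else arr)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    out <- array(out, dim = nd)
  } else {
    f <- lapply(1:3, function(a) pmin(pmax(src[[a]], 1), d[a]))
    l0 <- lapply(1:3, function(a) pmin(floor(f[[a]]), d[a] - ifelse(d[a] > 1, 1, 0)))
    fr <- lapply(1:3, function(a) f[[a]] - l0[[a]])
    l1 <- lapply(1:3, function(a) pmin(l0[[a]] + 1, d[a]))
    out <- array(0, dim = nd)
    for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
      wx <- if (cx == 0) 1 - fr[[1]] else fr[[1]]
      wy <- if (cy == 0) 1 - fr[[2]] else fr[[2]]
      wz <- if (cz == 0) 1 - fr[[3]] else fr[[3]]
      ix <- if (cx == 0) l0[[1]] else l1[[1]]
      iy <- if (cy == 0) l0[[2]] else l1[[2]]
      iz <- if (cz == 0) l0[[3]] else l1[[3]]
      w3 <- outer(outer(wx, wy), wz)
      out <- out + w3 * arr[ix, iy, iz, drop = FALSE]
    }
  }
  if (is_mask) {
    lesion_mask(array(out > 0.5, dim = nd), spacing = target_mm,
                origin = vol$origin)
  } else {
    ct_volume(out, spacing = target_mm, origin = vol$origin, domain = vol$domain)
  }
}

#' Crop a volume and mask to the lesion bounding box
#'
#' The bounding box of the mask is expanded by `margin_vox` voxels per side
#' and clipped to the image extent; no padding is added.
#'
#' @param vol a `ct_volume`.
#' @param mask a `lesion_mask` aligned to `vol`.
#' @param margin_vox non-negative integer margin, in voxels.
#' @return `list(volume = , mask = )` on the cropped grid.
#' @export
crop_voi <- function(vol, mask, margin_vox = 2L) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "lesion_mask"))
  check_aligned(vol, mask)
  if (!any(mask$voxels)) stop_habitat("mask is empty", "habitat_empty_mask_error")
  if (margin_vox < 0) stop_habitat("margin must be >= 0", "habitat_parameter_error")
  d <- dim(mask$voxels)
  w <- which(mask$voxels, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - margin_vox, 1L)
  hi <- pmin(apply(w, 2, max) + margin_vox, d)
  v2 <- vol$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  m2 <- mask$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  origin2 <- vol$origin + (lo - 1) * vol$spacing
  list(volume = ct_volume(v2, vol$spacing, origin2, vol$domain),
       mask = lesion_mask(m2, vol$spacing, origin2))
}

#' Dice similarity coefficient between two masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined to agree perfectly
#' (Dice = 1), a documented convention.
#'
#' @param a,b `lesion_mask` objects on the same grid.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "lesion_mask"), inherits(b, "lesion_mask"))
  check_aligned(a, b)
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) return(1)
  2 * sum(a$voxels & b$voxels) / (na + nb)
}
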