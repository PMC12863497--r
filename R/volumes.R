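#' CT volume container
#'
#' A light container for a 3D scalar grid with voxel spacing and origin in
#' millimetres. `domain` records whether voxel values are Hounsfield units
#' (`"HU"`) or window-normalized values in \[0, 1\] (`"unit"`).
#'
#' @param voxels 3D numeric array.
#' @param spacing numeric length-3, voxel spacing in mm (strictly positive).
#' @param origin numeric length-3, position of voxel (1,1,1) in mm.
#' @param domain `"HU"` or `"unit"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      domain = c("HU", "unit")) {
  domain <- match.arg(domain)
  if (length(dim(voxels)) != 3L) stop_habitat("voxels must be a 3D array", "habitat_parameter_error")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_habitat("spacing must be 3 strictly positive values", "habitat_parameter_error")
  if (domain == "unit") {
    rng <- range(voxels)
    if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
      stop_habitat("unit-domain volume must lie in [0, 1]", "habitat_parameter_error")
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), domain = domain),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, domain %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$domain))
  invisible(x)
}

#' Binary lesion mask aligned to a CT volume
#'
#' @param voxels 3D logical (or 0/1) array.
#' @inheritParams ct_volume
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3L) stop_habitat("mask must be a 3D array", "habitat_parameter_error")
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1))) stop_habitat("mask values must be binary", "habitat_parameter_error")
    voxels <- array(voxels > 0, dim = dim(voxels))
  }
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<lesion_mask> %d x %d x %d voxels, %d foreground\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

check_aligned <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop_habitat("grids are not aligned (shape mismatch)", "habitat_alignment_error")
  invisible(TRUE)
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}. Spacing is carried in the NIfTI header
#' (`pixdim`); masks round-trip as integer 0/1 volumes.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param x a `ct_volume` or `lesion_mask`.
#' @return `read_nifti_volume` returns a `ct_volume` (HU domain);
#'   `read_nifti_mask` a `lesion_mask`; the writers return `path` invisibly.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)),
            spacing = RNifti::pixdim(img)[1:3], domain = "HU")
}

#' @rdname read_nifti_volume
#' @export
read_nifti_mask <- function(path) {
  img <- RNifti::readNifti(path)
  lesion_mask(array(as.numeric(img) > 0.5, dim = dim(img)),
              spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_nifti_volume
#' @export
write_nifti_volume <- function(x, path) {
  arr <- if (is.logical(x$voxels)) array(as.integer(x$voxels), dim = dim(x$voxels)) else x$voxels
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
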