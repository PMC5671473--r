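#' Gaussian PSF smoothing
#'
#' Separable 3D Gaussian convolution, the single smoothing primitive shared
#' by every pipeline stage (mask adjudication, the extra-cortical-hotspot
#' searchable region, the GTM transfer matrix and the calculated pre-PVC
#' image). Sharing one implementation guarantees that the forward model and
#' the residual diagnostic use an identical kernel.
#'
#' The kernel is specified by its full width at half maximum (FWHM) in mm,
#' the convention used for PET scanner resolution; sigma = FWHM /
#' (2 sqrt(2 ln 2)), converted to voxels per axis via the voxel sizes.
#' Boundaries are zero-padded: activity outside the field of view is
#' assumed zero, matching the GTM convention that unlabeled space has zero
#' activity. The discrete kernel is normalized to unit sum, so the total
#' image sum is conserved up to boundary loss. An axis whose FWHM is below
#' half a voxel is under-resolved by the grid and degenerates to the
#' identity along that axis (with a warning).
#'
#' @param volume a volume object (masks are coerced to 0/1 reals first) or
#'   a plain 3D array (then `voxel_size_mm` must be given).
#' @param fwhm_mm positive scalar (isotropic) or length-3 FWHM in mm.
#' @param voxel_size_mm voxel sizes, only needed for plain-array input.
#' @return A volume of class `taupvc_scalar` on the same grid (or a plain
#'   array for plain-array input).
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm = NULL) {
  if (is_volume(volume)) {
    out <- smooth_array(as.numeric_array(volume$data), fwhm_mm,
                        volume$voxel_size_mm)
    new_volume(out, volume$voxel_size_mm, volume$affine, "taupvc_scalar")
  } else {
    if (is.null(voxel_size_mm))
      stop("voxel_size_mm is required for plain-array input")
    smooth_array(as.numeric_array(volume), fwhm_mm, voxel_size_mm)
  }
}

as.numeric_array <- function(x) {
  if (is.logical(x) || is.integer(x)) array(as.numeric(x), dim = dim(x)) else x
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  w / sum(w)
}

smooth_array <- function(x, fwhm_mm, voxel_size_mm) {
  stopifnot(length(dim(x)) == 3L)
  fwhm_mm <- rep_len(as.numeric(fwhm_mm), 3L)
  if (any(!is.finite(fwhm_mm)) || any(fwhm_mm <= 0))
    stop("FWHM must be strictly positive")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  fwhm_vox <- fwhm_mm / voxel_size_mm
  degenerate <- fwhm_vox < 0.5
  if (any(degenerate))
    warning("FWHM below half a voxel on axis ",
            paste(which(degenerate), collapse = ", "),
            "; smoothing degenerates to the identity there")
  for (axis in 1:3) {
    if (degenerate[axis]) next
    w <- gaussian_kernel_1d(fwhm_vox[axis] * FWHM_TO_SIGMA)
    x <- conv_axis(x, w, axis)
  }
  x
}

# 1D zero-padded convolution along one axis of a 3D array, done as a sum of
# weighted in-bounds shifts (vectorized; no per-voxel loop).
conv_axis <- function(x, w, axis) {
  n <- dim(x)[axis]
  r <- (length(w) - 1L) %/% 2L
  out <- array(0, dim = dim(x))
  idx <- list(TRUE, TRUE, TRUE)
  for (k in seq_along(w)) {
    off <- k - 1L - r
    if (off >= 0L) {
      if (off >= n) next
      dst <- seq_len(n - off)
      src <- dst + off
    } else {
      if (-off >= n) next
      src <- seq_len(n + off)
      dst <- src - off
    }
    id <- idx; id[[axis]] <- dst
    is <- idx; is[[axis]] <- src
    piece <- do.call(`[`, c(list(x), is, list(drop = FALSE)))
    cur <- do.call(`[`, c(list(out), id, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), id, list(cur + w[k] * piece)))
  }
  out
}
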