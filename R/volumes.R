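#' Volume containers
#'
#' All pipeline stages operate on simple S3 volume objects: a 3D array plus
#' the grid it lives on (voxel sizes in mm and a 4x4 voxel-to-world affine).
#' Three flavours exist, differing only in the invariants enforced on the
#' data: `taupvc_label` (non-negative integers, 0 = unassigned background),
#' `taupvc_prob` (values in \[0, 1\]) and `taupvc_scalar` (finite reals).
#' All inputs to a pipeline run must share one grid; no resampling is done
#' here -- volumes are expected to be co-registered and resliced upstream.
#'
#' @param data 3D numeric array.
#' @param voxel_size_mm length-3 positive numeric, voxel edge lengths in mm.
#' @param affine 4x4 voxel-to-world transform. Defaults to a scaled identity
#'   consistent with `voxel_size_mm`.
#' @return A volume object: a list with elements `data`, `voxel_size_mm`,
#'   `affine`, of class `c("taupvc_label"|"taupvc_prob"|"taupvc_scalar",
#'   "taupvc_volume")`.
#' @name volumes
NULL

new_volume <- function(data, voxel_size_mm, affine, subclass) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dims")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(!is.finite(voxel_size_mm)) || any(voxel_size_mm <= 0))
    stop("voxel sizes must be strictly positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (!is.finite(det(affine)) || abs(det(affine)) < .Machine$double.eps)
    stop("affine must be invertible")
  structure(list(data = data, voxel_size_mm = voxel_size_mm, affine = affine),
            class = c(subclass, "taupvc_volume"))
}

#' @rdname volumes
#' @export
labeled_volume <- function(data, voxel_size_mm = c(1, 1, 1), affine = NULL) {
  d <- as.numeric(data)
  if (any(abs(d - round(d)) >= 1e-6))
    stop("label volume contains non-integer values")
  d <- round(d)
  if (any(d < 0))
    stop("label volume contains negative values")
  arr <- array(as.integer(d), dim = dim(data))
  new_volume(arr, voxel_size_mm, affine, "taupvc_label")
}

#' @rdname volumes
#' @export
probability_volume <- function(data, voxel_size_mm = c(1, 1, 1), affine = NULL) {
  d <- as.numeric(data)
  if (any(!is.finite(d)))
    stop("probability volume contains non-finite values")
  if (any(d < -1e-6) || any(d > 1 + 1e-6))
    stop("probability volume has values outside [0, 1]: range ",
         min(d), " .. ", max(d))
  arr <- array(pmin(pmax(d, 0), 1), dim = dim(data))
  new_volume(arr, voxel_size_mm, affine, "taupvc_prob")
}

#' @rdname volumes
#' @export
scalar_volume <- function(data, voxel_size_mm = c(1, 1, 1), affine = NULL) {
  d <- as.numeric(data)
  if (any(!is.finite(d)))
    stop("scalar volume contains non-finite values")
  new_volume(array(d, dim = dim(data)), voxel_size_mm, affine, "taupvc_scalar")
}

#' @export
print.taupvc_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, %.3g x %.3g x %.3g mm\n",
              class(x)[1L], paste(dim(x$data), collapse = " x "),
              x$voxel_size_mm[1L], x$voxel_size_mm[2L], x$voxel_size_mm[3L]))
  invisible(x)
}

#' @export
dim.taupvc_volume <- function(x) dim(x$data)

# Rebuild a volume on the same grid with new data.
with_data <- function(vol, data, subclass = class(vol)[1L]) {
  new_volume(array(data, dim = dim(vol$data)), vol$voxel_size_mm, vol$affine,
             subclass)
}

is_volume <- function(x) inherits(x, "taupvc_volume")

#' Assert that volumes share one grid
#'
#' Every stage of the pipeline assumes all inputs are on the same voxel
#' grid. This checks shapes for equality and affines element-wise within an
#' absolute tolerance of 1e-4, and reports which volume and which field
#' differs. Resampling between grids is out of scope by design.
#'
#' @param volumes list of at least two volume objects.
#' @param tol absolute per-element tolerance for the affine comparison.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
assert_same_grid <- function(volumes, tol = 1e-4) {
  stopifnot(is.list(volumes), length(volumes) >= 2L)
  nm <- names(volumes)
  if (is.null(nm)) nm <- paste0("volume ", seq_along(volumes))
  ref <- volumes[[1L]]
  for (i in seq_along(volumes)[-1L]) {
    v <- volumes[[i]]
    if (!identical(dim(v$data), dim(ref$data)))
      stop(sprintf("grid mismatch: %s has shape (%s) but %s has shape (%s)",
                   nm[i], paste(dim(v$data), collapse = ","),
                   nm[1L], paste(dim(ref$data), collapse = ",")))
    d <- abs(v$affine - ref$affine)
    if (any(d > tol)) {
      ij <- which(d == max(d), arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "grid mismatch: %s affine[%d,%d] = %.6g differs from %s (%.6g) by %.3g",
        nm[i], ij[1L], ij[2L], v$affine[ij[1L], ij[2L]],
        nm[1L], ref$affine[ij[1L], ij[2L]], max(d)))
    }
  }
  invisible(TRUE)
}
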