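#' Read a NIfTI volume
#'
#' Reads a 3D NIfTI-1 file and validates it against the expected volume
#' type. Label volumes must hold integer values (float-stored integers are
#' tolerance-rounded, |x - round(x)| < 1e-6); probability volumes must lie
#' in \[0, 1\] within 1e-6.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param expect one of `"label"`, `"probability"`, `"scalar"`.
#' @return A [labeled_volume()], [probability_volume()] or
#'   [scalar_volume()].
#' @export
read_volume <- function(path, expect = c("scalar", "label", "probability")) {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img <- img[, , , 1L, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  vox <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  arr <- array(as.numeric(img), dim = d)
  switch(expect,
    label = labeled_volume(arr, vox, aff),
    probability = probability_volume(arr, vox, aff),
    scalar = scalar_volume(arr, vox, aff))
}

#' Write a volume to NIfTI
#'
#' Label volumes are written as int16 (int32 when any label exceeds 32767)
#' so that a read/write round trip reproduces labels bit-exactly; scalar
#' and probability volumes are written as float32.
#'
#' @param volume a volume object.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_volume(volume))
  dtype <- if (inherits(volume, "taupvc_label")) {
    if (max(volume$data) > 32767L) "int32" else "int16"
  } else "float"
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$voxel_size_mm
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}
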