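#' Split the choroid plexus into high- and low-binding ROIs
#'
#' The choroid plexus shows a bimodal distribution of tracer binding: the
#' ventral portion next to the hippocampus binds strongly (off-target) and
#' the dorsal portion weakly. Treating it as one homogeneous ROI degrades
#' partial volume correction of the hippocampus, so it is split around the
#' reference level:
#'
#' 1. Seed components: connected components (26-connectivity) of choroid
#'    voxels with SUVR <= `suvr_threshold` (low) or > `suvr_threshold`
#'    (high) containing at least `min_cluster_voxels` voxels.
#' 2. Both seed masks are Gaussian-smoothed (`mask_fwhm_mm`, default 8 mm).
#' 3. Every choroid voxel not in a seed is assigned high where the smoothed
#'    high seed exceeds the smoothed low seed, low where the reverse holds,
#'    and high on an exact tie.
#'
#' If neither class yields a seed component the whole choroid is labeled by
#' direct thresholding with a warning (the smoothing adjudication carries
#' no information in that case). The result is always a total partition of
#' the choroid mask into labels 79 (high) and 80 (low).
#'
#' @param suvr `taupvc_scalar` SUVR volume.
#' @param choroid_mask logical array of choroid plexus voxels.
#' @param suvr_threshold split level in SUVR units (default 1, the
#'   reference level).
#' @param min_cluster_voxels seed contiguity cut, inclusive (default 100).
#' @param mask_fwhm_mm adjudication smoothing FWHM.
#' @param connectivity component connectivity.
#' @return Integer array: 79 on high-binding, 80 on low-binding choroid
#'   voxels, 0 elsewhere.
#' @export
split_choroid <- function(suvr, choroid_mask, suvr_threshold = 1,
                          min_cluster_voxels = 100L, mask_fwhm_mm = 8,
                          connectivity = 26L) {
  stopifnot(inherits(suvr, "taupvc_scalar"))
  if (!any(choroid_mask)) stop("choroid mask is empty")
  hi <- taupvc_labels$choroid_high
  lo <- taupvc_labels$choroid_low
  out <- array(0L, dim = dim(suvr$data))

  seed_low <- filter_clusters(choroid_mask & suvr$data <= suvr_threshold,
                              min_cluster_voxels, strict = FALSE,
                              connectivity = connectivity)$labels > 0L
  seed_high <- filter_clusters(choroid_mask & suvr$data > suvr_threshold,
                               min_cluster_voxels, strict = FALSE,
                               connectivity = connectivity)$labels > 0L

  if (!any(seed_low) && !any(seed_high)) {
    warning("no choroid seed component of either class; ",
            "falling back to direct SUVR thresholding")
    out[choroid_mask] <- ifelse(suvr$data[choroid_mask] > suvr_threshold,
                                hi, lo)
    return(out)
  }

  out[seed_high] <- hi
  out[seed_low] <- lo
  rest <- choroid_mask & out == 0L
  if (any(rest)) {
    sm_hi <- smooth_array(as.numeric_array(seed_high), mask_fwhm_mm,
                          suvr$voxel_size_mm)
    sm_lo <- smooth_array(as.numeric_array(seed_low), mask_fwhm_mm,
                          suvr$voxel_size_mm)
    # tie (incl. both zero) -> high: overestimating off-target choroid
    # signal protects the hippocampal estimate better than the reverse
    out[rest] <- ifelse(sm_lo[rest] > sm_hi[rest], lo, hi)
  }
  out
}
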