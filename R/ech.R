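#' Build the extra-cortical-hotspot searchable region
#'
#' Off-target binding in skull, meninges and dura ("extra-cortical
#' hotspots", ECH) must be modeled as ROIs or it bleeds into adjacent
#' cortex under the PSF. The searchable region where hotspots are looked
#' for is built from the tissue-probability maps:
#'
#' * a brain mask (nonzero voxels of the segmentation) is smoothed to the
#'   scanner resolution;
#' * a bone mask (`c4 + c5 > 0.5`) is smoothed likewise;
#' * CSF-probability voxels (`c3 > 0.5`) that are closer to bone than to
#'   brain — operationalized as smoothed-bone > smoothed-brain — join the
#'   searchable region, because the CSF class also captures dura and soft
#'   tissue away from cortex;
#' * any voxel with `c4 + c5 > 0.3` joins unconditionally.
#'
#' @param c3,c4,c5 `taupvc_prob` volumes (CSF, skull, meninges).
#' @param aparc `taupvc_label` segmentation volume (raw or remapped).
#' @param psf_fwhm_mm scanner resolution FWHM in mm (scalar or length 3).
#' @param c45_mask_cut bone-mask probability cut (default 0.5).
#' @param c3_probability_cut CSF probability cut (default 0.5).
#' @param c45_direct_cut unconditional-inclusion cut on c4+c5 (default 0.3).
#' @return Logical 3D array.
#' @export
build_searchable_roi <- function(c3, c4, c5, aparc, psf_fwhm_mm,
                                 c3_probability_cut = 0.5,
                                 c45_mask_cut = 0.5,
                                 c45_direct_cut = 0.3) {
  assert_same_grid(list(c3 = c3, c4 = c4, c5 = c5, aparc = aparc))
  c45 <- c4$data + c5$data
  brain <- as.numeric_array(array(aparc$data != 0L, dim = dim(aparc$data)))
  bone <- as.numeric_array(array(c45 > c45_mask_cut, dim = dim(c45)))
  brain_s <- smooth_array(brain, psf_fwhm_mm, aparc$voxel_size_mm)
  bone_s <- smooth_array(bone, psf_fwhm_mm, aparc$voxel_size_mm)
  (c3$data > c3_probability_cut & bone_s > brain_s) | (c45 > c45_direct_cut)
}

#' Detect extra-cortical hotspots
#'
#' Within the searchable region, voxels with SUVR above `threshold`
#' (default 1.6) are probable hotspot voxels; their connected components
#' with strictly more than `min_cluster_voxels` voxels (default 500)
#' become individual ROIs, labeled `first_label` (default 85), counting
#' up. Labels are assigned in a deterministic order: descending cluster
#' size, ties by the smallest (x, y, z) bounding-box corner. Sub-threshold
#' components are discarded and their voxels left unassigned for the
#' downstream tissue classification.
#'
#' @param suvr `taupvc_scalar` SUVR volume.
#' @param searchable logical array from [build_searchable_roi()].
#' @param threshold SUVR cut (default 1.6; 1.3 and 1.9 are the
#'   conventional alternatives).
#' @param min_cluster_voxels size cut, strict (default 500).
#' @param first_label first ROI label (default 85).
#' @param connectivity component connectivity (default 26).
#' @return List: `labels` (integer array, 0 off-hotspot), `clusters`
#'   (data frame: label, n_voxels, mean_suvr), `searchable` (the input
#'   mask, for reporting).
#' @export
detect_ech <- function(suvr, searchable, threshold = 1.6,
                       min_cluster_voxels = 500L,
                       first_label = taupvc_labels$ech_first,
                       connectivity = 26L) {
  stopifnot(inherits(suvr, "taupvc_scalar"))
  probable <- searchable & (suvr$data > threshold)
  fc <- filter_clusters(probable, min_cluster_voxels, strict = TRUE,
                        connectivity = connectivity)
  k <- length(fc$sizes)
  labels <- array(0L, dim = dim(suvr$data))
  if (k > 0L) {
    pos <- fc$labels > 0L
    labels[pos] <- fc$labels[pos] + (first_label - 1L)
  }
  clusters <- data.frame(
    label = if (k) first_label + seq_len(k) - 1L else integer(0),
    n_voxels = as.integer(fc$sizes),
    mean_suvr = if (k) vapply(seq_len(k), function(i)
      mean(suvr$data[fc$labels == i]), numeric(1)) else numeric(0))
  list(labels = labels, clusters = clusters, searchable = searchable)
}
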