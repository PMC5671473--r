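#' SUIT lobule codes of the cerebellar split
#'
#' The cerebellar gray is divided using the SUIT lobule labels: the
#' inferior portion (the reference region, spared of the off-target
#' binding frequently seen dorsally) is lobule codes 6, 8-28, 33, 34; the
#' superior portion is codes 1-5 and 7.
#'
#' @name suit_codes
#' @export
suit_inferior_indices <- c(6L, 8:28, 33L, 34L)

#' @rdname suit_codes
#' @export
suit_superior_indices <- c(1:5, 7L)

#' Split cerebellar gray into inferior and superior portions
#'
#' Builds binary masks of the inferior and superior cerebellar lobules from
#' the SUIT label volume, smooths each (default 8 mm FWHM), and assigns
#' every cerebellar-gray voxel of the structural segmentation to whichever
#' smoothed mask is strictly larger there. The smoothing guarantees that
#' segmentation voxels outside the SUIT coverage still receive a side. On a
#' tie (including both smoothed values zero) the voxel goes to the superior
#' side, keeping ambiguous voxels out of the reference denominator. The two
#' output masks partition the cerebellar gray exactly.
#'
#' @param aparc FreeSurfer-coded or remapped `taupvc_label` volume; its
#'   cerebellar gray is codes 8/47 (or the reserved post-remap code).
#' @param suit `taupvc_label` volume of SUIT lobule codes.
#' @param mask_fwhm_mm smoothing FWHM for the adjudication masks, mm.
#' @param inferior_indices,superior_indices SUIT lobule code sets.
#' @return List with logical arrays `inferior_mask`, `superior_mask`.
#' @export
split_cerebellum <- function(aparc, suit, mask_fwhm_mm = 8,
                             inferior_indices = suit_inferior_indices,
                             superior_indices = suit_superior_indices) {
  assert_same_grid(list(aparc = aparc, suit = suit))
  cg <- cerebellar_gray_mask(aparc)
  if (!any(cg)) stop("no cerebellar-gray voxels in the segmentation")
  if (all(suit$data == 0L)) stop("SUIT volume is empty")
  inf_s <- smooth_array(as.numeric_array(array(suit$data %in% inferior_indices,
                                               dim = dim(suit$data))),
                        mask_fwhm_mm, suit$voxel_size_mm)
  sup_s <- smooth_array(as.numeric_array(array(suit$data %in% superior_indices,
                                               dim = dim(suit$data))),
                        mask_fwhm_mm, suit$voxel_size_mm)
  inferior <- cg & (inf_s > sup_s)     # tie (incl. 0/0) -> superior
  superior <- cg & !inferior
  list(inferior_mask = inferior, superior_mask = superior)
}

cerebellar_gray_mask <- function(aparc) {
  array(aparc$data %in% c(CEREB_GRAY_FS_CODES,
                          taupvc_labels$reserved_cereb_gray),
        dim = dim(aparc$data))
}

#' Normalize PET to SUVR against a reference mask
#'
#' Divides the PET volume by the mean PET value over the reference mask
#' (the inferior cerebellar gray in the standard pipeline), producing a
#' standardized uptake value ratio image whose mean over the reference is
#' exactly 1. The divisor is recorded as attribute `reference_mean`.
#'
#' @param pet `taupvc_scalar` volume.
#' @param reference_mask logical array on the same grid.
#' @return A `taupvc_scalar` SUVR volume with attribute `reference_mean`.
#' @export
normalize_suvr <- function(pet, reference_mask) {
  stopifnot(inherits(pet, "taupvc_scalar"))
  if (!any(reference_mask)) stop("reference mask is empty")
  m <- mean(pet$data[reference_mask])
  if (!is.finite(m) || m <= 0)
    stop("reference mean must be positive, got ", m)
  out <- with_data(pet, pet$data / m)
  attr(out, "reference_mean") <- m
  out
}

#' Scan the reference region for hotspots and renormalize
#'
#' The inferior cerebellar gray occasionally contains isolated high-binding
#' clusters that would inflate the reference mean. This searches the
#' reference for connected clusters of voxels with SUVR above `threshold`
#' (default 1.6) containing strictly more than `min_cluster_voxels`
#' (default 500) voxels. Each qualifying cluster is removed from the
#' reference and given its own integer label counting up from `next_label`
#' (after the highest extra-cortical-hotspot label), and the SUVR is
#' renormalized to the cleaned reference mean. With no qualifying cluster
#' the inputs are returned unchanged.
#'
#' @param suvr `taupvc_scalar` SUVR volume.
#' @param inferior_mask logical reference mask.
#' @param threshold SUVR cut for hotspot voxels.
#' @param min_cluster_voxels cluster size cut (strict >).
#' @param next_label first integer label to assign.
#' @param connectivity component connectivity (default 26).
#' @return List: `hotspot_labels` (integer array, 0 outside hotspots),
#'   `inferior_mask` (cleaned), `suvr` (renormalized), `n_hotspots`.
#' @export
scan_reference_hotspots <- function(suvr, inferior_mask, threshold = 1.6,
                                    min_cluster_voxels = 500L, next_label,
                                    connectivity = 26L) {
  stopifnot(inherits(suvr, "taupvc_scalar"))
  hot <- inferior_mask & (suvr$data > threshold)
  labels <- array(0L, dim = dim(suvr$data))
  if (any(hot)) {
    fc <- filter_clusters(hot, min_cluster_voxels, strict = TRUE,
                          connectivity = connectivity)
    k <- length(fc$sizes)
    if (k > 0L) {
      pos <- fc$labels > 0L
      labels[pos] <- fc$labels[pos] + (next_label - 1L)
      cleaned <- inferior_mask & !pos
      if (!any(cleaned)) stop("reference region empty after hotspot removal")
      ref_mean_old <- attr(suvr, "reference_mean")
      new_mean <- mean(suvr$data[cleaned])
      out <- with_data(suvr, suvr$data / new_mean)
      attr(out, "reference_mean") <-
        if (is.null(ref_mean_old)) new_mean else ref_mean_old * new_mean
      return(list(hotspot_labels = labels, inferior_mask = cleaned,
                  suvr = out, n_hotspots = k))
    }
  }
  list(hotspot_labels = labels, inferior_mask = inferior_mask, suvr = suvr,
       n_hotspots = 0L)
}
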