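#' The ten standard ROI configurations
#'
#' Declarative presets for the ROI-construction variants used to compare
#' partial-volume-correction fits:
#'
#' 1. anatomical ROIs plus the whole choroid plexus; everything undefined
#'    assumed zero activity
#' 2. choroid plexus split into high/low binding ROIs
#' 3. as 2, plus per-subject extra-cortical hotspots (threshold 1.6)
#' 4. as 2, plus one CSF ROI and one bone+meninges ROI, no hotspots
#' 5. as 3, plus the CSF and bone+meninges ROIs
#' 6. as 4, with CSF and bone+meninges each split at SUVR 1
#' 7. as 5, with CSF and bone+meninges each split at SUVR 1
#' 8. as 7, plus the reference-region hotspot scan
#' 9. as 8, with hotspot threshold 1.3
#' 10. as 8, with hotspot threshold 1.9
#'
#' @param config_id integer 1-10.
#' @return A `roi_config` list with fields `config_id`, `split_choroid`,
#'   `include_ech`, `ech_threshold`, `include_tissue`, `split_tissue`,
#'   `scan_reference`.
#' @export
roi_config <- function(config_id) {
  config_id <- as.integer(config_id)
  stopifnot(length(config_id) == 1L, config_id >= 1L, config_id <= 10L)
  p <- list(
    list(FALSE, FALSE, 1.6, FALSE, FALSE, FALSE),
    list(TRUE,  FALSE, 1.6, FALSE, FALSE, FALSE),
    list(TRUE,  TRUE,  1.6, FALSE, FALSE, FALSE),
    list(TRUE,  FALSE, 1.6, TRUE,  FALSE, FALSE),
    list(TRUE,  TRUE,  1.6, TRUE,  FALSE, FALSE),
    list(TRUE,  FALSE, 1.6, TRUE,  TRUE,  FALSE),
    list(TRUE,  TRUE,  1.6, TRUE,  TRUE,  FALSE),
    list(TRUE,  TRUE,  1.6, TRUE,  TRUE,  TRUE),
    list(TRUE,  TRUE,  1.3, TRUE,  TRUE,  TRUE),
    list(TRUE,  TRUE,  1.9, TRUE,  TRUE,  TRUE))[[config_id]]
  structure(list(config_id = config_id, split_choroid = p[[1L]],
                 include_ech = p[[2L]], ech_threshold = p[[3L]],
                 include_tissue = p[[4L]], split_tissue = p[[5L]],
                 scan_reference = p[[6L]]),
            class = "roi_config")
}

#' Default pipeline parameters
#'
#' All tunable constants of the ROI construction in one place. Values are
#' the standard ones: 8 mm FWHM for adjudication-mask smoothing, choroid
#' split at SUVR 1 with >= 100-voxel seeds, hotspot clusters of > 500
#' voxels above SUVR 1.6, tissue probability cut 0.3, SUVR floor 0.1,
#' 26-connectivity throughout.
#'
#' @return Named list of parameters.
#' @export
taupvc_params <- function() {
  list(mask_smooth_fwhm_mm = 8,
       choroid_fs_codes = CHOROID_FS_CODES,
       choroid_suvr_threshold = 1,
       choroid_min_voxels = 100L,
       ech_min_voxels = 500L,
       reference_hotspot_threshold = 1.6,
       reference_hotspot_min_voxels = 500L,
       tissue_probability_cut = 0.3,
       suvr_floor = 0.1,
       suvr_split = 1,
       stray_max_passes = 10L,
       connectivity = 26L)
}

#' Run the full per-subject pipeline
#'
#' Executes, in order: label remap; cerebellar split and SUVR
#' normalization to the inferior cerebellar gray; choroid handling (whole
#' or high/low split); extra-cortical hotspot detection; CSF and
#' bone+meninges classification plus stray gray-voxel assignment; the
#' reference-region hotspot scan with renormalization; then GTM build and
#' solve, the PVC image, the calculated pre-PVC image and the residual QC
#' report. Which stages run is controlled by the [roi_config()].
#'
#' @param aparc FreeSurfer-coded `taupvc_label` volume.
#' @param suit SUIT lobule `taupvc_label` volume.
#' @param c1,c2,c3,c4,c5 `taupvc_prob` tissue-probability volumes (c2 is
#'   accepted for interface completeness; the ROI construction uses c1 and
#'   c3-c5).
#' @param pet `taupvc_scalar` mean PET volume.
#' @param psf_fwhm_mm approximate scanner resolution, FWHM in mm.
#' @param config a [roi_config()] (default configuration 8).
#' @param params parameter list from [taupvc_params()].
#' @param remap_table remap table (default [default_remap_table()]).
#' @param qc_labels label set for the global PVCnstd (default 1:77).
#' @param out_dir optional directory: when given, the edited segmentation,
#'   SUVR, PVC, calculated pre-PVC and residual volumes plus TSV/JSON
#'   reports are written there.
#' @return A `pipeline_result` list: `edited`, `suvr`, `gtm`, `pvc`,
#'   `pre_pvc`, `qc`, `ech_clusters`, `reference` (masks and hotspot
#'   count), `provenance`.
#' @export
run_subject <- function(aparc, suit, c1, c2, c3, c4, c5, pet, psf_fwhm_mm,
                        config = roi_config(8L), params = taupvc_params(),
                        remap_table = default_remap_table(),
                        qc_labels = 1:77, out_dir = NULL) {
  stopifnot(inherits(config, "roi_config"))
  vols <- list(aparc = aparc, suit = suit, c1 = c1, c2 = c2, c3 = c3,
               c4 = c4, c5 = c5, pet = pet)
  assert_same_grid(vols)

  # step 1: remap into the edited scheme (cerebellar gray held in reserve)
  edited <- remap_labels(aparc, remap_table)

  # step 2: SUIT-based cerebellar split, SUVR normalization
  split <- split_cerebellum(aparc, suit, params$mask_smooth_fwhm_mm)
  lab <- edited$data
  lab[split$superior_mask] <- taupvc_labels$superior_cerebellar
  lab[split$inferior_mask] <- taupvc_labels$inferior_cerebellar
  suvr <- normalize_suvr(pet, split$inferior_mask)

  # step 3: choroid plexus
  choroid_mask <- array(aparc$data %in% params$choroid_fs_codes,
                        dim = dim(aparc$data))
  if (any(choroid_mask)) {
    if (config$split_choroid) {
      frag <- split_choroid(suvr, choroid_mask,
                            suvr_threshold = params$choroid_suvr_threshold,
                            min_cluster_voxels = params$choroid_min_voxels,
                            mask_fwhm_mm = params$mask_smooth_fwhm_mm,
                            connectivity = params$connectivity)
      lab[frag > 0L] <- frag[frag > 0L]
    } else {
      lab[choroid_mask] <- taupvc_labels$whole_choroid
    }
  }
  edited <- with_data(edited, lab)

  # step 4: extra-cortical hotspots (never overwriting assigned ROIs)
  ech <- NULL
  if (config$include_ech) {
    searchable <- build_searchable_roi(c3, c4, c5, aparc, psf_fwhm_mm) &
      edited$data == 0L
    ech <- detect_ech(suvr, searchable, threshold = config$ech_threshold,
                      min_cluster_voxels = params$ech_min_voxels,
                      connectivity = params$connectivity)
    lab <- edited$data
    lab[ech$labels > 0L] <- ech$labels[ech$labels > 0L]
    edited <- with_data(edited, lab)
  }

  # step 5: CSF / bone+meninges classes and stray gray voxels
  if (config$include_tissue) {
    edited <- classify_csf_bone(edited, c1, c3, c4, c5, suvr,
                                probability_cut = params$tissue_probability_cut,
                                suvr_floor = params$suvr_floor,
                                suvr_split = params$suvr_split)
    if (!config$split_tissue) {
      lab <- edited$data
      lab[lab == taupvc_labels$csf_high] <- taupvc_labels$csf_low
      lab[lab == taupvc_labels$bone_high] <- taupvc_labels$bone_low
      edited <- with_data(edited, lab)
    }
    edited <- assign_stray_gray(edited, c1, c3, c4, c5, suvr,
                                probability_cut = params$tissue_probability_cut,
                                suvr_floor = params$suvr_floor,
                                max_passes = params$stray_max_passes)
  }

  # last: reference-region hotspot scan and renormalization
  inferior_mask <- split$inferior_mask
  n_ref_hotspots <- 0L
  if (config$scan_reference) {
    next_label <- if (!is.null(ech) && nrow(ech$clusters) > 0L)
      max(ech$clusters$label) + 1L else taupvc_labels$ech_first
    scan <- scan_reference_hotspots(
      suvr, inferior_mask,
      threshold = params$reference_hotspot_threshold,
      min_cluster_voxels = params$reference_hotspot_min_voxels,
      next_label = next_label, connectivity = params$connectivity)
    if (scan$n_hotspots > 0L) {
      lab <- edited$data
      hs <- scan$hotspot_labels > 0L
      lab[hs] <- scan$hotspot_labels[hs]
      edited <- with_data(edited, lab)
      inferior_mask <- scan$inferior_mask
      suvr <- scan$suvr
      n_ref_hotspots <- scan$n_hotspots
    }
  }

  # GTM over every modeled ROI present
  roi_labels <- sort(unique(as.vector(edited$data)))
  roi_labels <- roi_labels[roi_labels != 0L]
  gtm <- build_transfer_matrix(edited, roi_labels, psf_fwhm_mm)
  gtm <- observe_roi_means(gtm, suvr, edited)
  gtm <- solve_gtm(gtm)

  pvc <- pvc_image(edited, gtm)
  pre <- calc_pre_pvc(pvc, psf_fwhm_mm)
  qc <- residuals_and_pvcnstd(suvr, pre, edited, labels = qc_labels,
                              names = roi_names(remap_table))

  result <- structure(list(
    edited = edited, suvr = suvr, gtm = gtm, pvc = pvc, pre_pvc = pre,
    qc = qc,
    ech_clusters = if (is.null(ech)) NULL else ech$clusters,
    reference = list(inferior_mask = inferior_mask,
                     superior_mask = split$superior_mask,
                     reference_mean = attr(suvr, "reference_mean"),
                     n_hotspots = n_ref_hotspots),
    provenance = list(config = unclass(config), params = params,
                      psf_fwhm_mm = psf_fwhm_mm, qc_labels = qc_labels)),
    class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Names for the full edited label space (anatomy + special ROIs).
roi_names <- function(remap_table = default_remap_table()) {
  nm <- stats::setNames(remap_table$name, remap_table$edited_index)
  c(nm, stats::setNames(
    c("Inferior Cerebellar Gray (reference)", "Choroid Plexus High",
      "Choroid Plexus Low", "CSF Low", "CSF High", "Bone+Meninges Low",
      "Bone+Meninges High", "Whole Choroid Plexus"),
    c(taupvc_labels$inferior_cerebellar, taupvc_labels$choroid_high,
      taupvc_labels$choroid_low, taupvc_labels$csf_low,
      taupvc_labels$csf_high, taupvc_labels$bone_low,
      taupvc_labels$bone_high, taupvc_labels$whole_choroid)))
}

# Display name for any label, including per-subject hotspot labels >= 85.
label_display_names <- function(labels) {
  nm <- unname(roi_names()[as.character(labels)])
  hot <- is.na(nm) & labels >= taupvc_labels$ech_first
  nm[hot] <- paste0("Hotspot ", labels[hot])
  nm[is.na(nm)] <- ""
  nm
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(result$edited, file.path(out_dir, "edited_aparc_aseg.nii.gz"))
  write_volume(result$suvr, file.path(out_dir, "suvr.nii.gz"))
  write_volume(result$pvc, file.path(out_dir, "pvc.nii.gz"))
  write_volume(result$pre_pvc, file.path(out_dir, "calc_pre_pvc.nii.gz"))
  write_volume(result$qc$residual, file.path(out_dir, "residual.nii.gz"))
  means <- data.frame(label = result$gtm$roi_labels,
                      name = label_display_names(result$gtm$roi_labels),
                      n_voxels = result$gtm$n_voxels,
                      observed = result$gtm$observed_means,
                      corrected = result$gtm$corrected_means)
  utils::write.table(means, file.path(out_dir, "roi_means.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$qc$per_roi, file.path(out_dir, "qc_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$ech_clusters))
    utils::write.table(result$ech_clusters,
                       file.path(out_dir, "ech_clusters.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  manifest <- c(result$provenance,
                list(global_pvcnstd = result$qc$global_pvcnstd,
                     solver = result$gtm$solver,
                     condition_number = result$gtm$condition_number))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Compare ROI configurations on one subject
#'
#' Runs several configurations on identical inputs and tabulates the
#' global PVCnstd of each, the quantitative basis for choosing an ROI
#' configuration: lower means the configuration explains the observed
#' image better.
#'
#' @inheritParams run_subject
#' @param config_ids integer vector of configuration ids (default 1:10).
#' @return Data frame: `config_id`, `global_pvcnstd`, `n_rois`,
#'   `n_ech`, `solver`.
#' @export
compare_configurations <- function(aparc, suit, c1, c2, c3, c4, c5, pet,
                                   psf_fwhm_mm, config_ids = 1:10,
                                   params = taupvc_params(),
                                   qc_labels = 1:77) {
  rows <- lapply(config_ids, function(id) {
    r <- run_subject(aparc, suit, c1, c2, c3, c4, c5, pet, psf_fwhm_mm,
                     config = roi_config(id), params = params,
                     qc_labels = qc_labels)
    data.frame(config_id = id, global_pvcnstd = r$qc$global_pvcnstd,
               n_rois = length(r$gtm$roi_labels),
               n_ech = if (is.null(r$ech_clusters)) 0L
                       else nrow(r$ech_clusters),
               solver = r$gtm$solver)
  })
  do.call(rbind, rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> config %d: %d ROIs, global PVCnstd %.4g (%s solve)\n",
    x$provenance$config$config_id, length(x$gtm$roi_labels),
    x$qc$global_pvcnstd, x$gtm$solver))
  invisible(x)
}
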