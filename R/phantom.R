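#' Phantom specification
#'
#' Describes a fully synthetic, ground-truthed test subject: a
#' geometrically simple brain (nested ellipsoids for cortical gray and
#' white matter, hippocampi, ventricles with adjacent choroid slabs, a
#' spherical cerebellum with SUIT-style lobule codes, a brainstem bridge,
#' a CSF gap and a skull shell) plus the off-target features the pipeline
#' exists to handle: a bimodal choroid plexus, an extra-cortical hotspot
#' sphere embedded in the skull, extracerebral CSF/skull activity with a
#' superior/inferior skull contrast, a stray gray-matter pocket missed by
#' the segmentation, and (off by default, as it is rare in practice) a
#' hotspot inside the inferior cerebellar reference region.
#'
#' The PET volume is the exact forward model -- the PSF-smoothed
#' piecewise-constant truth -- plus optional additive Gaussian noise, so
#' every downstream estimate can be checked against known ground truth.
#'
#' @param grid_dim voxels per axis (default 64).
#' @param voxel_size_mm isotropic voxel size (default 2 mm).
#' @param psf_fwhm_mm scanner PSF FWHM (default 6 mm).
#' @param noise_sd additive Gaussian noise SD on the smoothed image, in
#'   activity units (default 0 = noiseless).
#' @param seed RNG seed for the noise.
#' @param ech include the extra-cortical hotspot sphere.
#' @param ech_suvr hotspot activity (default 2.2).
#' @param ech_radius_vox hotspot sphere radius in voxels (default 7,
#'   about 1400 voxels, so that the supra-threshold core after PSF
#'   smoothing still exceeds the 500-voxel cluster cut).
#' @param bimodal_choroid give the ventral/dorsal choroid halves distinct
#'   activities (default high 1.8 / low 0.7; otherwise uniform 1.2).
#' @param extracerebral_tissue give CSF and skull nonzero activity
#'   (CSF 0.4; skull 1.3 superior / 0.5 inferior).
#' @param stray_gray include a small unsegmented gray-matter pocket.
#' @param reference_hotspot include a hotspot inside the inferior
#'   cerebellar gray (activity 2.5).
#' @param reference_hotspot_voxels its size in voxels (default 1200; the
#'   supra-threshold core left after PSF smoothing and the reference-mean
#'   inflation the lesion itself causes must still exceed 500 voxels).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_dim = 64L, voxel_size_mm = 2,
                         psf_fwhm_mm = 6, noise_sd = 0, seed = 1L,
                         ech = TRUE, ech_suvr = 2.2, ech_radius_vox = 7,
                         bimodal_choroid = TRUE,
                         extracerebral_tissue = TRUE,
                         stray_gray = TRUE,
                         reference_hotspot = FALSE,
                         reference_hotspot_voxels = 1200L) {
  stopifnot(grid_dim >= 48L, voxel_size_mm > 0, psf_fwhm_mm > 0,
            noise_sd >= 0)
  structure(as.list(environment()), class = "phantom_spec")
}

# True activities, in reference-region units (inferior cerebellar gray = 1).
phantom_true_means <- function(spec) {
  c("1" = 1.4, "2" = 1.4,        # entorhinal L/R
    "3" = 1.3, "4" = 1.3,        # hippocampus L/R
    "5" = 1.5, "9" = 1.5,        # parahippocampal L/R
    "31" = 1.2, "47" = 1.2,      # frontal L/R
    "37" = 1.6, "53" = 1.6,      # lateral occipital L/R
    "73" = 0.9, "74" = 0.9, "75" = 0.9,   # white matter, brainstem
    "77" = 1.3,                  # superior cerebellar gray (off-target)
    "78" = 1.0,                  # inferior cerebellar gray (reference)
    "79" = if (spec$bimodal_choroid) 1.8 else 1.2,
    "80" = if (spec$bimodal_choroid) 0.7 else 1.2,
    csf = if (spec$extracerebral_tissue) 0.4 else 0,
    skull_high = if (spec$extracerebral_tissue) 1.3 else 0,
    skull_low = if (spec$extracerebral_tissue) 0.5 else 0,
    ech = spec$ech_suvr,
    reference_hotspot = 2.5,
    stray = 1.4)
}

#' Generate a synthetic ground-truthed subject
#'
#' Builds all pipeline inputs on one grid: a FreeSurfer-coded label
#' volume, a SUIT-style cerebellar lobule volume (deliberately slightly
#' smaller than the cerebellar gray, so some gray voxels fall outside the
#' atlas and must be adjudicated by mask smoothing), the five
#' tissue-probability maps, and the PET volume as PSF-smoothed truth plus
#' seeded Gaussian noise. Ground truth (per-region activities and voxel
#' masks of every feature) is returned alongside.
#'
#' @param spec a [phantom_spec()].
#' @return List: `aparc`, `suit` (`taupvc_label`), `c1`..`c5`
#'   (`taupvc_prob`), `pet` (`taupvc_scalar`), `truth` (list with
#'   `true_means`, feature masks, `activity` and `pet_noiseless` arrays).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_dim
  d <- c(n, n, n)
  sc <- n / 64                       # geometry scales with the grid
  ix <- array(rep(seq_len(n), times = n * n), dim = d)
  iy <- array(rep(seq_len(n), each = n, times = n), dim = d)
  iz <- array(rep(seq_len(n), each = n * n), dim = d)

  ell <- function(cx, cy, cz, rx, ry, rz)
    ((ix - cx) / rx)^2 + ((iy - cy) / ry)^2 + ((iz - cz) / rz)^2

  aparc <- array(0L, dim = d)
  paint <- function(mask, code, require_full = FALSE) {
    free <- mask & aparc == 0L
    if (require_full && !all(free == mask))
      stop("phantom ROIs forced to overlap at code ", code)
    aparc[free] <<- as.integer(code)
    free
  }

  # cerebrum: gray shell around white core, notched by the brainstem
  e_cer <- ell(32 * sc, 34 * sc, 40 * sc, 20 * sc, 17 * sc, 14 * sc)
  e_wm <- ell(32 * sc, 34 * sc, 40 * sc, 13 * sc, 11 * sc, 9 * sc)

  # ventricles, and choroid slabs inside the white core; the ventral
  # (high-binding) and dorsal (low-binding) choroid halves are separated
  # by two voxel layers of white matter so that PSF smoothing does not
  # carry one mode across the other's seed
  vent <- ix >= 28 * sc & ix <= 35 * sc & iy >= 34 * sc & iy <= 38 * sc &
          iz >= 38 * sc & iz <= 44 * sc
  chor_box <- ix >= 26 * sc & ix <= 37 * sc & iy >= 30 * sc & iy <= 33 * sc
  chor_high <- chor_box & iz >= 36 * sc & iz <= 38 * sc   # ventral, hot
  chor_low <- chor_box & iz >= 41 * sc & iz <= 43 * sc    # dorsal, cool
  chor <- chor_high | chor_low
  paint(vent & ix < 32 * sc, 4L, TRUE)       # L lateral ventricle
  paint(vent & ix >= 32 * sc, 43L, TRUE)     # R lateral ventricle
  paint(chor & ix < 32 * sc, 31L, TRUE)      # choroid plexus L
  paint(chor & ix >= 32 * sc, 63L, TRUE)     # choroid plexus R

  # hippocampi: small spheres next to the ventral choroid
  hipL <- ell(24 * sc, 28 * sc, 35 * sc, 2.5 * sc, 2.5 * sc, 2.5 * sc) <= 1
  hipR <- ell(40 * sc, 28 * sc, 35 * sc, 2.5 * sc, 2.5 * sc, 2.5 * sc) <= 1
  paint(hipL, 17L, TRUE)
  paint(hipR, 53L, TRUE)

  # brainstem bridge below the cerebrum
  stem <- ix >= 29 * sc & ix <= 35 * sc & iy >= 22 * sc & iy <= 27 * sc &
          iz >= 26 * sc & iz <= 34 * sc
  paint(stem, 16L)

  paint(e_wm <= 1 & ix < 32 * sc, 2L)        # L cerebral white
  paint(e_wm <= 1 & ix >= 32 * sc, 41L)      # R cerebral white

  # cortical gray: shell split into four bilateral regions
  gray <- e_cer <= 1 & e_wm > 1
  front <- iy >= 34 * sc & iz >= 40 * sc
  occ <- iy >= 34 * sc & iz < 40 * sc
  ento <- iy < 34 * sc & iz < 40 * sc
  parah <- iy < 34 * sc & iz >= 40 * sc
  paint(gray & front & ix < 32 * sc, 1028L)  # L frontal
  paint(gray & front & ix >= 32 * sc, 2028L) # R frontal
  paint(gray & occ & ix < 32 * sc, 1011L)    # L lateral occipital
  paint(gray & occ & ix >= 32 * sc, 2011L)   # R lateral occipital
  paint(gray & ento & ix < 32 * sc, 1006L)   # L entorhinal
  paint(gray & ento & ix >= 32 * sc, 2006L)  # R entorhinal
  paint(gray & parah & ix < 32 * sc, 1016L)  # L parahippocampal
  paint(gray & parah & ix >= 32 * sc, 2016L) # R parahippocampal

  # cerebellum: sphere, gray shell over white core
  e_cb <- ell(32 * sc, 14 * sc, 16 * sc, 13 * sc, 13 * sc, 13 * sc)
  e_cbw <- ell(32 * sc, 14 * sc, 16 * sc, 6 * sc, 6 * sc, 6 * sc)
  cb_inf_cut <- 16 * sc
  cb_gray <- e_cb <= 1 & e_cbw > 1 & aparc == 0L
  paint(e_cbw <= 1 & ix < 32 * sc, 7L)       # L cerebellar white
  paint(e_cbw <= 1 & ix >= 32 * sc, 46L)     # R cerebellar white
  paint(cb_gray & ix < 32 * sc, 8L)          # L cerebellar gray
  paint(cb_gray & ix >= 32 * sc, 47L)        # R cerebellar gray

  # stray gray pocket just outside the segmented cortex (aparc stays 0)
  stray <- ix >= 30 * sc & ix <= 33 * sc & iy >= 51 * sc & iy <= 52 * sc &
           iz >= 38 * sc & iz <= 41 * sc & e_cer > 1 & aparc == 0L
  if (!spec$stray_gray) stray[] <- FALSE

  # CSF gap and skull shell around the cerebrum (only where unassigned)
  csf <- e_cer > 1 & e_cer <= 1.2 & aparc == 0L & !stray
  skull <- e_cer > 1.2 & e_cer <= 1.55 & aparc == 0L
  skull_high <- skull & iz >= 40 * sc

  # extra-cortical hotspot sphere against the right parieto-occipital
  # skull (partly in soft tissue beyond it)
  ech_mask <- array(FALSE, dim = d)
  if (spec$ech) {
    r <- spec$ech_radius_vox * sc
    ech_mask <- ell(46 * sc, 50 * sc, 52 * sc, r, r, r) <= 1
    if (any(ech_mask & aparc != 0L))
      stop("phantom ROIs forced to overlap at the extra-cortical hotspot")
    skull <- skull & !ech_mask
    skull_high <- skull_high & !ech_mask
    csf <- csf & !ech_mask
  }

  # rare reference-region hotspot: the k inferior-gray voxels nearest a
  # seed at the bottom of the cerebellum
  ref_hot <- array(FALSE, dim = d)
  if (spec$reference_hotspot) {
    inf_gray <- which(cb_gray & iz < 16 * sc)
    dist2 <- (ix[inf_gray] - 32 * sc)^2 + (iy[inf_gray] - 14 * sc)^2 +
             (iz[inf_gray] - 5 * sc)^2
    k <- min(spec$reference_hotspot_voxels, length(inf_gray))
    ref_hot[inf_gray[order(dist2)[seq_len(k)]]] <- TRUE
  }

  # SUIT lobule codes over the cerebellar gray, slightly eroded so a ring
  # of gray falls outside the atlas
  suit <- array(0L, dim = d)
  in_suit <- cb_gray & e_cb <= 0.93
  suit[in_suit & iz >= 16 * sc] <- 1L        # a superior lobule code
  suit[in_suit & iz < 16 * sc] <- 8L         # an inferior lobule code

  # ground-truth activity
  tm <- phantom_true_means(spec)
  act <- array(0, dim = d)
  fs2edited <- c("1006" = 1, "2006" = 2, "17" = 3, "53" = 4, "1016" = 5,
                 "2016" = 9, "1028" = 31, "2028" = 47, "1011" = 37,
                 "2011" = 53, "2" = 73, "41" = 73, "7" = 74, "46" = 74,
                 "16" = 75)
  for (code in names(fs2edited))
    act[aparc == as.integer(code)] <- tm[as.character(fs2edited[code])]
  act[cb_gray & iz >= 16 * sc] <- tm["77"]
  act[cb_gray & iz < 16 * sc] <- tm["78"]
  act[chor_high] <- tm["79"]
  act[chor & !chor_high] <- tm["80"]
  act[csf] <- tm["csf"]
  act[skull_high] <- tm["skull_high"]
  act[skull & !skull_high] <- tm["skull_low"]
  act[ech_mask] <- tm["ech"]
  act[ref_hot] <- tm["reference_hotspot"]
  act[stray] <- tm["stray"]
  act[vent] <- 0

  pet0 <- smooth_array(act, spec$psf_fwhm_mm, rep(spec$voxel_size_mm, 3))
  pet <- pet0
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    pet <- pet0 + array(stats::rnorm(length(pet0), 0, spec$noise_sd),
                        dim = d)
  }

  # tissue-probability maps consistent with the geometry
  c1 <- array(0, dim = d)
  c1[gray & aparc > 1000L] <- 1
  c1[hipL | hipR | cb_gray] <- 1
  c1[stray] <- 1
  c2 <- array(0, dim = d)
  c2[aparc %in% c(2L, 41L, 7L, 46L, 16L)] <- 1
  c3 <- array(0, dim = d)
  c3[vent | csf] <- 1
  c3[chor] <- 0.6
  c4 <- array(0, dim = d)
  c5 <- array(0, dim = d)
  c4[skull | ech_mask] <- 0.7
  c5[skull | ech_mask] <- 0.3

  vs <- rep(spec$voxel_size_mm, 3)
  list(
    aparc = labeled_volume(aparc, vs),
    suit = labeled_volume(suit, vs),
    c1 = probability_volume(c1, vs), c2 = probability_volume(c2, vs),
    c3 = probability_volume(c3, vs), c4 = probability_volume(c4, vs),
    c5 = probability_volume(c5, vs),
    pet = scalar_volume(pet, vs),
    truth = list(true_means = tm,
                 activity = act, pet_noiseless = pet0,
                 masks = list(ech = ech_mask, choroid_high = chor_high,
                              choroid_low = chor & !chor_high,
                              csf = csf, skull_high = skull_high,
                              skull_low = skull & !skull_high,
                              stray = stray, reference_hotspot = ref_hot,
                              cerebellar_gray = cb_gray,
                              inferior_gray_true = cb_gray & iz < 16 * sc,
                              superior_gray_true = cb_gray & iz >= 16 * sc),
                 spec = spec))
}

#' Minimal block phantom for GTM validation
#'
#' A bare geometric phantom: `n_rois` disjoint rectangular ROIs in an
#' otherwise zero grid, with known activities, and a PET volume that is
#' exactly the PSF-smoothed piecewise-constant truth (plus optional
#' noise). Because every nonzero voxel belongs to a modeled ROI, the GTM
#' is exact on this phantom: corrected means must recover the true
#' activities to numerical precision. This is the primary oracle for the
#' GTM solver.
#'
#' @param n_rois number of blocks (default 6).
#' @param grid_dim grid size (default 64).
#' @param voxel_size_mm voxel size (default 2).
#' @param psf_fwhm_mm PSF FWHM (default 6).
#' @param true_means activities; default `seq(0.5, by = 0.5)`.
#' @param noise_sd,seed optional additive Gaussian noise.
#' @return List: `edited` (`taupvc_label`, labels 1..n_rois), `pet`
#'   (`taupvc_scalar`), `true_means`.
#' @export
generate_block_phantom <- function(n_rois = 6L, grid_dim = 64L,
                                   voxel_size_mm = 2, psf_fwhm_mm = 6,
                                   true_means = seq(0.5, by = 0.5,
                                                    length.out = n_rois),
                                   noise_sd = 0, seed = 1L) {
  stopifnot(n_rois >= 1L, n_rois <= 8L, length(true_means) == n_rois)
  n <- grid_dim
  d <- c(n, n, n)
  lab <- array(0L, dim = d)
  act <- array(0, dim = d)
  # blocks at the 8 octant centers, well separated
  centers <- as.matrix(expand.grid(c(0.3, 0.7), c(0.3, 0.7), c(0.3, 0.7)))
  half <- max(2L, round(n * 0.09))
  for (i in seq_len(n_rois)) {
    cx <- round(centers[i, ] * n)
    lab[(cx[1] - half):(cx[1] + half), (cx[2] - half):(cx[2] + half),
        (cx[3] - half):(cx[3] + half)] <- i
    act[lab == i] <- true_means[i]
  }
  pet <- smooth_array(act, psf_fwhm_mm, rep(voxel_size_mm, 3))
  if (noise_sd > 0) {
    set.seed(seed)
    pet <- pet + array(stats::rnorm(length(pet), 0, noise_sd), dim = d)
  }
  vs <- rep(voxel_size_mm, 3)
  list(edited = labeled_volume(lab, vs), pet = scalar_volume(pet, vs),
       true_means = true_means)
}

#' Monte-Carlo recovery experiment
#'
#' Repeats the phantom's noise realization `n_reps` times and reports the
#' bias and RMSE of the GTM-corrected ROI means. The ROI model (edited
#' labels and transfer matrix) is fixed from the noiseless run; each
#' repetition adds fresh seeded noise to the noiseless PET, renormalizes
#' the SUVR, recomputes observed means and re-solves. Estimates are
#' compared in activity units (corrected mean times the recorded reference
#' mean), in which the estimator is linear in the noise, against the
#' noiseless-run estimand; the geometric true activity is reported where
#' the label corresponds to a single truth region (NA for the
#' classification-derived tissue ROIs).
#'
#' @param spec a [phantom_spec()] with `noise_sd > 0`.
#' @param config a [roi_config()] (default 8).
#' @param n_reps repetitions (default 100).
#' @param seed base seed; repetition i uses `seed + i`.
#' @return Data frame: label, true_mean, noiseless_mean, mean_corrected,
#'   bias, rmse, mc_se (Monte-Carlo standard error of the bias).
#' @export
recovery_experiment <- function(spec, config = roi_config(8L),
                                n_reps = 100L, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), spec$noise_sd > 0)
  spec0 <- spec
  spec0$noise_sd <- 0
  ph <- generate_phantom(spec0)
  base <- run_subject(ph$aparc, ph$suit, ph$c1, ph$c2, ph$c3, ph$c4, ph$c5,
                      ph$pet, spec$psf_fwhm_mm, config = config)
  edited <- base$edited
  gtm0 <- base$gtm
  inferior <- base$reference$inferior_mask
  ref0 <- base$reference$reference_mean
  noiseless_act <- gtm0$corrected_means * ref0

  idx <- lapply(gtm0$roi_labels, function(l) which(edited$data == l))
  inf_idx <- which(inferior)
  pet0 <- ph$truth$pet_noiseless
  est <- matrix(NA_real_, n_reps, length(gtm0$roi_labels))
  for (r in seq_len(n_reps)) {
    set.seed(seed + r)
    noisy <- pet0 + stats::rnorm(length(pet0), 0, spec$noise_sd)
    ref_mean <- mean(noisy[inf_idx])
    t_obs <- vapply(idx, function(ii) mean(noisy[ii]), numeric(1)) / ref_mean
    m <- gtm0
    m$observed_means <- t_obs
    m <- solve_gtm(m)
    est[r, ] <- m$corrected_means * ref_mean
  }

  # geometric truth for labels that are a single truth region
  tm <- ph$truth$true_means
  truth_of <- function(l) {
    key <- as.character(l)
    if (key %in% names(tm)) return(unname(tm[key]))
    NA_real_
  }
  mean_est <- colMeans(est)
  bias <- mean_est - noiseless_act
  rmse <- sqrt(colMeans(sweep(est, 2L, noiseless_act)^2))
  data.frame(label = gtm0$roi_labels,
             true_mean = vapply(gtm0$roi_labels, truth_of, numeric(1)),
             noiseless_mean = noiseless_act,
             mean_corrected = mean_est, bias = bias, rmse = rmse,
             mc_se = apply(est, 2L, stats::sd) / sqrt(n_reps))
}
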