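#' Build the geometric transfer matrix
#'
#' The Rousset GTM models the observed mean of each ROI as a known linear
#' mixture of the true ROI means: smoothing the indicator of ROI j by the
#' scanner PSF and averaging it over the voxels of ROI i gives the matrix
#' entry `omega[i, j]`, the fraction of ROI i's observed signal
#' attributable to ROI j. Voxels labeled 0 contribute no column: unlabeled
#' space is assumed to have zero activity, so a row may sum to less than 1
#' where signal leaks into unmodeled space.
#'
#' @param edited `taupvc_label` volume.
#' @param roi_labels ordered integer vector of ROI labels to model;
#'   defaults to all nonzero labels present. Requested labels absent from
#'   the volume are dropped with a warning (e.g. a subject without
#'   hotspots).
#' @param psf_fwhm_mm scanner PSF FWHM in mm.
#' @return A `gtm_model` list: `roi_labels`, `omega` (N x N),
#'   `n_voxels`, plus empty slots for the observed and corrected means.
#' @export
build_transfer_matrix <- function(edited, roi_labels = NULL, psf_fwhm_mm) {
  stopifnot(inherits(edited, "taupvc_label"))
  present <- sort(unique(as.vector(edited$data)))
  present <- present[present != 0L]
  if (is.null(roi_labels)) roi_labels <- present
  missing <- setdiff(roi_labels, present)
  if (length(missing)) {
    warning("labels absent from the volume dropped from the GTM: ",
            paste(missing, collapse = ", "))
    roi_labels <- setdiff(roi_labels, missing)
  }
  n <- length(roi_labels)
  if (n == 0L) stop("no ROI labels to model")

  idx <- lapply(roi_labels, function(l) which(edited$data == l))
  omega <- matrix(0, n, n)
  for (j in seq_len(n)) {
    ind <- array(0, dim = dim(edited$data))
    ind[idx[[j]]] <- 1
    sm <- smooth_array(ind, psf_fwhm_mm, edited$voxel_size_mm)
    for (i in seq_len(n)) omega[i, j] <- mean(sm[idx[[i]]])
  }
  structure(list(roi_labels = as.integer(roi_labels), omega = omega,
                 n_voxels = lengths(idx),
                 observed_means = NULL, corrected_means = NULL,
                 condition_number = kappa(omega, exact = TRUE),
                 solver = NULL),
            class = "gtm_model")
}

#' Observed ROI means
#'
#' Mean SUVR over the voxels of each modeled ROI.
#'
#' @param model a `gtm_model`.
#' @param suvr `taupvc_scalar` SUVR volume.
#' @param edited the `taupvc_label` volume the model was built from.
#' @return The model with `observed_means` filled.
#' @export
observe_roi_means <- function(model, suvr, edited) {
  stopifnot(inherits(model, "gtm_model"), inherits(suvr, "taupvc_scalar"))
  model$observed_means <- vapply(model$roi_labels, function(l)
    mean(suvr$data[edited$data == l]), numeric(1))
  model
}

#' Solve the GTM system for corrected ROI means
#'
#' Solves `omega %*% c = t` for the partial-volume-corrected means `c`
#' given the observed means `t`. When the 2-norm condition number of
#' `omega` exceeds `cond_limit` (default 1e8; tiny ROIs adjacent to large
#' ones can make the matrix near-singular) the system is solved in the
#' least-squares sense through the SVD pseudo-inverse and the model is
#' flagged. Corrected means can legitimately exceed observed means
#' (spill-out recovery).
#'
#' @param model a `gtm_model` with `observed_means` filled.
#' @param cond_limit condition-number threshold for the pseudo-inverse
#'   fallback.
#' @return The model with `corrected_means` and `solver` filled.
#' @export
solve_gtm <- function(model, cond_limit = 1e8) {
  stopifnot(inherits(model, "gtm_model"),
            !is.null(model$observed_means))
  om <- model$omega
  t_ <- model$observed_means
  model$condition_number <- kappa(om, exact = TRUE)
  if (is.finite(model$condition_number) &&
      model$condition_number <= cond_limit) {
    model$corrected_means <- as.numeric(solve(om, t_))
    model$solver <- "direct"
  } else {
    model$corrected_means <- as.numeric(pinv(om) %*% t_)
    model$solver <- "pseudoinverse"
    warning(sprintf(
      "transfer matrix ill-conditioned (condition number %.3g); %s",
      model$condition_number, "solved in the least-squares sense"))
  }
  model
}

# Moore-Penrose pseudo-inverse via SVD.
pinv <- function(m, tol = .Machine$double.eps * max(dim(m))) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) stop("matrix is numerically zero; no least-squares solution")
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Piecewise-constant PVC image
#'
#' Assigns each ROI's corrected mean to all of its voxels; label-0 voxels
#' get 0.
#'
#' @param edited `taupvc_label` volume.
#' @param model solved `gtm_model`.
#' @return A `taupvc_scalar` volume.
#' @export
pvc_image <- function(edited, model) {
  stopifnot(inherits(model, "gtm_model"), !is.null(model$corrected_means))
  out <- array(0, dim = dim(edited$data))
  for (i in seq_along(model$roi_labels))
    out[edited$data == model$roi_labels[i]] <- model$corrected_means[i]
  with_data(edited, out, "taupvc_scalar")
}

#' Calculated pre-PVC image
#'
#' Smooths the piecewise-constant PVC image by the scanner PSF. If the ROI
#' model and PSF explain the data perfectly this reproduces the observed
#' SUVR; departures are the residuals the fit diagnostic is built on.
#'
#' @param pvc `taupvc_scalar` volume from [pvc_image()].
#' @param psf_fwhm_mm scanner PSF FWHM in mm.
#' @return A `taupvc_scalar` volume.
#' @export
calc_pre_pvc <- function(pvc, psf_fwhm_mm) {
  gaussian_smooth(pvc, psf_fwhm_mm)
}

#' Residuals and the normalized residual standard deviation (PVCnstd)
#'
#' The residual image is calculated pre-PVC minus observed SUVR. Its mean
#' within an ROI is near zero by construction and carries no fit
#' information; its standard deviation does: it is low when the ROI
#' configuration explains the observed image well. Each ROI's residual
#' standard deviation is normalized by the ROI's mean observed SUVR
#' (PVCnstd); the global score is the unweighted mean of PVCnstd over the
#' requested label set (default 1-77, the anatomical ROIs).
#'
#' @param suvr observed `taupvc_scalar` SUVR volume.
#' @param pre `taupvc_scalar` calculated pre-PVC volume.
#' @param edited `taupvc_label` volume.
#' @param labels label set for the per-ROI table and global score
#'   (default 1:77; labels absent from the volume are skipped).
#' @param names optional named character vector of ROI names.
#' @param sd_type `"population"` (divide by n, default) or `"sample"`.
#' @return A `taupvc_qc` list: `per_roi` data frame (label, name,
#'   n_voxels, observed_mean, residual_mean, residual_std, pvcnstd),
#'   `global_pvcnstd`, `residual` volume.
#' @export
residuals_and_pvcnstd <- function(suvr, pre, edited, labels = 1:77,
                                  names = NULL,
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  res <- pre$data - suvr$data
  present <- intersect(labels, unique(as.vector(edited$data)))
  rows <- lapply(present, function(l) {
    v <- edited$data == l
    r <- res[v]
    m <- mean(suvr$data[v])
    s <- stats::sd(r)
    if (sd_type == "population" && length(r) > 1L)
      s <- s * sqrt((length(r) - 1) / length(r))
    if (length(r) == 1L) s <- 0
    data.frame(label = l,
               name = if (!is.null(names) && !is.na(names[as.character(l)]))
                 names[as.character(l)] else NA_character_,
               n_voxels = sum(v), observed_mean = m,
               residual_mean = mean(r), residual_std = s,
               pvcnstd = if (m > 0) s / m else NA_real_)
  })
  per_roi <- do.call(rbind, rows)
  if (any(is.na(per_roi$pvcnstd)))
    warning("ROI(s) with nonpositive mean SUVR excluded from the global ",
            "PVCnstd: ", paste(per_roi$label[is.na(per_roi$pvcnstd)],
                               collapse = ", "))
  structure(list(per_roi = per_roi,
                 global_pvcnstd = mean(per_roi$pvcnstd, na.rm = TRUE),
                 residual = with_data(suvr, res)),
            class = "taupvc_qc")
}
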