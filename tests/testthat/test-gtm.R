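test_that("the transfer matrix tends to the identity as the PSF vanishes", {
  d <- c(10, 10, 10)
  lab <- array(0L, dim = d)
  lab[2:4, 2:4, 2:4] <- 1L
  lab[6:9, 6:9, 6:9] <- 2L
  ed <- labeled_volume(lab, c(2, 2, 2))
  m <- suppressWarnings(build_transfer_matrix(ed, psf_fwhm_mm = 0.1))
  expect_equal(m$omega, diag(2), tolerance = 1e-12)

  # a single ROI filling the whole grid: only boundary leakage
  full <- labeled_volume(array(1L, dim = c(24, 24, 24)), c(2, 2, 2))
  m2 <- build_transfer_matrix(full, psf_fwhm_mm = 6)
  expect_gt(m2$omega[1, 1], 0.8)
  expect_lte(m2$omega[1, 1], 1 + 1e-9)
})

test_that("omega rows are in [0,1], sum to <= 1, and reach 1 on a fully labeled grid", {
  ph <- default_phantom()
  m <- default_run8()$gtm
  expect_true(all(m$omega >= 0 & m$omega <= 1 + 1e-9))
  expect_true(all(rowSums(m$omega) <= 1 + 1e-9))

  # two half-space ROIs tiling the grid: symmetric geometry, rows sum to 1
  # exactly (no unlabeled space to leak into, zero padding aside)
  d <- c(20, 20, 20)
  lab <- array(2L, dim = d)
  lab[1:10, , ] <- 1L
  m3 <- build_transfer_matrix(labeled_volume(lab, c(2, 2, 2)),
                              psf_fwhm_mm = 6)
  expect_equal(m3$omega[1, 1], m3$omega[2, 2], tolerance = 1e-12)
  expect_equal(m3$omega[1, 2], m3$omega[2, 1], tolerance = 1e-12)
  # both rows lose the same mass through the zero-padded faces
  expect_equal(rowSums(m3$omega)[1], rowSums(m3$omega)[2], tolerance = 1e-12)
  expect_lt(rowSums(m3$omega)[1], 1)

  # an ROI buried > 4 sigma from every face of a fully labeled grid leaks
  # only into modeled neighbors: its row sums to 1 almost exactly
  d4 <- c(30, 30, 30)
  lab4 <- array(1L, dim = d4)
  lab4[13:18, 13:18, 13:18] <- 2L
  m4 <- build_transfer_matrix(labeled_volume(lab4, c(2, 2, 2)),
                              psf_fwhm_mm = 6)
  expect_equal(unname(rowSums(m4$omega)[2]), 1, tolerance = 1e-6)
})

test_that("requested labels absent from the volume are dropped with a warning", {
  d <- c(8, 8, 8)
  lab <- array(0L, dim = d); lab[2:4, 2:4, 2:4] <- 7L
  ed <- labeled_volume(lab, c(2, 2, 2))
  expect_warning(m <- build_transfer_matrix(ed, roi_labels = c(7L, 85L),
                                            psf_fwhm_mm = 6), "absent")
  expect_identical(m$roi_labels, 7L)
  expect_error(suppressWarnings(
    build_transfer_matrix(ed, roi_labels = 85L, psf_fwhm_mm = 6)), "no ROI")
})

test_that("solve_gtm inverts hand-checkable and random systems", {
  base <- structure(list(roi_labels = 1:2, n_voxels = c(1L, 1L)),
                    class = "gtm_model")
  m <- base
  m$omega <- diag(2)
  m$observed_means <- c(1.4, 0.7)
  expect_equal(solve_gtm(m)$corrected_means, c(1.4, 0.7))

  m2 <- base
  m2$omega <- matrix(c(0.8, 0.2, 0.2, 0.8), 2, 2)
  m2$observed_means <- c(1, 2)
  s2 <- solve_gtm(m2)
  expect_equal(s2$corrected_means, c(2 / 3, 7 / 3), tolerance = 1e-12)
  expect_identical(s2$solver, "direct")

  # random well-conditioned systems vs the SVD least-squares oracle
  set.seed(51)
  for (n in c(3L, 6L, 10L)) {
    om <- diag(n) * 0.7 + matrix(runif(n * n, 0, 0.3 / n), n, n)
    t_ <- runif(n, 0.5, 2.5)
    m3 <- structure(list(roi_labels = seq_len(n), omega = om,
                         observed_means = t_), class = "gtm_model")
    got <- solve_gtm(m3)$corrected_means
    expect_equal(got, svd_lstsq(om, t_), tolerance = 1e-10)
  }

  # near-singular matrix falls back to the pseudo-inverse with a warning
  m4 <- base
  m4$omega <- matrix(c(0.5, 0.5, 0.5, 0.5 + 1e-12), 2, 2)
  m4$observed_means <- c(1, 1)
  expect_warning(s4 <- solve_gtm(m4), "ill-conditioned")
  expect_identical(s4$solver, "pseudoinverse")
  expect_true(all(is.finite(s4$corrected_means)))
})

test_that("GTM recovers exact means on an ideal forward-model phantom", {
  bp <- generate_block_phantom(n_rois = 6L)
  m <- build_transfer_matrix(bp$edited, psf_fwhm_mm = 6)
  m <- observe_roi_means(m, bp$pet, bp$edited)
  m <- solve_gtm(m)
  expect_lt(max(abs(m$corrected_means - bp$true_means) / bp$true_means),
            1e-6)
})

test_that("pvc_image and calc_pre_pvc reproduce the forward model", {
  bp <- generate_block_phantom(n_rois = 4L)
  m <- build_transfer_matrix(bp$edited, psf_fwhm_mm = 6)
  m <- observe_roi_means(m, bp$pet, bp$edited)
  m <- solve_gtm(m)
  pvc <- pvc_image(bp$edited, m)
  vals <- sort(setdiff(unique(as.vector(pvc$data)), 0))
  expect_length(vals, 4L)
  expect_true(all(pvc$data[bp$edited$data == 0L] == 0))
  expect_equal(pvc$data[bp$edited$data == 2L][1], m$corrected_means[2])

  # round trip: re-smoothing the corrected image reproduces the PET
  pre <- calc_pre_pvc(pvc, psf_fwhm_mm = 6)
  expect_lt(max(abs(pre$data - bp$pet$data)), 1e-6)
})

test_that("PVCnstd is ~0 on the ideal phantom, positive under an unmodeled hotspot, and drops when it is modeled", {
  bp <- generate_block_phantom(n_rois = 4L)
  fit <- function(edited, pet, labels) {
    m <- build_transfer_matrix(edited, psf_fwhm_mm = 6)
    m <- observe_roi_means(m, pet, edited)
    m <- solve_gtm(m)
    pre <- calc_pre_pvc(pvc_image(edited, m), 6)
    residuals_and_pvcnstd(pet, pre, edited, labels = labels)
  }
  qc0 <- fit(bp$edited, bp$pet, 1:4)
  expect_lt(max(qc0$per_roi$pvcnstd), 1e-9)

  # inject an unmodeled hotspot next to ROI 1
  lab <- bp$edited$data
  hot <- array(FALSE, dim = dim(lab))
  hot[27:32, 14:19, 14:19] <- TRUE
  act <- array(0, dim = dim(lab))
  for (i in 1:4) act[lab == i] <- bp$true_means[i]
  act[hot] <- 3
  pet_hot <- scalar_volume(
    gaussian_smooth(act, 6, c(2, 2, 2)), c(2, 2, 2))
  qc_un <- fit(bp$edited, pet_hot, 1:4)
  expect_gt(qc_un$global_pvcnstd, 1e-4)

  lab2 <- lab
  lab2[hot] <- 9L
  qc_mod <- fit(labeled_volume(lab2, c(2, 2, 2)), pet_hot, 1:4)
  expect_lt(qc_mod$global_pvcnstd, qc_un$global_pvcnstd)
  expect_lt(max(qc_mod$per_roi$pvcnstd), 1e-9)

  # a constant residual has zero standard deviation
  pre_shift <- scalar_volume(bp$pet$data + 0.25, c(2, 2, 2))
  qc_sh <- residuals_and_pvcnstd(bp$pet, pre_shift, bp$edited, labels = 1:4)
  expect_equal(qc_sh$per_roi$residual_mean, rep(0.25, 4))
  expect_lt(max(qc_sh$per_roi$pvcnstd), 1e-12)
})
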