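test_that("the cerebellar split partitions the cerebellar gray exactly", {
  ph <- default_phantom()
  sp <- split_cerebellum(ph$aparc, ph$suit)
  cg <- ph$truth$masks$cerebellar_gray
  expect_identical(sp$inferior_mask | sp$superior_mask, cg)
  expect_false(any(sp$inferior_mask & sp$superior_mask))
  # the SUIT atlas is eroded in the phantom: some gray voxels lie outside
  # it, yet all are assigned
  outside <- cg & ph$suit$data == 0L
  expect_gt(sum(outside), 0L)
  expect_true(all((sp$inferior_mask | sp$superior_mask)[outside]))
  # far from the superior lobules, assignment follows the atlas
  deep_inf <- ph$suit$data %in% suit_inferior_indices &
    cg & ph$truth$masks$inferior_gray_true
  expect_true(mean(sp$inferior_mask[deep_inf]) > 0.95)
})

test_that("equidistant voxels between equal SUIT blocks go to the superior side", {
  d <- c(21, 21, 21)
  suit <- array(0L, dim = d)
  suit[5:7, 10:12, 10:12] <- 6L          # an inferior lobule code
  suit[15:17, 10:12, 10:12] <- 1L        # a superior lobule code, mirrored
  aparc <- array(0L, dim = d)
  aparc[11, 11, 11] <- 8L                # exactly between the blocks
  sp <- split_cerebellum(labeled_volume(aparc), labeled_volume(suit))
  expect_true(sp$superior_mask[11, 11, 11])
  expect_false(sp$inferior_mask[11, 11, 11])
})

test_that("split_cerebellum validates its inputs", {
  d <- c(8, 8, 8)
  empty <- labeled_volume(array(0L, dim = d))
  some_suit <- labeled_volume(array(c(6L, rep(0L, prod(d) - 1)), dim = d))
  some_cg <- labeled_volume(array(c(8L, rep(0L, prod(d) - 1)), dim = d))
  expect_error(split_cerebellum(empty, some_suit), "cerebellar-gray")
  expect_error(split_cerebellum(some_cg, empty), "SUIT")
})

test_that("SUVR normalization divides by the reference mean", {
  d <- c(6, 6, 6)
  pet <- scalar_volume(array(5, dim = d))
  mask <- array(TRUE, dim = d)
  s <- normalize_suvr(pet, mask)
  expect_true(all(s$data == 1))
  expect_equal(attr(s, "reference_mean"), 5)

  mask2 <- array(FALSE, dim = d); mask2[1:3, , ] <- TRUE
  pet2 <- scalar_volume(array(ifelse(mask2, 2, 6), dim = d))
  s2 <- normalize_suvr(pet2, mask2)
  expect_true(all(s2$data[mask2] == 1))
  expect_true(all(s2$data[!mask2] == 3))
  expect_equal(mean(s2$data[mask2]), 1, tolerance = 1e-12)

  expect_error(normalize_suvr(pet, array(FALSE, dim = d)), "empty")
  expect_error(normalize_suvr(scalar_volume(array(0, dim = d)), mask),
               "positive")
})

test_that("reference hotspot scan removes only strictly >500-voxel clusters and renormalizes", {
  d <- c(40, 40, 40)
  ref <- array(FALSE, dim = d)
  ref[2:26, 2:26, 2:17] <- TRUE          # 10,000-voxel reference
  su <- array(1, dim = d)

  # 600-voxel hot cluster inside the reference
  hot <- array(FALSE, dim = d)
  hot[5:14, 5:14, 5:10] <- TRUE          # 10*10*6 = 600
  su[hot] <- 2
  s <- as_suvr(su)
  out <- scan_reference_hotspots(s, ref, next_label = 90L)
  expect_identical(out$n_hotspots, 1L)
  expect_identical(sort(unique(as.vector(out$hotspot_labels))), c(0L, 90L))
  expect_identical(sum(out$hotspot_labels == 90L), 600L)
  expect_identical(out$inferior_mask, ref & !hot)
  expect_identical(sum(out$inferior_mask), 9400L)
  expect_equal(mean(out$suvr$data[out$inferior_mask]), 1, tolerance = 1e-12)
  # the 9,400 clean voxels sat at SUVR 1, so renormalization is a no-op
  # on them and the hotspot stays at 2
  expect_equal(mean(out$suvr$data[hot]), 2, tolerance = 1e-12)

  # exactly 500 voxels: rejected (strict >)
  su2 <- array(1, dim = d)
  hot2 <- array(FALSE, dim = d)
  hot2[5:14, 5:14, 5:9] <- TRUE          # 500
  su2[hot2] <- 2
  out2 <- scan_reference_hotspots(as_suvr(su2), ref, next_label = 90L)
  expect_identical(out2$n_hotspots, 0L)
  expect_identical(out2$inferior_mask, ref)
  expect_identical(out2$suvr$data, su2)

  # nothing above threshold: identity
  out3 <- scan_reference_hotspots(as_suvr(array(1, dim = d)), ref,
                                  next_label = 90L)
  expect_identical(out3$n_hotspots, 0L)
})
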