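mk_prob <- function(p, d) probability_volume(array(p, dim = d))

test_that("the four tissue predicates assign the published codes", {
  d <- c(3, 3, 3)
  ed0 <- labeled_volume(array(0L, dim = d))
  run1 <- function(c1, c3, c45, s, edited = ed0) {
    out <- classify_csf_bone(edited, mk_prob(c1, d), mk_prob(c3, d),
                             mk_prob(c45, d), mk_prob(0, d),
                             as_suvr(array(s, dim = d)))
    out$data[2, 2, 2]
  }
  expect_identical(run1(0, 0.6, 0.2, 0.5), 81L)     # CSF low
  expect_identical(run1(0, 0.6, 0.2, 1.0), 82L)     # CSF high (>= 1)
  expect_identical(run1(0.5, 0.0, 0.0, 0.5), 0L)    # c1 high but c3 = 0
  expect_identical(run1(0.5, 0.1, 0.0, 0.5), 81L)   # gray-by-probability CSF
  expect_identical(run1(0, 0.1, 0.6, 0.5), 83L)     # bone low
  expect_identical(run1(0, 0.1, 0.6, 1.2), 84L)     # bone high
  expect_identical(run1(0, 0.6, 0.2, 0.05), 0L)     # below the SUVR floor
  # assigned voxels are never overwritten
  ed3 <- labeled_volume(array(3L, dim = d))
  expect_identical(run1(0, 0.6, 0.2, 0.5, edited = ed3), 3L)
})

test_that("tissue predicates are mutually exclusive on randomized inputs", {
  set.seed(41)
  n <- 5000
  c1 <- runif(n); c3 <- runif(n); c45 <- runif(n); s <- runif(n, -0.5, 2.5)
  csf <- (c3 > 0.3 | c1 > 0.3) & c3 > 0 & c3 > c45 & s > 0.1
  bone <- c45 > 0.3 & c45 > c3 & s > 0.1
  hits <- cbind(csf & s < 1, csf & s >= 1, bone & s < 1, bone & s >= 1)
  expect_true(all(rowSums(hits) <= 1))
})

test_that("stray gray voxels take the modal neighbor label, ties to the smaller", {
  d <- c(3, 3, 3)
  lab <- array(6L, dim = d)
  lab[2, 2, 2] <- 0L
  lab[, , 3] <- 20L                      # 9 of 26 neighbors are 20
  qual1 <- array(1, dim = d)             # c1 = 1 everywhere
  zero <- array(0, dim = d)
  out <- assign_stray_gray(labeled_volume(lab), mk_prob(qual1, d),
                           mk_prob(zero, d), mk_prob(zero, d),
                           mk_prob(zero, d), as_suvr(array(1, dim = d)))
  expect_identical(out$data[2, 2, 2], 6L)

  # exact tie 13 vs 13 -> smaller label
  lab2 <- array(20L, dim = d)
  lab2[2, 2, 2] <- 0L
  lab2[, , 1] <- 6L; lab2[, 1, 2] <- 6L; lab2[1, 2, 2] <- 6L
  out2 <- assign_stray_gray(labeled_volume(lab2), mk_prob(qual1, d),
                            mk_prob(zero, d), mk_prob(zero, d),
                            mk_prob(zero, d), as_suvr(array(1, dim = d)))
  expect_identical(out2$data[2, 2, 2], 6L)

  # neighborhood all zero -> stays zero
  lab3 <- array(0L, dim = d)
  out3 <- assign_stray_gray(labeled_volume(lab3), mk_prob(qual1, d),
                            mk_prob(zero, d), mk_prob(zero, d),
                            mk_prob(zero, d), as_suvr(array(1, dim = d)))
  expect_true(all(out3$data == 0L))
})

test_that("iterated stray assignment reaches interior voxels; single pass does not", {
  d <- c(7, 3, 3)
  lab <- array(0L, dim = d)
  lab[1, , ] <- 5L                       # labels only at one end
  c1 <- array(0, dim = d); c1[2:6, 2, 2] <- 1   # a stray corridor
  zero <- array(0, dim = d)
  args <- function(maxp) list(labeled_volume(lab), mk_prob(c1, d),
                              mk_prob(zero, d), mk_prob(zero, d),
                              mk_prob(zero, d), as_suvr(array(1, dim = d)),
                              max_passes = maxp)
  one <- do.call(assign_stray_gray, args(1L))
  expect_identical(one$data[2, 2, 2], 5L)
  expect_identical(one$data[4, 2, 2], 0L)      # out of reach in one pass
  full <- do.call(assign_stray_gray, args(10L))
  expect_true(all(full$data[2:6, 2, 2] == 5L))
  expect_lte(attr(full, "passes"), 10L)
  # deterministic
  again <- do.call(assign_stray_gray, args(10L))
  expect_identical(full$data, again$data)
})

test_that("classification never overwrites and only touches qualifying voxels", {
  ph <- default_phantom()
  r <- default_run8()
  before <- remap_labels(ph$aparc)
  after <- r$edited
  nz <- before$data > 0L & before$data != taupvc_labels$reserved_cereb_gray
  expect_identical(after$data[nz], before$data[nz])
})
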