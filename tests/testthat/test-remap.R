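test_that("the built-in remap table covers indices 1..77 with the published entries", {
  tbl <- default_remap_table()
  expect_setequal(tbl$edited_index, 1:77)

  lookup <- function(fs) tbl$edited_index[vapply(tbl$freesurfer_indices,
                                                 function(v) fs %in% v,
                                                 logical(1))]
  expect_identical(lookup(17), 3L)      # L hippocampus
  expect_identical(lookup(53), 4L)      # R hippocampus
  expect_identical(lookup(1012), 32L)   # orbitofrontal composite
  expect_identical(lookup(1014), 32L)
  expect_identical(lookup(1032), 32L)
  expect_identical(lookup(253), 73L)    # corpus callosum range 251..255
  expect_identical(lookup(1000), 76L)   # "Other" grab-bag
  expect_length(lookup(4), 0L)          # ventricles are not table entries
  expect_length(tbl$freesurfer_indices[[77L]], 0L)  # filled by the split

  # no FreeSurfer code is claimed twice
  expect_false(anyDuplicated(unlist(tbl$freesurfer_indices)) > 0)
})

test_that("remap_labels applies the scheme, zeroes ventricles, reserves cerebellar gray", {
  d <- c(6, 6, 6)
  mk <- function(code) labeled_volume(array(code, dim = d))
  expect_true(all(remap_labels(mk(17))$data == 3L))
  expect_true(all(remap_labels(mk(43))$data == 0L))   # R lateral ventricle
  expect_true(all(remap_labels(mk(0))$data == 0L))
  expect_true(all(remap_labels(mk(8))$data ==
                    taupvc_labels$reserved_cereb_gray))
  expect_true(all(remap_labels(mk(47))$data ==
                    taupvc_labels$reserved_cereb_gray))
  # unknown codes drop to zero with a message, choroid codes silently
  expect_message(out <- remap_labels(mk(9999)), "unrecognized")
  expect_true(all(out$data == 0L))
  expect_silent(out2 <- remap_labels(mk(31)))
  expect_true(all(out2$data == 0L))
})

test_that("a volume containing every table code maps onto exactly 1..76", {
  tbl <- default_remap_table()
  codes <- unlist(tbl$freesurfer_indices)
  arr <- array(0L, dim = c(20, 20, 2))
  arr[seq_along(codes)] <- codes
  out <- remap_labels(labeled_volume(arr))
  expect_setequal(setdiff(unique(as.vector(out$data)), 0L), 1:76)
})

test_that("remap tables round-trip through TSV", {
  tbl <- default_remap_table()
  dir <- withr::local_tempdir()
  f <- file.path(dir, "remap.tsv")
  flat <- data.frame(
    edited_index = tbl$edited_index,
    freesurfer_indices = vapply(tbl$freesurfer_indices, paste,
                                character(1), collapse = ","),
    name = tbl$name)
  write.table(flat, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- load_remap_table(f)
  expect_identical(back$edited_index, tbl$edited_index)
  expect_identical(back$freesurfer_indices, tbl$freesurfer_indices)
  expect_identical(back$name, tbl$name)
})

test_that("Braak composites have the published sizes and membership", {
  comp <- braak_composites()
  expect_length(comp$braak_12, 4L)
  expect_length(comp$braak_34, 24L)
  expect_length(comp$braak_56, 34L)
  expect_false(any(c(14L, 23L) %in% comp$braak_34))
  expect_false(any(c(35L, 36L, 41L, 45L, 51L, 52L, 57L, 61L) %in%
                     comp$braak_56))
  expect_false(any(duplicated(unlist(comp))))
})

test_that("Braak means weight by voxel count and skip absent members", {
  means <- c("1" = 2, "2" = 2, "3" = 4, "4" = 4)
  counts <- c("1" = 10L, "2" = 10L, "3" = 10L, "4" = 10L)
  comp <- list(braak_12 = 1:4)
  expect_equal(unname(braak_means(means, counts, comp)), 3)

  counts2 <- c("1" = 30L, "2" = 30L, "3" = 10L, "4" = 10L)
  expect_equal(unname(braak_means(means, counts2, comp)), 2.5)
  expect_equal(unname(braak_means(means, counts2, comp, weighted = FALSE)), 3)

  # members outside a composite contribute nothing; absent members warn
  means34 <- c("5" = 1, "14" = 100)
  counts34 <- c("5" = 10L, "14" = 10L)
  expect_warning(
    got <- braak_means(means34, counts34, list(braak_34 = braak_composites()$braak_34)),
    "missing")
  expect_equal(unname(got), 1)
  expect_error(
    suppressWarnings(braak_means(c("50" = 1), c("50" = 1L),
                                 list(braak_12 = 1:4))),
    "no member")
})
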