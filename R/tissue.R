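#' Classify remaining voxels into CSF and bone+meninges ROIs
#'
#' Voxels undefined in the segmentation (edited label 0) that were not
#' classified as hotspots carry real tracer signal that would otherwise be
#' assumed zero by the GTM. They are classified by tissue probability and
#' SUVR:
#'
#' * CSF low (81): (c3 > 0.3 or c1 > 0.3), c3 > 0, c3 > c4+c5, and
#'   0.1 < SUVR < 1. The gray-matter probability is consulted because the
#'   two segmentations disagree at the gray/CSF boundary: a voxel the
#'   surface segmentation calls nothing but the tissue segmentation calls
#'   gray is treated as CSF here.
#' * CSF high (82): same, except SUVR >= 1 (no upper bound).
#' * bone+meninges low (83): c4+c5 > 0.3, c4+c5 > c3, 0.1 < SUVR < 1.
#' * bone+meninges high (84): same, except SUVR >= 1.
#'
#' Never overwrites a nonzero label. The four predicates are mutually
#' exclusive at any voxel.
#'
#' @param edited `taupvc_label` volume (the edited segmentation so far).
#' @param c1,c3,c4,c5 `taupvc_prob` volumes.
#' @param suvr `taupvc_scalar` SUVR volume.
#' @param probability_cut tissue probability cut (default 0.3).
#' @param suvr_floor lower SUVR bound (default 0.1, strict).
#' @param suvr_split low/high split (default 1; low is strict <, high >=).
#' @return Updated `taupvc_label` volume.
#' @export
classify_csf_bone <- function(edited, c1, c3, c4, c5, suvr,
                              probability_cut = 0.3, suvr_floor = 0.1,
                              suvr_split = 1) {
  stopifnot(inherits(edited, "taupvc_label"), suvr_floor < suvr_split)
  free <- edited$data == 0L
  p1 <- c1$data; p3 <- c3$data; p45 <- c4$data + c5$data
  s <- suvr$data
  csf <- free & (p3 > probability_cut | p1 > probability_cut) &
         p3 > 0 & p3 > p45 & s > suvr_floor
  bone <- free & p45 > probability_cut & p45 > p3 & s > suvr_floor
  out <- edited$data
  out[csf & s < suvr_split] <- taupvc_labels$csf_low
  out[csf & s >= suvr_split] <- taupvc_labels$csf_high
  out[bone & s < suvr_split] <- taupvc_labels$bone_low
  out[bone & s >= suvr_split] <- taupvc_labels$bone_high
  with_data(edited, out)
}

#' Assign stray gray-matter voxels by neighborhood vote
#'
#' Voxels with gray-matter probability above 0.3, exactly zero probability
#' of CSF, skull and meninges, SUVR above 0.1, and still unassigned are
#' mostly gray matter missed by the surface segmentation; left at 0 they
#' would be assumed signal-free by the GTM. Each such voxel receives the
#' most common nonzero label among its 26 neighbors (ties go to the
#' smallest label, for determinism). Because one sweep can leave interior
#' strays without labeled neighbors, the sweep repeats until no voxel
#' changes or `max_passes` is reached; set `max_passes = 1` for a strict
#' single application.
#'
#' @param edited `taupvc_label` volume after [classify_csf_bone()].
#' @param c1,c3,c4,c5 `taupvc_prob` volumes.
#' @param suvr `taupvc_scalar` SUVR volume.
#' @param probability_cut gray-probability cut (default 0.3).
#' @param suvr_floor SUVR floor (default 0.1, strict).
#' @param zero_tol values below this count as exactly zero probability.
#' @param max_passes maximum number of sweeps (default 10).
#' @return Updated `taupvc_label` volume; the number of passes used is
#'   attached as attribute `passes`.
#' @export
assign_stray_gray <- function(edited, c1, c3, c4, c5, suvr,
                              probability_cut = 0.3, suvr_floor = 0.1,
                              zero_tol = 1e-9, max_passes = 10L) {
  stopifnot(inherits(edited, "taupvc_label"))
  d <- dim(edited$data)
  qual <- c1$data > probability_cut &
          c3$data < zero_tol & c4$data < zero_tol & c5$data < zero_tol &
          suvr$data > suvr_floor
  lab <- edited$data
  offs <- neighbor_offsets(26L)
  passes <- 0L
  repeat {
    todo <- which(qual & lab == 0L)
    if (length(todo) == 0L || passes >= max_passes) break
    new_lab <- modal_neighbor_label(lab, todo, offs, d)
    changed <- new_lab > 0L
    if (!any(changed)) break
    lab[todo[changed]] <- new_lab[changed]
    passes <- passes + 1L
  }
  out <- with_data(edited, lab)
  attr(out, "passes") <- passes
  out
}

# Modal nonzero label over the 26-neighborhood of each linear index in
# `todo`; 0 where no labeled neighbor exists. Ties -> smallest label.
modal_neighbor_label <- function(lab, todo, offs, d) {
  coords <- arrayInd(todo, d)
  n <- length(todo)
  neigh <- matrix(0L, n, nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[i, ], n, 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    lin <- nb[ok, 1L] + d[1L] * (nb[ok, 2L] - 1L) +
           d[1L] * d[2L] * (nb[ok, 3L] - 1L)
    neigh[ok, i] <- lab[lin]
  }
  vapply(seq_len(n), function(j) {
    v <- neigh[j, ]
    v <- v[v > 0L]
    if (length(v) == 0L) return(0L)
    tb <- table(v)
    best <- tb[tb == max(tb)]
    as.integer(names(best)[1L])   # table names sort numerically ascending
  }, integer(1))
}
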