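# Independent oracles used across the suite. These are deliberately naive
# (brute-force) implementations, kept separate from the package's code
# paths.

# Breadth-first flood fill: reference connected-component labeling.
flood_fill_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  s <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = s == 1, "18" = s >= 1 & s <= 2, "26" = s >= 1), ,
               drop = FALSE]
  out <- array(0L, dim = d)
  cur <- 0L
  for (start in which(mask != 0)) {
    if (out[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    out[start] <- cur
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      co <- arrayInd(v, d)
      for (k in seq_len(nrow(offs))) {
        nb <- co + offs[k, ]
        if (any(nb < 1L) || nb[1L] > d[1L] || nb[2L] > d[2L] || nb[3L] > d[3L])
          next
        lin <- nb[1L] + d[1L] * (nb[2L] - 1L) + d[1L] * d[2L] * (nb[3L] - 1L)
        if (mask[lin] != 0 && out[lin] == 0L) {
          out[lin] <- cur
          queue <- c(queue, lin)
        }
      }
    }
  }
  out
}

# Canonical form of a component labeling: relabel each component by the
# smallest linear index it contains, so two labelings can be compared as
# partitions.
canonical_components <- function(lab) {
  out <- array(0L, dim = dim(lab))
  for (id in setdiff(unique(as.vector(lab)), 0L)) {
    vox <- which(lab == id)
    out[vox] <- min(vox)
  }
  out
}

# Direct dense Gaussian convolution at one voxel: definition-based sum
# over a truncated, unit-normalized 3D kernel.
dense_gauss_at <- function(x, v, fwhm_mm, voxel_size_mm) {
  d <- dim(x)
  sigma <- (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
  sigma <- rep_len(sigma, 3L)
  r <- pmax(1L, ceiling(4 * sigma))
  off <- as.matrix(expand.grid(-r[1]:r[1], -r[2]:r[2], -r[3]:r[3]))
  w <- exp(-0.5 * (off[, 1]^2 / sigma[1]^2 + off[, 2]^2 / sigma[2]^2 +
                   off[, 3]^2 / sigma[3]^2))
  w <- w / sum(w)
  src <- matrix(rep(v, each = nrow(off)), ncol = 3L) + off
  ok <- src[, 1] >= 1 & src[, 1] <= d[1] & src[, 2] >= 1 & src[, 2] <= d[2] &
        src[, 3] >= 1 & src[, 3] <= d[3]
  lin <- src[ok, 1] + d[1] * (src[ok, 2] - 1) + d[1] * d[2] * (src[ok, 3] - 1)
  sum(w[ok] * x[lin])
}

# SVD-based dense least-squares solve, the oracle for the GTM solver.
svd_lstsq <- function(a, b) {
  s <- svd(a)
  as.numeric(s$v %*% ((t(s$u) %*% b) / s$d))
}
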