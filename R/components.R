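#' Connected components of a 3D mask
#'
#' Labels the connected components of a logical 3D mask under 6-, 18- or
#' 26-connectivity (default 26, the usual convention for 3D cluster
#' detection in neuroimaging). Components are numbered deterministically:
#' descending voxel count, ties broken by the lexicographically smallest
#' (x, y, z) minimum corner of the component's bounding box, so repeated
#' runs on the same input give identical labels.
#'
#' @param mask logical (or 0/1) 3D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape: 0 outside the mask, component
#'   id (1, 2, ...) inside, numbered largest-first.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3L)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  d <- dim(mask)
  fg <- which(mask != 0)
  out <- array(0L, dim = d)
  if (length(fg) == 0L) return(out)

  coords <- arrayInd(fg, d)
  inside <- array(FALSE, dim = d)
  inside[fg] <- TRUE
  rank <- array(0L, dim = d)
  rank[fg] <- seq_along(fg)

  offs <- neighbor_offsets(connectivity)
  # only "positive" half of the neighborhood: each edge found once
  offs <- offs[offs[, 3L] > 0L |
               (offs[, 3L] == 0L & offs[, 2L] > 0L) |
               (offs[, 3L] == 0L & offs[, 2L] == 0L & offs[, 1L] > 0L), ,
               drop = FALSE]

  edges <- vector("list", nrow(offs))
  for (i in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[i, ], nrow(coords), 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    if (!any(ok)) next
    lin <- nb[ok, 1L] + d[1L] * (nb[ok, 2L] - 1L) +
           d[1L] * d[2L] * (nb[ok, 3L] - 1L)
    hit <- inside[lin]
    if (!any(hit)) next
    edges[[i]] <- cbind(rank[fg[ok]][hit], rank[lin[hit]])
  }
  edges <- do.call(rbind, edges)

  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership

  out[fg] <- order_component_ids(memb, coords)
  out
}

# Renumber raw membership ids: descending size, ties by lexicographically
# smallest (x, y, z) minimum corner.
order_component_ids <- function(memb, coords) {
  sizes <- tabulate(memb)
  minx <- tapply(coords[, 1L], memb, min)
  miny <- tapply(coords[, 2L], memb, min)
  minz <- tapply(coords[, 3L], memb, min)
  ord <- order(-sizes, minx, miny, minz)
  new_id <- integer(length(sizes))
  new_id[ord] <- seq_along(ord)
  as.integer(new_id[memb])
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  s <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = s == 1L,
                 "18" = s >= 1L & s <= 2L,
                 "26" = s >= 1L)
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

#' Extract clusters above a size cutoff
#'
#' Thresholds a mask's connected components by voxel count. Used for
#' extra-cortical hotspots and reference-region hotspots (strictly more
#' than `min_voxels`) and for choroid plexus seeds (at least `min_voxels`).
#'
#' @param mask logical 3D array.
#' @param min_voxels size cutoff.
#' @param strict if `TRUE`, keep components with size > `min_voxels`;
#'   otherwise >= `min_voxels`.
#' @param connectivity passed to [label_components()].
#' @return list with `labels` (integer array; surviving components
#'   renumbered 1..k in the deterministic order) and `sizes` (integer
#'   vector of the surviving component sizes).
#' @export
filter_clusters <- function(mask, min_voxels, strict = TRUE,
                            connectivity = 26L) {
  comp <- label_components(mask, connectivity)
  sizes <- tabulate(comp[comp > 0L])
  keep <- if (strict) sizes > min_voxels else sizes >= min_voxels
  out <- array(0L, dim = dim(comp))
  if (any(keep)) {
    kept <- which(keep)          # already in deterministic order
    remap <- integer(length(sizes))
    remap[kept] <- seq_along(kept)
    pos <- comp > 0L
    out[pos] <- remap[comp[pos]]
  }
  list(labels = out, sizes = sizes[keep])
}
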