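# Grid-bucket (cell list) fixed-radius neighbor search. Points are binned
# into square cells of side >= radius, so all neighbors of a point lie in
# the 3 x 3 block of cells around it. This is the accelerated counting path
# behind local density, the co-localization index and DBSCAN; the tests hold
# it against brute-force all-pairs oracles.

.grid_key <- function(ix, iy) paste(ix, iy, sep = ",")

.grid_bin <- function(pts, cell, origin) {
  ix <- floor((pts[, 1] - origin[1]) / cell)
  iy <- floor((pts[, 2] - origin[2]) / cell)
  list(ix = ix, iy = iy, key = .grid_key(ix, iy))
}

# Candidate indices (into ref) for each occupied query cell.
.cell_candidates <- function(ix, iy, ref_cells) {
  keys <- .grid_key(rep(ix + (-1:1), each = 3), rep(iy + (-1:1), times = 3))
  unlist(ref_cells[keys], use.names = FALSE)
}

#' Count neighbors within a fixed radius (same point set)
#'
#' For each point, the number of points of the same set within Euclidean
#' distance `radius` (boundary inclusive). With `include_self = FALSE` the
#' point itself is not counted; coincident duplicates (distinct records at
#' distance 0) are always counted.
#'
#' @param pts n x 2 matrix of coordinates (nm).
#' @param radius search radius (nm), > 0.
#' @param include_self logical; count the point itself (distance 0)?
#' @param exclude_zero logical; when TRUE, count only strictly positive
#'   distances (drops the point itself *and* coincident duplicates),
#'   overriding `include_self`.
#' @return integer vector of length n.
#' @keywords internal
radius_count <- function(pts, radius, include_self = FALSE,
                         exclude_zero = FALSE) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  stopifnot(radius > 0)
  origin <- c(min(pts[, 1]), min(pts[, 2]))
  g <- .grid_bin(pts, radius, origin)
  cells <- split(seq_len(n), g$key)
  counts <- integer(n)
  for (ids in cells) {
    i1 <- ids[1]
    cand <- .cell_candidates(g$ix[i1], g$iy[i1], cells)
    d2 <- outer(pts[cand, 1], pts[ids, 1], "-")^2 +
          outer(pts[cand, 2], pts[ids, 2], "-")^2
    counts[ids] <- if (exclude_zero) {
      colSums(d2 <= radius^2 & d2 > 0)
    } else {
      colSums(d2 <= radius^2)
    }
  }
  if (!exclude_zero && !include_self) counts <- counts - 1L
  as.integer(counts)
}

#' Count reference points within a radius of each query point
#'
#' @param query m x 2 matrix; points at which to count.
#' @param ref n x 2 matrix; points being counted.
#' @param radius search radius (nm), > 0; boundary inclusive.
#' @param exclude_zero logical; when TRUE, zero-distance hits (a reference
#'   point exactly coincident with the query) are not counted.
#' @return integer vector of length m.
#' @keywords internal
cross_radius_count <- function(query, ref, radius, exclude_zero = FALSE) {
  m <- nrow(query)
  if (m == 0) return(integer(0))
  if (nrow(ref) == 0) return(integer(m))
  stopifnot(radius > 0)
  origin <- c(min(query[, 1], ref[, 1]), min(query[, 2], ref[, 2]))
  gq <- .grid_bin(query, radius, origin)
  gr <- .grid_bin(ref, radius, origin)
  ref_cells <- split(seq_len(nrow(ref)), gr$key)
  counts <- integer(m)
  qcells <- split(seq_len(m), gq$key)
  for (ids in qcells) {
    i1 <- ids[1]
    cand <- .cell_candidates(gq$ix[i1], gq$iy[i1], ref_cells)
    if (length(cand) == 0) next
    d2 <- outer(ref[cand, 1], query[ids, 1], "-")^2 +
          outer(ref[cand, 2], query[ids, 2], "-")^2
    counts[ids] <- if (exclude_zero) {
      colSums(d2 <= radius^2 & d2 > 0)
    } else {
      colSums(d2 <= radius^2)
    }
  }
  as.integer(counts)
}

#' Radius neighbor lists (same point set, self included)
#' @return list of integer vectors; element i holds indices j with
#'   d(i, j) <= radius, including i itself.
#' @keywords internal
radius_neighbors <- function(pts, radius) {
  n <- nrow(pts)
  if (n == 0) return(list())
  stopifnot(radius > 0)
  origin <- c(min(pts[, 1]), min(pts[, 2]))
  g <- .grid_bin(pts, radius, origin)
  cells <- split(seq_len(n), g$key)
  out <- vector("list", n)
  for (ids in cells) {
    i1 <- ids[1]
    cand <- .cell_candidates(g$ix[i1], g$iy[i1], cells)
    d2 <- outer(pts[cand, 1], pts[ids, 1], "-")^2 +
          outer(pts[cand, 2], pts[ids, 2], "-")^2
    for (k in seq_along(ids)) out[[ids[k]]] <- cand[d2[, k] <= radius^2]
  }
  out
}

#' Nearest-neighbor distance of each point
#'
#' Grid search: a first pass scans the 3 x 3 cell block (sufficient whenever
#' the nearest neighbor is within one cell width); unresolved points fall
#' back to an exact scan against all points.
#'
#' @param pts n x 2 matrix, n >= 2.
#' @return numeric vector of length n.
#' @keywords internal
nearest_neighbor_dist <- function(pts) {
  n <- nrow(pts)
  if (n < 2) stop("nearest-neighbor distance needs at least 2 points")
  span <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), .Machine$double.eps)
  cell <- max(1.5 * span / sqrt(n), span * 1e-9)
  origin <- c(min(pts[, 1]), min(pts[, 2]))
  g <- .grid_bin(pts, cell, origin)
  cells <- split(seq_len(n), g$key)
  nnd <- rep(Inf, n)
  for (ids in cells) {
    i1 <- ids[1]
    cand <- .cell_candidates(g$ix[i1], g$iy[i1], cells)
    if (length(cand) < 2) next
    d2 <- outer(pts[cand, 1], pts[ids, 1], "-")^2 +
          outer(pts[cand, 2], pts[ids, 2], "-")^2
    d2[cbind(match(ids, cand), seq_along(ids))] <- Inf
    nnd[ids] <- sqrt(apply(d2, 2, min))
  }
  # guaranteed correct only when the neighbor found is within one cell width
  unresolved <- which(!(nnd <= cell))
  for (i in unresolved) {
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    d2[i] <- Inf
    nnd[i] <- sqrt(min(d2))
  }
  nnd
}
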