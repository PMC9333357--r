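# Planar geometry primitives used by ROI segmentation and the Voronoi
# nanodomain boundaries. Polygons are n x 2 matrices of vertices in nm,
# open rings (the first vertex is not repeated at the end).

#' Polygon area by the shoelace formula
#'
#' @param poly numeric matrix with columns x, y (nm); vertices of a simple
#'   polygon, first vertex not repeated.
#' @return area in nm^2 (non-negative).
#' @export
polygon_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Polygon centroid (area-weighted)
#' @keywords internal
polygon_centroid <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(colMeans(poly))
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

#' Test points against a closed polygon
#'
#' Even-odd ray casting; points on the boundary count as inside (closed
#' polygon convention, so a localization on a synapse ROI edge belongs to it).
#'
#' @param px,py point coordinates (nm), equal length.
#' @param poly polygon matrix (x, y).
#' @param boundary_tol distance (nm) under which a point is treated as lying
#'   on an edge.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly, boundary_tol = 1e-9) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(rep(FALSE, length(px)))
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    crosses <- (ys[k] > py) != (ye[k] > py)
    if (any(crosses)) {
      xint <- xs[k] + (py[crosses] - ys[k]) * (xe[k] - xs[k]) / (ye[k] - ys[k])
      idx <- which(crosses)[xint > px[crosses]]
      inside[idx] <- !inside[idx]
    }
    # distance from points to segment k
    dx <- xe[k] - xs[k]; dy <- ye[k] - ys[k]
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, length(px)) else
      pmin(1, pmax(0, ((px - xs[k]) * dx + (py - ys[k]) * dy) / L2))
    d2 <- (px - (xs[k] + t * dx))^2 + (py - (ys[k] + t * dy))^2
    on_edge <- on_edge | d2 <= boundary_tol^2
  }
  inside | on_edge
}

# Clip a convex polygon with edge labels to the half-plane a*x + b*y <= c
# (Sutherland-Hodgman). lab[k] identifies the constraint that generated the
# edge starting at vertex k (0 = original clip polygon edge); the edge
# created by this cut is labeled `newlab`. Convexity guarantees a single
# entry and exit, hence one new edge.
clip_halfplane_lab <- function(poly, lab, a, b, cc, newlab) {
  n <- nrow(poly)
  if (is.null(n) || n == 0) return(list(poly = poly, lab = lab))
  v <- a * poly[, 1] + b * poly[, 2] - cc
  if (all(v <= 0)) return(list(poly = poly, lab = lab))
  if (all(v >= 0)) {
    return(list(poly = poly[0, , drop = FALSE], lab = integer(0)))
  }
  outp <- matrix(0, n + 2, 2)
  outl <- integer(n + 2)
  m <- 0L
  for (k in seq_len(n)) {
    k2 <- if (k == n) 1L else k + 1L
    in1 <- v[k] <= 0; in2 <- v[k2] <= 0
    if (in1) {
      m <- m + 1L; outp[m, ] <- poly[k, ]
      outl[m] <- lab[k]
    }
    if (in1 != in2) {
      t <- v[k] / (v[k] - v[k2])
      m <- m + 1L
      outp[m, ] <- poly[k, ] + t * (poly[k2, ] - poly[k, ])
      outl[m] <- if (in1) newlab else lab[k]
    }
  }
  list(poly = outp[seq_len(m), , drop = FALSE], lab = outl[seq_len(m)])
}

# Backwards-compatible unlabeled clip.
clip_halfplane <- function(poly, a, b, cc) {
  clip_halfplane_lab(poly, integer(nrow(poly)), a, b, cc, 0L)$poly
}

# Labeled Voronoi cell of site `i` among all `points`, clipped to
# `clip_poly`. Competing sites are visited nearest-first so clipping stops
# once a bisector can no longer cut the current cell. Edge labels are global
# point indices (0 for clip-polygon edges).
voronoi_cell_site <- function(i, points, clip_poly) {
  poly <- clip_poly
  if (nrow(poly) < 3) {
    return(list(poly = poly[0, , drop = FALSE], lab = integer(0)))
  }
  lab <- integer(nrow(poly))
  site <- points[i, ]
  d2 <- (points[, 1] - site[1])^2 + (points[, 2] - site[2])^2
  d2[i] <- Inf
  ord <- order(d2)
  rmax2 <- max((poly[, 1] - site[1])^2 + (poly[, 2] - site[2])^2)
  for (j in ord) {
    if (!is.finite(d2[j])) break
    if (d2[j] <= 0) next  # coincident duplicate shares the cell
    if (d2[j] > 4 * rmax2) break
    cl <- clip_halfplane_lab(
      poly, lab,
      2 * (points[j, 1] - site[1]), 2 * (points[j, 2] - site[2]),
      points[j, 1]^2 + points[j, 2]^2 - site[1]^2 - site[2]^2, j
    )
    poly <- cl$poly; lab <- cl$lab
    if (nrow(poly) < 3) {
      return(list(poly = poly[0, , drop = FALSE], lab = integer(0)))
    }
    rmax2 <- max((poly[, 1] - site[1])^2 + (poly[, 2] - site[2])^2)
  }
  list(poly = poly, lab = lab)
}

#' Voronoi cell of one site, clipped to a polygon
#'
#' Intersects the clip polygon with the half-planes closer to `site` than to
#' each other site.
#'
#' @param site length-2 numeric (x, y).
#' @param others matrix of the competing sites.
#' @param clip_poly bounding polygon (e.g. the synapse ROI).
#' @return polygon matrix (possibly with 0 rows when the site lies outside
#'   the clip polygon).
#' @keywords internal
voronoi_cell <- function(site, others, clip_poly) {
  pts <- rbind(matrix(site, 1, 2), as.matrix(others))
  voronoi_cell_site(1L, pts, clip_poly)$poly
}

# Labeled Voronoi cells for a subset of sites among all points, clipped to a
# polygon. Returns a list of list(poly, lab), one per element of member_idx.
voronoi_cells_labeled <- function(member_idx, points, clip_poly) {
  lapply(member_idx, function(i) voronoi_cell_site(i, points, clip_poly))
}

# Plain polygons of the labeled cells.
voronoi_cells <- function(member_idx, points, clip_poly) {
  lapply(voronoi_cells_labeled(member_idx, points, clip_poly),
         function(cl) cl$poly)
}

# Outer boundary ring(s) of a union of labeled Voronoi cells. Internal edges
# are bisector edges against another member site (their label is a member
# index); they cancel between adjacent cells. Remaining edges are chained
# into rings by endpoint matching.
voronoi_union_rings <- function(cells_lab, member_idx, points, tol = 1e-6) {
  segs <- list()
  is_member <- rep(FALSE, nrow(points))
  is_member[member_idx] <- TRUE
  for (ci in seq_along(cells_lab)) {
    poly <- cells_lab[[ci]]$poly
    lab <- cells_lab[[ci]]$lab
    n <- nrow(poly)
    if (is.null(n) || n < 3) next
    nxt <- c(2:n, 1)
    internal <- lab > 0L & is_member[pmax(lab, 1L)]
    keep <- which(!internal)
    for (k in keep) {
      segs[[length(segs) + 1L]] <- c(poly[k, ], poly[nxt[k], ])
    }
  }
  if (length(segs) == 0) return(list())
  segm <- do.call(rbind, segs)
  key <- function(x, y) paste(round(x / tol), round(y / tol))
  from <- key(segm[, 1], segm[, 2])
  used <- rep(FALSE, nrow(segm))
  start_of <- split(seq_len(nrow(segm)), from)
  rings <- list()
  for (s in seq_len(nrow(segm))) {
    if (used[s]) next
    ring <- segm[s, 1:2, drop = FALSE]
    used[s] <- TRUE
    cur <- segm[s, 3:4]
    k0 <- key(segm[s, 1], segm[s, 2])
    repeat {
      kc <- key(cur[1], cur[2])
      if (identical(kc, k0)) break
      cand <- start_of[[kc]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) break  # open chain: numerical mismatch, stop
      ring <- rbind(ring, cur)
      used[cand[1]] <- TRUE
      cur <- segm[cand[1], 3:4]
    }
    if (nrow(ring) >= 3) rings[[length(rings) + 1L]] <- unname(ring)
  }
  # largest ring first (outer boundary)
  if (length(rings) > 1) {
    rings <- rings[order(vapply(rings, polygon_area, 0), decreasing = TRUE)]
  }
  rings
}

#' Convex hull polygon of a point set
#' @keywords internal
convex_hull_poly <- function(points) {
  h <- grDevices::chull(points[, 1], points[, 2])
  points[h, , drop = FALSE]
}

# Axis-aligned bounding box polygon, optionally padded.
bbox_poly <- function(points, pad = 0) {
  rx <- range(points[, 1]); ry <- range(points[, 2])
  matrix(c(rx[1] - pad, ry[1] - pad,
           rx[2] + pad, ry[1] - pad,
           rx[2] + pad, ry[2] + pad,
           rx[1] - pad, ry[2] + pad), ncol = 2, byrow = TRUE)
}
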