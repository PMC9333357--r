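# Subsynaptic nanodomain detection by local point density, subcluster
# splitting, Voronoi-cell boundaries, PSD centroid and topology metrics.
#
# Pipeline per synapse and channel: (1) local density (LD) of every
# localization at radius 5 x MNND; (2) keep localizations with LD > 40;
# (3) group kept localizations by single-linkage clustering cut at the LD
# radius; (4) split groups holding multiple density peaks (> 80% of the
# maximum LD, > 80 nm apart, separated by a local minimum < 30% of the
# maximum); (5) bound each group by the union of its members' Voronoi cells
# clipped to the synapse ROI; (6) discard groups holding < 5% of the
# synapse's channel localizations or with an equal-area-circle diameter
# < 30 nm. All inequalities are strict.

#' Mean nearest-neighbor distance (MNND)
#'
#' Arithmetic mean over points of the Euclidean distance to each point's
#' nearest other point.
#'
#' @param points n x 2 matrix (nm), n >= 2.
#' @return MNND in nm.
#' @export
#' @examples
#' mnnd(cbind(c(0, 1, 3), 0))  # 4/3
mnnd <- function(points) {
  points <- as_points(points)
  if (nrow(points) < 2) stop("MNND is undefined for fewer than 2 points")
  mean(nearest_neighbor_dist(points))
}

as_points <- function(p) {
  if (inherits(p, "loc_table") || is.data.frame(p)) {
    cbind(p$x, p$y)
  } else {
    m <- as.matrix(p)
    stopifnot(ncol(m) == 2)
    m
  }
}

#' Local density of each point
#'
#' Number of *other* points of the same set within `radius` (boundary
#' inclusive; the point itself is excluded, so an isolated point has LD 0).
#'
#' @param points n x 2 matrix or localization table.
#' @param radius counting radius in nm (> 0); conventionally 5 x MNND.
#' @return integer vector of counts.
#' @export
local_density <- function(points, radius) {
  points <- as_points(points)
  if (nrow(points) == 0) return(integer(0))
  radius_count(points, radius, include_self = FALSE)
}

#' Nanodomain detection parameters
#'
#' Defaults are the published operating point of the analysis: counting
#' radius 5 x MNND, LD threshold 40, subcluster peaks > 80% of the maximum
#' LD and > 80 nm apart with a corridor minimum < 30%, and retention rules
#' of >= 5% of the synapse's channel localizations and an equal-area-circle
#' diameter >= 30 nm.
#'
#' @param density_radius_factor multiple of the MNND used as the LD radius.
#' @param ld_threshold a localization is part of a nanodomain if LD strictly
#'   exceeds this count.
#' @param peak_fraction subcluster peaks must exceed this fraction of the
#'   group's maximum LD.
#' @param peak_min_separation minimum peak separation (nm) for a split.
#' @param valley_fraction the corridor LD minimum must fall below this
#'   fraction of the maximum LD for a split.
#' @param corridor_width width (nm) of the straight corridor between two
#'   peaks over which the valley minimum is taken.
#' @param min_member_fraction retained nanodomains hold at least this
#'   fraction of the synapse's channel localizations (strict exclusion below).
#' @param min_diameter minimum equal-area-circle diameter (nm, strict
#'   exclusion below).
#' @param linkage_cut_factor dendrogram cut distance as a multiple of the LD
#'   radius (default 1: cut at the LD radius itself).
#' @export
nanodomain_params <- function(density_radius_factor = 5, ld_threshold = 40,
                              peak_fraction = 0.80, peak_min_separation = 80,
                              valley_fraction = 0.30, corridor_width = 40,
                              min_member_fraction = 0.05, min_diameter = 30,
                              linkage_cut_factor = 1) {
  stopifnot(density_radius_factor > 0, ld_threshold > 0,
            peak_fraction > 0, peak_fraction < 1,
            valley_fraction > 0, valley_fraction < 1,
            min_member_fraction > 0, min_member_fraction < 1,
            peak_min_separation > 0, corridor_width > 0, min_diameter > 0,
            linkage_cut_factor > 0)
  structure(as.list(environment()), class = "nanodomain_params")
}

#' Detect nanodomains in one synapse channel
#'
#' @param points channel localizations of one synapse (matrix or
#'   [loc_table()]), >= 2 points.
#' @param params a [nanodomain_params()].
#' @param roi clip polygon for the Voronoi boundary (nm); default the
#'   bounding box of `points` padded by the LD radius.
#' @param ld optional precomputed LD vector (at radius
#'   `density_radius_factor * mnnd`); computed when `NULL`.
#' @return list of `nanodomain` objects (members: indices into `points`;
#'   center: member centroid, nm; boundary: outer ring of the Voronoi-cell
#'   union; cells: the member Voronoi cells; area_nm2; diameter: nm,
#'   equal-area circle; diameter_max: max pairwise member distance;
#'   member_fraction). Attributes: `mnnd`, `radius`, `ld`,
#'   `n_candidates_dropped`. Empty list when no point passes the LD
#'   threshold.
#' @export
detect_nanodomains <- function(points, params = nanodomain_params(),
                               roi = NULL, ld = NULL) {
  pts <- as_points(points)
  n <- nrow(pts)
  if (n < 2) stop("nanodomain detection needs at least 2 points")
  mn <- mnnd(pts)
  radius <- params$density_radius_factor * mn
  if (is.null(ld)) ld <- local_density(pts, radius)
  if (is.null(roi)) roi <- bbox_poly(pts, pad = radius)
  empty <- structure(list(), mnnd = mn, radius = radius, ld = ld,
                     n_candidates_dropped = 0L)
  kept <- which(ld > params$ld_threshold)
  if (length(kept) == 0) return(empty)
  # single-linkage groups of high-density points, cut at the LD radius
  cut_h <- params$linkage_cut_factor * radius
  if (length(kept) == 1) {
    groups <- list(kept)
  } else {
    hc <- stats::hclust(stats::dist(pts[kept, , drop = FALSE]),
                        method = "single")
    lab <- stats::cutree(hc, h = cut_h)
    groups <- split(kept, lab)
  }
  # subcluster splitting
  groups <- unlist(lapply(groups, function(g) {
    split_nanodomain(pts[g, , drop = FALSE], ld[g], params) |>
      lapply(function(sub) g[sub])
  }), recursive = FALSE)
  dropped <- 0L
  out <- list()
  for (g in groups) {
    cells_lab <- voronoi_cells_labeled(g, pts, roi)
    cells <- lapply(cells_lab, function(cl) cl$poly)
    area <- sum(vapply(cells, polygon_area, 0))
    diameter <- 2 * sqrt(area / pi)
    frac <- length(g) / n
    if (frac < params$min_member_fraction || diameter < params$min_diameter) {
      dropped <- dropped + 1L
      next
    }
    dmax <- if (length(g) > 1) max(stats::dist(pts[g, , drop = FALSE])) else 0
    rings <- voronoi_union_rings(cells_lab, g, pts)
    out[[length(out) + 1L]] <- structure(
      list(members = g, center = colMeans(pts[g, , drop = FALSE]),
           boundary = if (length(rings)) rings[[1]] else NULL,
           rings = rings, cells = cells, area_nm2 = area,
           diameter = diameter, diameter_max = dmax,
           member_fraction = frac),
      class = "nanodomain")
  }
  structure(out, mnnd = mn, radius = radius, ld = ld,
            n_candidates_dropped = dropped)
}

#' @export
print.nanodomain <- function(x, ...) {
  cat(sprintf(paste0("<nanodomain> %d members (%.1f%%), center (%.0f, %.0f) nm, ",
                     "diameter %.0f nm\n"),
              length(x$members), 100 * x$member_fraction,
              x$center[1], x$center[2], x$diameter))
  invisible(x)
}

#' Split a candidate nanodomain at multiple local-density peaks
#'
#' Peaks are members whose LD is maximal among members within
#' `peak_min_separation / 2` of themselves. The group splits between two
#' peaks iff both exceed `peak_fraction` of the group's maximum LD, they are
#' more than `peak_min_separation` apart, and the minimum LD among members in
#' a `corridor_width`-wide straight corridor between them falls below
#' `valley_fraction` of the maximum LD. Members are reassigned to the nearest
#' retained peak.
#'
#' @param group_points member coordinates (m x 2, nm).
#' @param ld member LD values (length m).
#' @param params a [nanodomain_params()].
#' @return list of integer index vectors into the group (length 1 when no
#'   split occurs).
#' @export
split_nanodomain <- function(group_points, ld, params = nanodomain_params()) {
  pts <- as_points(group_points)
  m <- nrow(pts)
  if (m < 2) return(list(seq_len(m)))
  ld_max <- max(ld)
  d <- as.matrix(stats::dist(pts))
  half_sep <- params$peak_min_separation / 2
  is_peak <- vapply(seq_len(m), function(i) {
    ld[i] == max(ld[d[i, ] <= half_sep])
  }, logical(1))
  cand <- which(is_peak & ld > params$peak_fraction * ld_max)
  cand <- cand[order(ld[cand], decreasing = TRUE)]
  if (length(cand) < 2) return(list(seq_len(m)))
  retained <- cand[1]
  for (p in cand[-1]) {
    separate <- vapply(retained, function(q) {
      d[p, q] > params$peak_min_separation &&
        .corridor_min_ld(pts, ld, p, q, params$corridor_width) <
          params$valley_fraction * ld_max
    }, logical(1))
    if (all(separate)) retained <- c(retained, p)
  }
  if (length(retained) < 2) return(list(seq_len(m)))
  assign <- apply(d[, retained, drop = FALSE], 1, which.min)
  unname(split(seq_len(m), assign))
}

# Minimum LD among members strictly inside the corridor between peaks p and q
# (projection strictly between the peaks, perpendicular offset <= width/2).
# Inf when the corridor holds no member.
.corridor_min_ld <- function(pts, ld, p, q, width) {
  a <- pts[p, ]; b <- pts[q, ]
  ab <- b - a
  L2 <- sum(ab^2)
  t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / L2
  perp <- abs((pts[, 1] - a[1]) * (-ab[2]) + (pts[, 2] - a[2]) * ab[1]) / sqrt(L2)
  sel <- t > 0 & t < 1 & perp <= width / 2
  sel[c(p, q)] <- FALSE
  if (!any(sel)) return(Inf)
  min(ld[sel])
}

#' PSD center and area from the PSD95 cluster
#'
#' The PSD95 localizations of a synapse are clustered with DBSCAN; the
#' largest cluster is the PSD. Its center is the arithmetic centroid of the
#' member localizations and its area the convex hull of the members.
#'
#' @param psd95_points PSD95 localizations of one synapse.
#' @param eps DBSCAN radius (nm); default 5 x MNND of the points.
#' @param min_pts DBSCAN core threshold (default 5).
#' @return list with `center` (nm), `psd_area` (um^2), `members` (indices),
#'   and `hull` (polygon, nm).
#' @export
psd_centroid <- function(psd95_points, eps = NULL, min_pts = 5) {
  pts <- as_points(psd95_points)
  if (nrow(pts) < min_pts) stop("no PSD cluster: fewer points than min_pts")
  if (is.null(eps)) eps <- 5 * mnnd(pts)
  labels <- dbscan_labels(pts, eps, min_pts)
  if (all(labels == 0L)) stop("no PSD cluster found by DBSCAN")
  sizes <- tabulate(labels)
  biggest <- which.max(sizes)
  members <- which(labels == biggest)
  hull <- convex_hull_poly(pts[members, , drop = FALSE])
  list(center = colMeans(pts[members, , drop = FALSE]),
       psd_area = polygon_area(hull) / 1e6,
       members = members, hull = hull)
}

#' Nanodomain topology metrics
#'
#' Per nanodomain: Euclidean distance from its center to the PSD center, and
#' center-to-center distance to the closest nanodomain of the other channel
#' (missing, with a flag, when the other channel has none).
#'
#' @param nd_a,nd_b lists of `nanodomain` objects for the two channels.
#' @param psd_center PSD center (nm), from [psd_centroid()].
#' @param channels labels for the two channels (default `c("A", "B")`).
#' @return data.frame with one row per nanodomain: channel, nanodomain id,
#'   center coordinates, diameter, member_fraction, `dist_psd_center`,
#'   `dist_other_channel`, `other_channel_missing`.
#' @export
topology_metrics <- function(nd_a, nd_b, psd_center,
                             channels = c("A", "B")) {
  one <- function(nds, other, ch) {
    if (length(nds) == 0) return(NULL)
    centers <- t(vapply(nds, function(d) d$center, numeric(2)))
    other_centers <- if (length(other) > 0) {
      t(vapply(other, function(d) d$center, numeric(2)))
    } else NULL
    cross <- if (is.null(other_centers)) rep(NA_real_, length(nds)) else {
      apply(centers, 1, function(cc) {
        min(sqrt((other_centers[, 1] - cc[1])^2 +
                 (other_centers[, 2] - cc[2])^2))
      })
    }
    data.frame(
      channel = ch, nanodomain = seq_along(nds),
      center_x = centers[, 1], center_y = centers[, 2],
      diameter = vapply(nds, function(d) d$diameter, 0),
      member_fraction = vapply(nds, function(d) d$member_fraction, 0),
      dist_psd_center = sqrt((centers[, 1] - psd_center[1])^2 +
                             (centers[, 2] - psd_center[2])^2),
      dist_other_channel = cross,
      other_channel_missing = is.null(other_centers),
      stringsAsFactors = FALSE)
  }
  out <- rbind(one(nd_a, nd_b, channels[1]), one(nd_b, nd_a, channels[2]))
  if (is.null(out)) {
    out <- data.frame(channel = character(0), nanodomain = integer(0),
                      center_x = numeric(0), center_y = numeric(0),
                      diameter = numeric(0), member_fraction = numeric(0),
                      dist_psd_center = numeric(0),
                      dist_other_channel = numeric(0),
                      other_channel_missing = logical(0))
  }
  out
}

#' Membership of points in a set of nanodomains
#'
#' A point lies inside the Voronoi-cell union of a nanodomain iff it falls
#' within the clip polygon and its nearest site among all the nanodomain
#' channel's localizations is a member of that nanodomain (exact, no polygon
#' chaining involved).
#'
#' @param px,py query coordinates (nm).
#' @param nds list of `nanodomain` objects of one channel.
#' @param channel_points all localizations of that channel in the synapse
#'   (the site set the Voronoi diagram was built from).
#' @param roi the clip polygon used at detection time.
#' @return logical vector: inside any of the nanodomains.
#' @export
in_nanodomain <- function(px, py, nds, channel_points, roi) {
  if (length(nds) == 0 || length(px) == 0) return(rep(FALSE, length(px)))
  pts <- as_points(channel_points)
  members <- sort(unique(unlist(lapply(nds, function(d) d$members))))
  inside_clip <- point_in_polygon(px, py, roi)
  nearest <- vapply(seq_along(px), function(i) {
    which.min((pts[, 1] - px[i])^2 + (pts[, 2] - py[i])^2)
  }, integer(1))
  inside_clip & nearest %in% members
}
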