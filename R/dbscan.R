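# Density-based spatial clustering (DBSCAN) over 2-D point sets, used to
# identify the PSD95 cluster that defines the PSD center and size. A point is
# a core point when at least `min_pts` points (itself included) lie within
# `eps`; clusters grow from core points through density-reachability. Border
# points join the first cluster that reaches them; noise is labeled 0.
# Deterministic: points are visited in index order.

#' DBSCAN clustering of a 2-D point set
#'
#' @param pts n x 2 matrix of coordinates (nm).
#' @param eps neighborhood radius (nm).
#' @param min_pts minimum number of points (including the point itself)
#'   within `eps` for a core point.
#' @return integer vector of cluster labels (0 = noise).
#' @export
dbscan_labels <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  stopifnot(eps > 0, min_pts >= 1)
  if (n == 0) return(integer(0))
  nb <- radius_neighbors(pts, eps)  # self included
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue) > 0) {
      j <- queue[1]
      queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
      }
    }
  }
  labels
}
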