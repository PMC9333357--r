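# Synapse ROI segmentation from a widefield reference image (FWHM regions
# around intensity peaks), point-in-polygon assignment of localizations, and
# the synapse inclusion criteria (per-channel minimum localization counts and
# a PSD-area window).

#' Segment synapse ROIs from a widefield image at the full-width half maximum
#'
#' The image is Gaussian-smoothed, the background is estimated as the median
#' of the smoothed image, and each local intensity maximum higher than
#' `background + min_peak_height` seeds one ROI: the connected region around
#' the peak where intensity >= background + (peak - background)/2, extracted
#' as a marching-squares contour polygon in nm. Peaks falling inside an
#' already-claimed ROI are skipped.
#'
#' @param image a [widefield_image()].
#' @param smoothing Gaussian smoothing sigma in nm; default one camera pixel.
#'   Use 0 for no smoothing.
#' @param min_peak_height minimum peak elevation above background (intensity
#'   units); default 3x the median absolute deviation of the smoothed image.
#' @return list of `synapse_roi` objects (id, boundary polygon in nm, area in
#'   um^2, peak position in nm); empty list when no peak qualifies.
#' @export
segment_widefield <- function(image, smoothing = NULL, min_peak_height = NULL) {
  p <- pixel_size(image)
  if (is.null(smoothing)) smoothing <- p
  stopifnot(smoothing >= 0)
  m <- unclass(image)
  attr(m, "pixel_size") <- NULL
  sm <- if (smoothing > 0) {
    EBImage::imageData(EBImage::gblur(m, sigma = smoothing / p))
  } else m
  bg <- stats::median(sm)
  if (is.null(min_peak_height)) min_peak_height <- 3 * stats::mad(sm)
  peaks <- .local_maxima(sm)
  keep <- sm[peaks] > bg + min_peak_height & sm[peaks] > bg
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) == 0) {
    warning("no intensity peak above background + min_peak_height; no ROIs")
    return(list())
  }
  peaks <- peaks[order(sm[peaks], decreasing = TRUE), , drop = FALSE]
  # pad with background so half-max contours close at the image edge
  ny <- nrow(sm); nx <- ncol(sm)
  zp <- matrix(bg, ny + 2, nx + 2)
  zp[2:(ny + 1), 2:(nx + 1)] <- sm
  xc <- (seq_len(nx + 2) - 1.5) * p  # pixel centers incl. pad, nm
  yc <- (seq_len(ny + 2) - 1.5) * p
  rois <- list()
  for (k in seq_len(nrow(peaks))) {
    iy <- peaks[k, 1]; ix <- peaks[k, 2]
    px_nm <- (ix - 0.5) * p; py_nm <- (iy - 0.5) * p
    claimed <- any(vapply(rois, function(r) {
      point_in_polygon(px_nm, py_nm, r$boundary)
    }, logical(1)))
    if (claimed) next
    level <- bg + (sm[iy, ix] - bg) / 2
    cl <- grDevices::contourLines(x = xc, y = yc, z = t(zp), levels = level)
    poly <- NULL
    for (cc in cl) {
      cand <- cbind(cc$x, cc$y)
      if (point_in_polygon(px_nm, py_nm, cand)) { poly <- cand; break }
    }
    if (is.null(poly)) next
    rois[[length(rois) + 1L]] <- structure(
      list(id = length(rois) + 1L, boundary = poly,
           area = polygon_area(poly) / 1e6, peak = c(px_nm, py_nm),
           peak_intensity = sm[iy, ix], half_max_level = level),
      class = "synapse_roi")
  }
  rois
}

# row/col indices of strict-in-neighborhood local maxima of a matrix
.local_maxima <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  if (ny < 3 || nx < 3) return(cbind(integer(0), integer(0)))
  core <- m[2:(ny - 1), 2:(nx - 1)]
  is_max <- matrix(TRUE, ny - 2, nx - 2)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- m[(2 + dy):(ny - 1 + dy), (2 + dx):(nx - 1 + dx)]
    is_max <- is_max & (core >= nb)
  }
  # strictly above at least one neighbor (excludes flat plateaus)
  any_less <- matrix(FALSE, ny - 2, nx - 2)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- m[(2 + dy):(ny - 1 + dy), (2 + dx):(nx - 1 + dx)]
    any_less <- any_less | (core > nb)
  }
  w <- which(is_max & any_less, arr.ind = TRUE)
  cbind(w[, 1] + 1L, w[, 2] + 1L)
}

#' @export
print.synapse_roi <- function(x, ...) {
  cat(sprintf("<synapse_roi #%d> area %.4f um^2, peak (%.0f, %.0f) nm, %d vertices\n",
              x$id, x$area, x$peak[1], x$peak[2], nrow(x$boundary)))
  invisible(x)
}

#' Assign localizations to synapse ROIs
#'
#' Point-in-polygon assignment (boundary points belong to the ROI).
#' Localizations inside no ROI are dropped from synapse analysis; a
#' localization inside several overlapping ROIs goes to the ROI with the
#' nearest peak, and the overlap count is recorded.
#'
#' @param table a [loc_table()] in the same nm coordinate frame as the ROIs.
#' @param rois list of `synapse_roi` from [segment_widefield()].
#' @return list of `synapse_record` objects: `roi`, `locs` (a [loc_table()]
#'   of members), per-channel counts, and `psd_area`/`psd_center` slots
#'   (filled later by [psd_centroid()]). The list carries attributes
#'   `n_unassigned` and `n_overlap`.
#' @export
assign_localizations <- function(table, rois) {
  n <- nrow(table)
  assignment <- rep(NA_integer_, n)
  best_d2 <- rep(Inf, n)
  n_overlap <- 0L
  for (r in rois) {
    inside <- point_in_polygon(table$x, table$y, r$boundary)
    d2 <- (table$x - r$peak[1])^2 + (table$y - r$peak[2])^2
    n_overlap <- n_overlap + sum(inside & !is.na(assignment))
    take <- inside & (is.na(assignment) | d2 < best_d2)
    assignment[take] <- r$id
    best_d2[take] <- d2[take]
  }
  chans <- unique(table$channel)
  records <- lapply(rois, function(r) {
    members <- subset_loc_table(table, which(assignment == r$id))
    structure(list(roi = r, locs = members,
                   counts = base::table(factor(members$channel,
                                               levels = chans)),
                   psd_area = NA_real_, psd_center = c(NA_real_, NA_real_)),
              class = "synapse_record")
  })
  attr(records, "n_unassigned") <- sum(is.na(assignment))
  attr(records, "n_overlap") <- n_overlap
  records
}

#' @export
print.synapse_record <- function(x, ...) {
  cnt <- paste(sprintf("%s=%d", names(x$counts), as.integer(x$counts)),
               collapse = ", ")
  cat(sprintf("<synapse_record> ROI #%d, %d locs (%s), psd_area %.4f um^2\n",
              x$roi$id, nrow(x$locs), cnt, x$psd_area))
  invisible(x)
}

#' Synapse inclusion criteria
#'
#' Defaults follow the standard analysis gate for this preparation: more than
#' 800 PSD95 and more than 400 GluA1 localizations, and a PSD area strictly
#' between 0.02 and 0.3 um^2.
#'
#' @param min_locs named integer vector; a synapse is retained only if each
#'   named channel's count strictly exceeds its entry.
#' @param area_min,area_max PSD-area window in um^2 (strict inequalities).
#' @export
inclusion_criteria <- function(min_locs = c(PSD95 = 800, GluA1 = 400),
                               area_min = 0.02, area_max = 0.3) {
  stopifnot(area_min < area_max)
  structure(list(min_locs = min_locs, area_min = area_min,
                 area_max = area_max),
            class = "inclusion_criteria")
}

#' Select synapses for further analysis
#'
#' Retained iff every per-channel localization count strictly exceeds its
#' minimum and `area_min < area < area_max`. The area used is `psd_area`
#' (the PSD95-cluster area from [psd_centroid()]); records without one fall
#' back to the ROI area, with a message.
#'
#' @param records list of `synapse_record`.
#' @param criteria an [inclusion_criteria()].
#' @return the retained sublist; attribute `n_rejected` counts removals.
#' @export
select_synapses <- function(records, criteria = inclusion_criteria()) {
  used_fallback <- FALSE
  keep <- vapply(records, function(rec) {
    area <- rec$psd_area
    if (is.na(area)) { used_fallback <<- TRUE; area <- rec$roi$area }
    counts_ok <- all(vapply(names(criteria$min_locs), function(ch) {
      n_ch <- sum(rec$locs$channel == ch)
      n_ch > criteria$min_locs[[ch]]
    }, logical(1)))
    counts_ok && area > criteria$area_min && area < criteria$area_max
  }, logical(1))
  if (used_fallback) message("psd_area missing for some synapses; ROI area used")
  out <- records[keep]
  attr(out, "n_rejected") <- sum(!keep)
  out
}
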