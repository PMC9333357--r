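# FRAP trace processing: background and bleaching correction, two-point
# normalization (pre-bleach mean -> 1, first post-bleach frame -> 0), mobile
# fraction as the mean of the last frames, and synapse/shaft enrichment.

#' Construct a FRAP trace
#'
#' @param times acquisition times (min), strictly increasing; the
#'   conventional protocol images every 5 min.
#' @param roi mean ROI intensities (a.u.).
#' @param background background intensities (a.u.), recycled if length 1.
#' @param reference bleach-reference intensities (an unbleached region,
#'   a.u.), recycled if length 1.
#' @param bleach_index index of the first post-bleach frame (>= 2 so that at
#'   least one pre-bleach frame exists).
#' @param stage one of `"raw"`, `"corrected"`, `"normalized"`.
#' @param roi_id,cell_id identifiers carried to summaries.
#' @return data.frame of class `frap_trace` with attributes `bleach_index`,
#'   `stage`, `roi_id`, `cell_id`.
#' @export
frap_trace <- function(times, roi, background = 0, reference = 1,
                       bleach_index, stage = "raw", roi_id = "roi1",
                       cell_id = "cell1") {
  n <- length(times)
  stopifnot(n >= 2, all(diff(times) > 0), length(roi) == n)
  if (length(background) == 1) background <- rep(background, n)
  if (length(reference) == 1) reference <- rep(reference, n)
  stopifnot(length(background) == n, length(reference) == n)
  bleach_index <- as.integer(bleach_index)
  if (bleach_index < 2 || bleach_index > n) {
    stop("bleach_index must leave >= 1 pre-bleach frame and be in range")
  }
  stage <- match.arg(stage, c("raw", "corrected", "normalized"))
  out <- data.frame(time = times, roi = roi, background = background,
                    reference = reference)
  structure(out, bleach_index = bleach_index, stage = stage,
            roi_id = roi_id, cell_id = cell_id,
            class = c("frap_trace", "data.frame"))
}

frap_attrs <- function(trace) {
  attributes(trace)[c("bleach_index", "stage", "roi_id", "cell_id")]
}

#' @export
print.frap_trace <- function(x, ...) {
  at <- frap_attrs(x)
  cat(sprintf("<frap_trace %s/%s> %d frames, bleach at frame %d, stage: %s\n",
              at$cell_id, at$roi_id, nrow(x), at$bleach_index, at$stage))
  invisible(x)
}

#' Background and bleaching correction of a FRAP trace
#'
#' `corrected(t) = (roi(t) - background(t)) * refPre / (ref(t) -
#' background(t))`, where `refPre` is the pre-bleach mean of the
#' background-subtracted bleach reference (ratio bleaching correction against
#' an unbleached region).
#'
#' @param trace a raw [frap_trace()] with background and reference columns.
#' @return the trace at stage `"corrected"`.
#' @export
correct_trace <- function(trace) {
  at <- frap_attrs(trace)
  if (at$stage != "raw") stop("correct_trace expects a raw trace")
  ref_net <- trace$reference - trace$background
  if (any(ref_net <= 0)) {
    stop("correction error: bleach reference <= background at frame(s) ",
         paste(which(ref_net <= 0), collapse = ", "))
  }
  pre <- seq_len(at$bleach_index - 1)
  ref_pre <- mean(ref_net[pre])
  corrected <- (trace$roi - trace$background) * ref_pre / ref_net
  frap_trace(trace$time, corrected, background = 0, reference = 1,
             bleach_index = at$bleach_index, stage = "corrected",
             roi_id = at$roi_id, cell_id = at$cell_id)
}

#' Two-point normalization of a corrected FRAP trace
#'
#' `norm(t) = (corrected(t) - F0) / (Fpre - F0)` with `Fpre` the mean of the
#' pre-bleach frames and `F0` the corrected intensity of the first
#' post-bleach frame, so the pre-bleach mean is 1 and the first post-bleach
#' frame 0.
#'
#' @param trace a corrected [frap_trace()].
#' @return the trace at stage `"normalized"`.
#' @export
normalize_trace <- function(trace) {
  at <- frap_attrs(trace)
  if (at$stage != "corrected") stop("normalize_trace expects a corrected trace")
  pre <- seq_len(at$bleach_index - 1)
  f_pre <- mean(trace$roi[pre])
  f0 <- trace$roi[at$bleach_index]
  if (f_pre == f0) stop("normalization error: no bleach depth (Fpre == F0)")
  frap_trace(trace$time, (trace$roi - f0) / (f_pre - f0),
             background = 0, reference = 1, bleach_index = at$bleach_index,
             stage = "normalized", roi_id = at$roi_id, cell_id = at$cell_id)
}

#' Mobile fraction of a normalized FRAP trace
#'
#' Arithmetic mean of the final `n_last` normalized intensities (default 4).
#'
#' @param trace a normalized [frap_trace()].
#' @param n_last number of trailing frames to average.
#' @return the mobile fraction (dimensionless).
#' @export
mobile_fraction <- function(trace, n_last = 4) {
  at <- frap_attrs(trace)
  if (at$stage != "normalized") stop("mobile_fraction expects a normalized trace")
  n_post <- nrow(trace) - at$bleach_index + 1L
  if (n_post < n_last) {
    stop(sprintf("fewer post-bleach frames (%d) than n_last (%d)",
                 n_post, n_last))
  }
  mean(utils::tail(trace$roi, n_last))
}

#' Process raw FRAP traces to per-ROI and per-cell mobile fractions
#'
#' Runs correct -> normalize -> mobile fraction on each trace and averages
#' per cell.
#'
#' @param traces list of raw [frap_trace()] objects.
#' @param n_last trailing frames averaged for the mobile fraction.
#' @return list with `per_roi` (data.frame: cell_id, roi_id,
#'   mobile_fraction) and `per_cell` (data.frame: cell_id, mean
#'   mobile_fraction, n_rois).
#' @export
frap_summary <- function(traces, n_last = 4) {
  per_roi <- do.call(rbind, lapply(traces, function(tr) {
    at <- frap_attrs(tr)
    mf <- mobile_fraction(normalize_trace(correct_trace(tr)), n_last)
    data.frame(cell_id = at$cell_id, roi_id = at$roi_id,
               mobile_fraction = mf, stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(mobile_fraction ~ cell_id, per_roi, mean)
  n <- stats::aggregate(mobile_fraction ~ cell_id, per_roi, length)
  per_cell <- data.frame(cell_id = agg$cell_id,
                         mobile_fraction = agg$mobile_fraction,
                         n_rois = n$mobile_fraction,
                         stringsAsFactors = FALSE)
  list(per_roi = per_roi, per_cell = per_cell)
}

#' Read FRAP traces from a long-format CSV
#'
#' Expected columns: `roi_id, t_min, roi_mean, bg_mean, ref_mean,
#' bleach_index` and optionally `cell_id`.
#'
#' @param path CSV path.
#' @return list of raw [frap_trace()] objects.
#' @export
read_frap_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "t_min", "roi_mean", "bg_mean", "ref_mean",
            "bleach_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("format error: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"cell_id" %in% names(df)) df$cell_id <- "cell1"
  lapply(split(df, list(df$cell_id, df$roi_id), drop = TRUE), function(g) {
    g <- g[order(g$t_min), ]
    frap_trace(g$t_min, g$roi_mean, g$bg_mean, g$ref_mean,
               bleach_index = g$bleach_index[1], stage = "raw",
               roi_id = g$roi_id[1], cell_id = g$cell_id[1])
  })
}

#' Write FRAP traces to a long-format CSV
#' @param traces list of [frap_trace()] objects.
#' @param path output CSV path.
#' @export
write_frap_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    at <- frap_attrs(tr)
    data.frame(cell_id = at$cell_id, roi_id = at$roi_id, t_min = tr$time,
               roi_mean = tr$roi, bg_mean = tr$background,
               ref_mean = tr$reference, bleach_index = at$bleach_index,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Synaptic enrichment from disc ROIs on an image
#'
#' Ratio of the mean background-subtracted intensity over synapse disc ROIs
#' to that over dendritic-shaft disc ROIs (default ten 250-nm-diameter discs
#' per compartment).
#'
#' @param image a [widefield_image()].
#' @param synapse_centers,shaft_centers k x 2 matrices of disc centers (nm).
#' @param diameter disc diameter in nm (default 250).
#' @param background intensity subtracted from each ROI mean (default 0).
#' @return list with `ratio`, `synapse_mean`, `shaft_mean`.
#' @export
synaptic_enrichment <- function(image, synapse_centers, shaft_centers,
                                diameter = 250, background = 0) {
  p <- pixel_size(image)
  disc_mean <- function(cc) {
    # pixels whose centers fall inside the disc
    r <- diameter / 2
    ix <- which(abs((seq_len(ncol(image)) - 0.5) * p - cc[1]) <= r)
    iy <- which(abs((seq_len(nrow(image)) - 0.5) * p - cc[2]) <= r)
    if (length(ix) == 0 || length(iy) == 0) {
      # disc smaller than a pixel: use the containing pixel
      ix <- min(max(ceiling(cc[1] / p), 1), ncol(image))
      iy <- min(max(ceiling(cc[2] / p), 1), nrow(image))
      return(image[iy, ix])
    }
    sub <- image[iy, ix, drop = FALSE]
    xx <- outer(rep(1, length(iy)), (ix - 0.5) * p)
    yy <- outer((iy - 0.5) * p, rep(1, length(ix)))
    sel <- (xx - cc[1])^2 + (yy - cc[2])^2 <= r^2
    if (!any(sel)) return(sub[which.min((xx - cc[1])^2 + (yy - cc[2])^2)])
    mean(sub[sel])
  }
  syn <- apply(as_points(synapse_centers), 1, disc_mean) - background
  sha <- apply(as_points(shaft_centers), 1, disc_mean) - background
  shaft_mean <- mean(sha)
  if (shaft_mean <= 0) stop("shaft mean <= 0 after background subtraction")
  list(ratio = mean(syn) / shaft_mean, synapse_mean = mean(syn),
       shaft_mean = shaft_mean)
}
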