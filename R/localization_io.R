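# Localization table IO: delimited single-molecule localization tables
# (one row per fitted emitter position), widefield reference images (TIFF),
# and 2-D histogram reconstruction rendering.

CANONICAL_COLUMNS <- c(x = "x_nm", y = "y_nm", frame = "frame",
                       photons = "photons", precision = "precision_nm",
                       channel = "channel")

#' Column-name dialect for localization tables
#'
#' Maps the five required semantic columns (plus the optional channel column)
#' onto the column names found in a file. Presets are shipped for the
#' canonical schema and for ThunderSTORM-like and DoM-like exports; any
#' explicit argument overrides the preset.
#'
#' @param preset one of `"canonical"`, `"thunderstorm"`, `"dom"`.
#' @param x,y,frame,photons,precision,channel file column names (characters)
#'   overriding the preset. `channel` may be `NA` when the file has none.
#' @return named character vector of class `loc_dialect`.
#' @export
#' @examples
#' loc_dialect("thunderstorm")
#' loc_dialect(x = "X", y = "Y")  # canonical otherwise
loc_dialect <- function(preset = "canonical", x = NULL, y = NULL,
                        frame = NULL, photons = NULL, precision = NULL,
                        channel = NULL) {
  presets <- list(
    canonical = CANONICAL_COLUMNS,
    thunderstorm = c(x = "x [nm]", y = "y [nm]", frame = "frame",
                     photons = "intensity [photon]",
                     precision = "uncertainty [nm]", channel = "channel"),
    dom = c(x = "X_(nm)", y = "Y_(nm)", frame = "Frame_Number",
            photons = "IntegratedInt_(photons)",
            precision = "X_loc_error_(nm)", channel = "channel")
  )
  if (!preset %in% names(presets)) {
    stop("unknown dialect preset: ", preset)
  }
  d <- presets[[preset]]
  for (f in c("x", "y", "frame", "photons", "precision", "channel")) {
    v <- get(f)
    if (!is.null(v)) d[[f]] <- v
  }
  structure(d, class = "loc_dialect")
}

#' Construct a localization table
#'
#' The central container: one row per localization with coordinates in nm
#' (origin at the image top-left, y increasing downward), acquisition frame
#' index, photon count, localization precision (nm) and channel label.
#'
#' @param x,y coordinates (nm), finite.
#' @param frame integer frame indices (>= 0).
#' @param photons photon counts (> 0).
#' @param precision localization precision (nm, > 0).
#' @param channel channel labels (recycled).
#' @param n_frames declared acquisition length in frames (default 20000).
#' @param frame_rate acquisition frame rate in Hz (default 50).
#' @param extra data.frame of additional columns carried along (optional).
#' @return data.frame of class `loc_table`.
#' @export
loc_table <- function(x = numeric(0), y = numeric(0), frame = integer(0),
                      photons = numeric(0), precision = numeric(0),
                      channel = character(0), n_frames = 20000L,
                      frame_rate = 50, extra = NULL) {
  n <- length(x)
  if (n > 0 && length(channel) %in% c(0L, 1L)) {
    channel <- rep(if (length(channel)) channel else "ch1", n)
  }
  tab <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    frame = as.integer(frame),
                    photons = as.numeric(photons),
                    precision = as.numeric(precision),
                    channel = as.character(channel),
                    stringsAsFactors = FALSE)
  if (!is.null(extra) && nrow(tab) == nrow(extra)) tab <- cbind(tab, extra)
  validate_loc_table(tab, n_frames)
  attr(tab, "n_frames") <- as.integer(n_frames)
  attr(tab, "frame_rate") <- frame_rate
  class(tab) <- c("loc_table", "data.frame")
  tab
}

validate_loc_table <- function(tab, n_frames = attr(tab, "n_frames")) {
  if (nrow(tab) == 0) return(invisible(TRUE))
  if (!all(is.finite(tab$x)) || !all(is.finite(tab$y))) {
    stop("localization coordinates must be finite")
  }
  if (any(tab$photons <= 0)) stop("photon counts must be strictly positive")
  if (any(tab$precision <= 0)) stop("precision must be strictly positive")
  if (any(tab$frame < 0)) stop("frame indices must be >= 0")
  if (!is.null(n_frames) && any(tab$frame >= n_frames)) {
    stop("frame indices exceed the declared acquisition length")
  }
  invisible(TRUE)
}

#' @export
print.loc_table <- function(x, ...) {
  cat(sprintf("<loc_table> %d localizations, %d channel(s): %s\n",
              nrow(x), length(unique(x$channel)),
              paste(unique(x$channel), collapse = ", ")))
  cat(sprintf("  acquisition: %s frames @ %s Hz\n",
              attr(x, "n_frames"), attr(x, "frame_rate")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 5), ...)
  invisible(x)
}

#' Read a localization table from delimited text
#'
#' @param path file path to a delimited text file with a header row.
#' @param dialect a [loc_dialect()] mapping semantic columns to file columns.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab.
#' @param channel channel label to assign when the file has no channel
#'   column (default `"ch1"`).
#' @param n_frames,frame_rate acquisition metadata attached to the table.
#' @return a [loc_table()] with one record per file row, in file order.
#'   Unmapped file columns are preserved as extra columns.
#' @export
read_localizations <- function(path, dialect = loc_dialect(), sep = NULL,
                               channel = "ch1", n_frames = 20000L,
                               frame_rate = 50) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("x", "y", "frame", "photons", "precision")
  for (f in required) {
    if (!dialect[[f]] %in% names(raw)) {
      stop(sprintf("format error: required column '%s' (mapped to '%s') not found",
                   f, dialect[[f]]))
    }
  }
  num <- function(f) {
    v <- raw[[dialect[[f]]]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("parse error: non-numeric value in column '%s' at row %d",
                   dialect[[f]], bad[1]))
    }
    out
  }
  ch <- if (!is.na(dialect[["channel"]]) && dialect[["channel"]] %in% names(raw)) {
    as.character(raw[[dialect[["channel"]]]])
  } else rep(channel, nrow(raw))
  mapped <- unname(dialect[required])
  extra_cols <- setdiff(names(raw), c(mapped, dialect[["channel"]]))
  loc_table(x = num("x"), y = num("y"), frame = as.integer(num("frame")),
            photons = num("photons"), precision = num("precision"),
            channel = ch, n_frames = n_frames, frame_rate = frame_rate,
            extra = if (length(extra_cols)) raw[extra_cols] else NULL)
}

#' Write a localization table as delimited text
#'
#' Writes the canonical header (`x_nm, y_nm, frame, photons, precision_nm,
#' channel`) with enough numeric digits for a bit-stable round trip at
#' 0.01 nm.
#'
#' @param table a [loc_table()].
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, sep = ",") {
  out <- data.frame(
    x_nm = sprintf("%.10g", table$x),
    y_nm = sprintf("%.10g", table$y),
    frame = table$frame,
    photons = sprintf("%.10g", table$photons),
    precision_nm = sprintf("%.10g", table$precision),
    channel = table$channel,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  if (nrow(table) == 0) {
    out <- out[0, , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Construct a widefield image
#'
#' @param data numeric matrix of pixel intensities; rows are y (downward),
#'   columns are x.
#' @param pixel_size pixel edge length in nm (> 0).
#' @return matrix of class `widefield_image` with a `pixel_size` attribute.
#' @export
widefield_image <- function(data, pixel_size) {
  stopifnot(is.matrix(data), nrow(data) > 0, ncol(data) > 0, pixel_size > 0)
  structure(data, pixel_size = pixel_size,
            class = c("widefield_image", class(data)))
}

#' @export
print.widefield_image <- function(x, ...) {
  cat(sprintf("<widefield_image> %d x %d px, %.3g nm/px, range [%.4g, %.4g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size"), min(x), max(x)))
  invisible(x)
}

#' Pixel size of a widefield image (nm)
#' @param image a `widefield_image`.
#' @export
pixel_size <- function(image) attr(image, "pixel_size")

#' Read a single-plane TIFF as a widefield image
#'
#' @param path TIFF file path.
#' @param pixel_size pixel size in nm (TIFFs rarely carry it reliably).
#' @export
read_widefield <- function(path, pixel_size) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  widefield_image(img, pixel_size)
}

#' Write a widefield image to TIFF
#'
#' Intensities are rescaled to the unit interval (the TIFF writer's domain);
#' absolute scale is not preserved.
#' @param image a `widefield_image`.
#' @param path output path.
#' @export
write_widefield <- function(image, path) {
  m <- unclass(image)
  attr(m, "pixel_size") <- NULL
  mx <- max(m)
  if (mx > 0) m <- m / mx
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' Render a 2-D histogram reconstruction
#'
#' Bins localizations into square pixels of side `pix` nm with half-open bins
#' `[k*pix, (k+1)*pix)`: the localization at (x, y) increments pixel
#' `(floor(x/pix), floor(y/pix))` (zero-based). The pixel sum equals the
#' number of localizations.
#'
#' @param table a [loc_table()].
#' @param pix reconstruction pixel size in nm (default 12, the conventional
#'   rendering scale for dSTORM data of this kind).
#' @param width_nm,height_nm optional extent; defaults grow to fit the data.
#' @return a [widefield_image()] of counts.
#' @export
render_reconstruction <- function(table, pix = 12, width_nm = NULL,
                                  height_nm = NULL) {
  stopifnot(pix > 0)
  if (nrow(table) > 0 && (any(table$x < 0) || any(table$y < 0))) {
    stop("render_reconstruction expects non-negative coordinates")
  }
  nx <- if (!is.null(width_nm)) ceiling(width_nm / pix) else
    if (nrow(table) == 0) 1L else floor(max(table$x) / pix) + 1L
  ny <- if (!is.null(height_nm)) ceiling(height_nm / pix) else
    if (nrow(table) == 0) 1L else floor(max(table$y) / pix) + 1L
  img <- matrix(0, nrow = ny, ncol = nx)
  if (nrow(table) > 0) {
    ix <- pmin(floor(table$x / pix), nx - 1L) + 1L
    iy <- pmin(floor(table$y / pix), ny - 1L) + 1L
    img[] <- tabulate(iy + (ix - 1L) * ny, nbins = nx * ny)
  }
  widefield_image(img, pix)
}
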