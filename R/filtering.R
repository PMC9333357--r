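# Localization quality filters and consecutive-localization (blinking)
# removal. All inequalities are strict, mirroring the acquisition protocol's
# wording: a localization is removed when precision exceeds the per-channel
# maximum, or the photon count falls below the minimum or above the maximum;
# repeated (consecutive-frame) localizations within the chaining radius are
# removed, and a chain persisting for more than `repeat_max_frames` frames
# loses its initial localization too.

#' Quality thresholds for localization filtering
#'
#' Defaults are the standard operating point for dual-color dSTORM of
#' GluA1/PSD95: precision <= 30 nm (GluA1) / 25 nm (PSD95), photon count in
#' (300, 30000) boundary-inclusive, 60 nm chaining radius, chains longer than
#' 10 frames lose their seed.
#'
#' @param precision_max named numeric vector, nm per channel.
#' @param photons_min,photons_max photon-count window (removal is strict:
#'   counts `< photons_min` or `> photons_max` are removed).
#' @param repeat_radius chaining radius in nm for consecutive localizations.
#' @param repeat_max_frames chains persisting more than this many frames lose
#'   their initial localization as well.
#' @param frame_gap maximum frame difference for "consecutive" (default 1).
#' @return list of class `quality_thresholds`.
#' @export
quality_thresholds <- function(precision_max = c(GluA1 = 30, PSD95 = 25),
                               photons_min = 300, photons_max = 30000,
                               repeat_radius = 60, repeat_max_frames = 10,
                               frame_gap = 1) {
  stopifnot(all(precision_max > 0), photons_min > 0,
            photons_min < photons_max, repeat_radius > 0,
            repeat_max_frames >= 1, frame_gap >= 1)
  structure(list(precision_max = precision_max, photons_min = photons_min,
                 photons_max = photons_max, repeat_radius = repeat_radius,
                 repeat_max_frames = repeat_max_frames, frame_gap = frame_gap),
            class = "quality_thresholds")
}

filter_report <- function(n_in, removed_precision = 0L, removed_photons = 0L,
                          removed_repeat = 0L) {
  n_out <- n_in - removed_precision - removed_photons - removed_repeat
  structure(list(n_in = as.integer(n_in),
                 removed_precision = as.integer(removed_precision),
                 removed_photons = as.integer(removed_photons),
                 removed_repeat = as.integer(removed_repeat),
                 n_out = as.integer(n_out)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("<filter_report> in %d -> out %d (precision -%d, ",
                     "photons -%d, repeats -%d)\n"),
              x$n_in, x$n_out, x$removed_precision, x$removed_photons,
              x$removed_repeat))
  invisible(x)
}

#' Apply precision and photon-count quality filters
#'
#' A record is retained iff `precision <= precision_max[channel]` and
#' `photons_min <= photons <= photons_max` (removal only on strict violation
#' of the thresholds). Record order is preserved. Records failing both tests
#' are tallied under precision.
#'
#' @param table a [loc_table()].
#' @param thresholds a [quality_thresholds()].
#' @return list with elements `table` (filtered [loc_table()]) and `report`
#'   (a `filter_report`).
#' @export
apply_quality_filter <- function(table, thresholds = quality_thresholds()) {
  chans <- unique(table$channel)
  missing <- setdiff(chans, names(thresholds$precision_max))
  if (length(missing) > 0) {
    stop("configuration error: no precision_max for channel(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(table) == 0) {
    return(list(table = table, report = filter_report(0L)))
  }
  pmax_per_rec <- unname(thresholds$precision_max[table$channel])
  bad_prec <- table$precision > pmax_per_rec
  bad_phot <- table$photons < thresholds$photons_min |
              table$photons > thresholds$photons_max
  keep <- !(bad_prec | bad_phot)
  rep <- filter_report(nrow(table),
                       removed_precision = sum(bad_prec),
                       removed_photons = sum(bad_phot & !bad_prec))
  list(table = subset_loc_table(table, keep), report = rep)
}

subset_loc_table <- function(table, idx) {
  out <- as.data.frame(table)[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_frames") <- attr(table, "n_frames")
  attr(out, "frame_rate") <- attr(table, "frame_rate")
  class(out) <- c("loc_table", "data.frame")
  out
}

#' Remove repeated (consecutive-frame) localizations
#'
#' Within each channel, localizations are chained when a record appears
#' within `radius` of the chain's most recent member and within `frame_gap`
#' frames of it. All chain members after the first are removed; when the
#' chain persists for more than `max_frames` distinct frames the initial
#' localization is removed as well. Same-frame records may join an
#' established chain (two records in one frame both within radius of a prior
#' member both belong to it); removal is deterministic in table order.
#'
#' @param table a [loc_table()].
#' @param radius chaining radius (nm).
#' @param max_frames chain length (distinct frames) above which the seed is
#'   also removed.
#' @param frame_gap maximum frame difference between a chain's last member
#'   and a joining record.
#' @return list with `table` (filtered) and `report`.
#' @export
remove_repeated_localizations <- function(table, radius = 60, max_frames = 10,
                                          frame_gap = 1) {
  stopifnot(radius > 0, max_frames >= 1, frame_gap >= 1)
  n <- nrow(table)
  if (n == 0) return(list(table = table, report = filter_report(0L)))
  removed <- rep(FALSE, n)
  for (ch in unique(table$channel)) {
    ridx <- which(table$channel == ch)
    ord <- ridx[order(table$frame[ridx], ridx)]
    # active chains: position/frame of last member, seed row, frame count
    cx <- numeric(0); cy <- numeric(0); clast <- integer(0)
    cseed <- integer(0); cframes <- integer(0); csize <- integer(0)
    flush <- function(keep) {
      long <- !keep & cframes > max_frames
      removed[cseed[long]] <<- TRUE
      cx <<- cx[keep]; cy <<- cy[keep]; clast <<- clast[keep]
      cseed <<- cseed[keep]; cframes <<- cframes[keep]; csize <<- csize[keep]
    }
    for (i in ord) {
      f <- table$frame[i]
      if (length(clast) > 0) flush(clast >= f - frame_gap)
      joined <- FALSE
      if (length(clast) > 0) {
        df <- f - clast
        ok <- (df >= 1L & df <= frame_gap) | (df == 0L & csize >= 2L)
        if (any(ok)) {
          d2 <- (cx - table$x[i])^2 + (cy - table$y[i])^2
          d2[!ok] <- Inf
          j <- which.min(d2)
          if (d2[j] <= radius^2) {
            removed[i] <- TRUE
            cx[j] <- table$x[i]; cy[j] <- table$y[i]
            if (f > clast[j]) cframes[j] <- cframes[j] + 1L
            clast[j] <- f
            csize[j] <- csize[j] + 1L
            joined <- TRUE
          }
        }
      }
      if (!joined) {
        cx <- c(cx, table$x[i]); cy <- c(cy, table$y[i])
        clast <- c(clast, f); cseed <- c(cseed, i)
        cframes <- c(cframes, 1L); csize <- c(csize, 1L)
      }
    }
    if (length(clast) > 0) flush(rep(FALSE, length(clast)))
  }
  rep <- filter_report(n, removed_repeat = sum(removed))
  list(table = subset_loc_table(table, !removed), report = rep)
}
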