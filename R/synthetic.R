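# Ground-truth-labeled synthetic data for every pipeline stage: two-channel
# synaptic localization tables with blinking emitters, matched widefield
# images, and FRAP recovery traces.
#
# The generator emulates the acquisition the analysis is designed for:
# 20,000 frames at 50 Hz, localization precision mostly in the <= 25-30 nm
# regime, photon counts spanning roughly 300-30,000, nanodomains of a few
# tens of nm, and emitters blinking over geometric runs of consecutive
# frames so the 60-nm/10-frame repeat filter has work to do.

#' Ground truth for one simulated synapse pair
#'
#' Defaults are the study conditions of the dual-color synapse analysis:
#' two channels (PSD95, GluA1), Gaussian nanodomains of sigma 25 nm with
#' ~300 localizations each, uniform background localizations, a 300 x 300 nm
#' synapse extent, 20,000 frames at 50 Hz, localization precision ~ N(12, 4)
#' nm truncated positive, and log-normal photon counts (median 2000).
#'
#' @param n_domains_a,n_domains_b nanodomain count per channel.
#' @param sigma_nm nanodomain spread (Gaussian sigma, nm).
#' @param locs_per_domain expected localizations per nanodomain.
#' @param background_density background localization density (per um^2).
#' @param extent_nm synapse side length (nm); domains live inside it.
#' @param shared_centers logical; when TRUE channel B domain centers are the
#'   channel A centers shifted by `center_offset_nm`, otherwise placed
#'   independently.
#' @param center_offset_nm cross-channel center offset (nm) applied when
#'   `shared_centers` (in a deterministic direction per domain).
#' @param domain_centers_a,domain_centers_b optional explicit k x 2 center
#'   matrices (nm, relative to the synapse extent); override the count
#'   arguments.
#' @param n_frames,frame_rate acquisition length and rate.
#' @param mean_blink_frames mean length (frames) of a blinking run; runs are
#'   1 + geometric, so lengths beyond 10 frames occur with positive
#'   probability.
#' @param precision_mean,precision_sd localization precision distribution
#'   (truncated normal, nm).
#' @param photons_meanlog,photons_sdlog log-normal photon-count parameters.
#' @param channels channel labels.
#' @return list of class `synapse_ground_truth`.
#' @export
synapse_ground_truth <- function(n_domains_a = 2, n_domains_b = 1,
                                 sigma_nm = 25, locs_per_domain = 300,
                                 background_density = 800,
                                 extent_nm = 300, shared_centers = TRUE,
                                 center_offset_nm = 0,
                                 domain_centers_a = NULL,
                                 domain_centers_b = NULL,
                                 n_frames = 20000L, frame_rate = 50,
                                 mean_blink_frames = 3,
                                 precision_mean = 12, precision_sd = 4,
                                 photons_meanlog = log(2000),
                                 photons_sdlog = 0.8,
                                 channels = c("PSD95", "GluA1")) {
  stopifnot(sigma_nm > 0, locs_per_domain > 0, background_density >= 0,
            extent_nm > 0, n_frames >= 1, frame_rate > 0,
            mean_blink_frames >= 1, precision_mean > 0, precision_sd >= 0,
            center_offset_nm >= 0, length(channels) == 2)
  structure(as.list(environment()), class = "synapse_ground_truth")
}

# Evenly spread k points inside the extent with generous separation: on a
# centered ring of radius extent/4 (k > 1) or at the center (k = 1).
.default_centers <- function(k, extent) {
  if (k == 0) return(matrix(numeric(0), 0, 2))
  if (k == 1) return(matrix(extent / 2, 1, 2))
  ang <- 2 * pi * (seq_len(k) - 1) / k + pi / 8
  cbind(extent / 2 + extent / 4 * cos(ang),
        extent / 2 + extent / 4 * sin(ang))
}

.rtruncnorm_pos <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= 0)
  }
  out
}

# Emitters -> blinking localization runs for one channel.
.emit_channel <- function(emitters, gt, channel) {
  n_em <- nrow(emitters)
  if (n_em == 0) {
    return(loc_table(channel = character(0), n_frames = gt$n_frames,
                     frame_rate = gt$frame_rate))
  }
  p_stop <- 1 / gt$mean_blink_frames
  run_len <- 1L + stats::rgeom(n_em, p_stop)
  start <- sample.int(gt$n_frames, n_em, replace = TRUE) - 1L
  run_len <- pmin(run_len, gt$n_frames - start)
  idx <- rep.int(seq_len(n_em), run_len)
  frame <- start[idx] + (sequence(run_len) - 1L)
  n_loc <- length(idx)
  precision <- .rtruncnorm_pos(n_loc, gt$precision_mean, gt$precision_sd)
  x <- emitters[idx, 1] + stats::rnorm(n_loc, 0, precision)
  y <- emitters[idx, 2] + stats::rnorm(n_loc, 0, precision)
  photons <- stats::rlnorm(n_loc, gt$photons_meanlog, gt$photons_sdlog)
  ord <- order(frame, seq_along(frame))
  loc_table(x = x[ord], y = y[ord], frame = frame[ord],
            photons = photons[ord], precision = precision[ord],
            channel = channel, n_frames = gt$n_frames,
            frame_rate = gt$frame_rate)
}

#' Simulate a two-channel synaptic localization pair
#'
#' Emitter positions are drawn from a Gaussian-mixture (nanodomains) plus
#' uniform (background) model; each emitter produces a geometric-length run
#' of consecutive-frame localizations, each jittered by its own sampled
#' precision, with log-normal photon counts. Deterministic given `seed`.
#'
#' @param gt a [synapse_ground_truth()].
#' @param seed integer RNG seed.
#' @param origin_nm offset added to all coordinates (length 2, nm).
#' @return list with `a`, `b` (per-channel [loc_table()]s), `truth` (the
#'   ground truth echoed back, with realized domain centers in absolute nm
#'   under `centers_a`/`centers_b`).
#' @export
simulate_synapse_pair <- function(gt = synapse_ground_truth(), seed = 1,
                                  origin_nm = c(0, 0)) {
  set.seed(as.integer(seed))
  ext <- gt$extent_nm
  ca <- if (!is.null(gt$domain_centers_a)) gt$domain_centers_a else
    .default_centers(gt$n_domains_a, ext)
  cb <- if (!is.null(gt$domain_centers_b)) {
    gt$domain_centers_b
  } else if (gt$shared_centers) {
    k <- min(nrow(ca), gt$n_domains_b)
    if (k == 0) matrix(numeric(0), 0, 2) else {
      ang <- 2 * pi * (seq_len(k) - 1) / max(k, 1)
      ca[seq_len(k), , drop = FALSE] +
        gt$center_offset_nm * cbind(cos(ang), sin(ang))
    }
  } else {
    # independent placement: uniform over the central half of the extent
    matrix(stats::runif(2 * gt$n_domains_b, ext / 4, 3 * ext / 4),
           ncol = 2)
  }
  n_bg <- round(gt$background_density * (ext / 1000)^2)
  mean_run <- gt$mean_blink_frames
  emitters_for <- function(centers) {
    n_dom_em <- round(gt$locs_per_domain / mean_run)
    dom <- if (nrow(centers) > 0) {
      do.call(rbind, lapply(seq_len(nrow(centers)), function(k) {
        cbind(stats::rnorm(n_dom_em, centers[k, 1], gt$sigma_nm),
              stats::rnorm(n_dom_em, centers[k, 2], gt$sigma_nm))
      }))
    } else matrix(numeric(0), 0, 2)
    n_bg_em <- round(n_bg / mean_run)
    bg <- cbind(stats::runif(n_bg_em, 0, ext), stats::runif(n_bg_em, 0, ext))
    rbind(dom, bg)
  }
  shift <- function(m) sweep(m, 2, origin_nm, "+")
  tab_a <- .emit_channel(shift(emitters_for(ca)), gt, gt$channels[1])
  tab_b <- .emit_channel(shift(emitters_for(cb)), gt, gt$channels[2])
  truth <- gt
  truth$centers_a <- if (nrow(ca)) shift(ca) else ca
  truth$centers_b <- if (nrow(cb)) shift(cb) else cb
  truth$origin_nm <- origin_nm
  list(a = tab_a, b = tab_b, truth = truth)
}

#' Simulate a widefield image from a localization table
#'
#' Localization density convolved with an isotropic Gaussian PSF and sampled
#' on the pixel grid; total intensity is proportional to the localization
#' count.
#'
#' @param table a [loc_table()].
#' @param psf_sigma PSF sigma (nm).
#' @param pix pixel size (nm).
#' @param width_nm,height_nm image extent (defaults fit the data).
#' @return a [widefield_image()].
#' @export
simulate_widefield <- function(table, psf_sigma = 150, pix = 117,
                               width_nm = NULL, height_nm = NULL) {
  stopifnot(psf_sigma > 0, pix > 0)
  img <- render_reconstruction(table, pix = pix, width_nm = width_nm,
                               height_nm = height_nm)
  if (nrow(table) == 0 || max(img) == 0) return(img)
  m <- unclass(img)
  attr(m, "pixel_size") <- NULL
  sm <- EBImage::imageData(EBImage::gblur(m, sigma = psf_sigma / pix))
  widefield_image(sm, pix)
}

#' Ground truth for a simulated FRAP trace
#'
#' @param mobile_fraction plateau of the normalized recovery, in `[0, 1]`.
#' @param tau recovery time constant (min).
#' @param n_pre pre-bleach frames.
#' @param post_duration post-bleach duration (min).
#' @param dt frame spacing (min).
#' @param noise_sd Gaussian noise sigma on the raw intensities (in units of
#'   the pre-bleach ROI intensity).
#' @param ref_decay_rate bleach-reference exponential decay rate (per min).
#' @param roi_intensity,background pre-bleach ROI plateau and background
#'   level (a.u.).
#' @export
frap_ground_truth <- function(mobile_fraction = 0.31, tau = 8, n_pre = 4,
                              post_duration = 30, dt = 5, noise_sd = 0.02,
                              ref_decay_rate = 0.01, roi_intensity = 100,
                              background = 10) {
  stopifnot(mobile_fraction >= 0, mobile_fraction <= 1, tau > 0, n_pre >= 1,
            post_duration >= dt, dt > 0, noise_sd >= 0, ref_decay_rate >= 0)
  structure(as.list(environment()), class = "frap_ground_truth")
}

#' Simulate a raw FRAP trace with known truth
#'
#' The corrected-domain truth is 1 before the bleach and
#' `M * (1 - exp(-t/tau))` after it (t from the bleach frame). The raw trace
#' reverses the correction pipeline: scale by the ROI intensity, apply the
#' reference decay, add background and Gaussian noise. Deterministic given
#' `seed`.
#'
#' @param gt a [frap_ground_truth()].
#' @param seed integer RNG seed.
#' @param roi_id,cell_id identifiers for the trace.
#' @return list with `trace` (raw [frap_trace()]) and `truth` (gt echoed,
#'   plus `times`, `truth_normalized`, and `expected_mobile_fraction`, the
#'   plateau mean the estimator targets at the sampled times).
#' @export
simulate_frap_trace <- function(gt = frap_ground_truth(), seed = 1,
                                roi_id = "roi1", cell_id = "cell1") {
  set.seed(as.integer(seed))
  t_pre <- seq(-gt$n_pre * gt$dt, -gt$dt, by = gt$dt)
  t_post <- seq(0, gt$post_duration, by = gt$dt)
  times <- c(t_pre, t_post)
  bleach_index <- length(t_pre) + 1L
  truth_norm <- c(rep(1, length(t_pre)),
                  gt$mobile_fraction * (1 - exp(-t_post / gt$tau)))
  decay <- exp(-gt$ref_decay_rate * (times - times[1]))
  roi_raw <- truth_norm * gt$roi_intensity * decay + gt$background +
    stats::rnorm(length(times), 0, gt$noise_sd * gt$roi_intensity)
  ref_raw <- gt$roi_intensity * decay + gt$background
  trace <- frap_trace(times, roi_raw, background = gt$background,
                      reference = ref_raw, bleach_index = bleach_index,
                      stage = "raw", roi_id = roi_id, cell_id = cell_id)
  truth <- gt
  truth$times <- times
  truth$truth_normalized <- truth_norm
  n_post <- length(t_post)
  last4 <- t_post[(n_post - 3):n_post]
  truth$expected_mobile_fraction <-
    mean(gt$mobile_fraction * (1 - exp(-last4 / gt$tau)))
  list(trace = trace, truth = truth)
}
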