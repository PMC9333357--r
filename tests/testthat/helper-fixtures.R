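# Programmatic fixtures shared across test files.

# Gaussian spot image: background + sum of isotropic Gaussians.
gaussian_spot_image <- function(pix = 30, n_px = 200, bg = 10,
                                spots = list(list(center = c(3000, 3000),
                                                  amplitude = 100,
                                                  sigma = 180))) {
  xc <- (seq_len(n_px) - 0.5) * pix
  img <- matrix(bg, n_px, n_px)
  for (s in spots) {
    img <- img + s$amplitude *
      outer(xc, xc, function(y, x) {
        exp(-((x - s$center[1])^2 + (y - s$center[2])^2) / (2 * s$sigma^2))
      })
  }
  widefield_image(img, pix)
}

# Minimal localization table at given coordinates.
locs_at <- function(x, y, frame = seq_along(x) - 1L, photons = 1000,
                    precision = 10, channel = "ch1", n_frames = 20000L) {
  loc_table(x = x, y = y, frame = frame,
            photons = rep_len(photons, length(x)),
            precision = rep_len(precision, length(x)),
            channel = rep_len(channel, length(x)), n_frames = n_frames)
}
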