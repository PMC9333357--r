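test_that("FWHM region of a Gaussian spot matches the analytic half-max disc", {
  sigma <- 180
  img <- gaussian_spot_image(pix = 30, n_px = 200, bg = 10,
                             spots = list(list(center = c(3000, 3000),
                                               amplitude = 100,
                                               sigma = sigma)))
  rois <- segment_widefield(img, smoothing = 0, min_peak_height = 5)
  expect_length(rois, 1L)
  analytic <- pi * (sigma * sqrt(2 * log(2)))^2 / 1e6  # um^2
  expect_equal(rois[[1]]$area, analytic, tolerance = 0.1)
  expect_equal(rois[[1]]$peak, c(3000, 3000), tolerance = 30)
})

test_that("a constant image yields no ROIs, with a warning", {
  img <- widefield_image(matrix(7, 50, 50), 100)
  expect_warning(rois <- segment_widefield(img), "no intensity peak")
  expect_length(rois, 0L)
})

test_that("two spots 3 um apart give two disjoint ROIs", {
  img <- gaussian_spot_image(pix = 100, n_px = 80, bg = 5, spots = list(
    list(center = c(2500, 2500), amplitude = 80, sigma = 200),
    list(center = c(5500, 2500), amplitude = 60, sigma = 200)))
  rois <- segment_widefield(img, smoothing = 0, min_peak_height = 10)
  expect_length(rois, 2L)
  # disjoint: no vertex of one inside the other
  b1 <- rois[[1]]$boundary; b2 <- rois[[2]]$boundary
  expect_false(any(point_in_polygon(b1[, 1], b1[, 2], b2)))
  expect_false(any(point_in_polygon(b2[, 1], b2[, 2], b1)))
})

test_that("segmentation is equivariant under whole-pixel translation", {
  base <- gaussian_spot_image(pix = 100, n_px = 60, bg = 5, spots = list(
    list(center = c(2000, 2500), amplitude = 90, sigma = 220)))
  shifted <- widefield_image(rbind(matrix(5, 3, 60), unclass(base)[1:57, ]),
                             100)  # shift down 3 px
  r1 <- segment_widefield(base, smoothing = 0, min_peak_height = 10)
  r2 <- segment_widefield(shifted, smoothing = 0, min_peak_height = 10)
  expect_equal(r2[[1]]$peak[2] - r1[[1]]$peak[2], 300)
  expect_equal(r2[[1]]$area, r1[[1]]$area, tolerance = 1e-6)
})

test_that("k well-separated spots give exactly k ROIs across seeds", {
  for (s in 1:10) {
    set.seed(s)
    k <- sample(1:4, 1)
    centers <- cbind(1500 + 3000 * (seq_len(k) - 1) %% 3,
                     1500 + 3000 * ((seq_len(k) - 1) %/% 3))
    spots <- lapply(seq_len(k), function(i) {
      list(center = centers[i, ] + runif(2, -200, 200),
           amplitude = runif(1, 50, 120), sigma = runif(1, 150, 250))
    })
    img <- gaussian_spot_image(pix = 100, n_px = 100, bg = 5, spots = spots)
    rois <- segment_widefield(img, smoothing = 0, min_peak_height = 20)
    expect_length(rois, k)
  }
})

test_that("localizations are assigned by point-in-polygon with conservation", {
  roi <- structure(list(id = 1L,
                        boundary = matrix(c(0, 0, 1000, 0, 1000, 1000,
                                            0, 1000), ncol = 2, byrow = TRUE),
                        area = 1, peak = c(500, 500)),
                   class = "synapse_roi")
  set.seed(3)
  inside <- locs_at(runif(100, 1, 999), runif(100, 1, 999))
  recs <- assign_localizations(inside, list(roi))
  expect_equal(nrow(recs[[1]]$locs), 100L)
  expect_equal(attr(recs, "n_unassigned"), 0L)
  # centroid localization assigned; far-away localization unassigned
  far <- locs_at(c(500, 2500), c(500, 500))
  recs2 <- assign_localizations(far, list(roi))
  expect_equal(nrow(recs2[[1]]$locs), 1L)
  expect_equal(attr(recs2, "n_unassigned"), 1L)
  # boundary localization belongs to the ROI
  edge <- locs_at(0, 500)
  expect_equal(nrow(assign_localizations(edge, list(roi))[[1]]$locs), 1L)
})

test_that("overlapping ROIs assign to the nearest peak and log the overlap", {
  sq <- function(id, x0, peak) structure(
    list(id = id, boundary = matrix(c(x0, 0, x0 + 1000, 0, x0 + 1000, 1000,
                                      x0, 1000), ncol = 2, byrow = TRUE),
         area = 1, peak = peak), class = "synapse_roi")
  rois <- list(sq(1L, 0, c(300, 500)), sq(2L, 500, c(1200, 500)))
  tab <- locs_at(c(600, 900), c(500, 500))  # both in the overlap
  recs <- assign_localizations(tab, rois)
  expect_equal(nrow(recs[[1]]$locs), 1L)  # 600 closer to peak 300
  expect_equal(nrow(recs[[2]]$locs), 1L)  # 900 closer to peak 1200
  expect_equal(attr(recs, "n_overlap"), 2L)
})

test_that("synapse selection applies strict count and area gates", {
  mk_rec <- function(n_psd, n_glua, area) {
    locs <- locs_at(runif(n_psd + n_glua, 0, 500),
                    runif(n_psd + n_glua, 0, 500),
                    channel = rep(c("PSD95", "GluA1"), c(n_psd, n_glua)))
    structure(list(roi = structure(list(id = 1L, boundary = NULL,
                                        area = area, peak = c(0, 0)),
                                   class = "synapse_roi"),
                   locs = locs, psd_area = area, psd_center = c(0, 0)),
              class = "synapse_record")
  }
  set.seed(1)
  crit <- inclusion_criteria()
  expect_length(select_synapses(list(mk_rec(801, 401, 0.10)), crit), 1L)
  expect_length(select_synapses(list(mk_rec(800, 401, 0.10)), crit), 0L)
  expect_length(select_synapses(list(mk_rec(801, 400, 0.10)), crit), 0L)
  expect_length(select_synapses(list(mk_rec(801, 401, 0.35)), crit), 0L)
  expect_length(select_synapses(list(mk_rec(801, 401, 0.02)), crit), 0L)
})
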