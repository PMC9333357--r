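mk_raw <- function(roi, bg = 0, ref = 1, bleach_index = 4L, dt = 5) {
  frap_trace(times = seq(0, by = dt, length.out = length(roi)) - dt * (bleach_index - 1),
             roi = roi, background = bg, reference = ref,
             bleach_index = bleach_index)
}

test_that("correction subtracts background and compensates reference decay", {
  # constant reference: background subtraction only
  tr <- mk_raw(rep(110, 8), bg = 10, ref = 100)
  expect_equal(correct_trace(tr)$roi, rep(100, 8))
  # reference decayed to 90%: roi-bg of 90 is restored to 100
  roi <- c(110, 110, 110, 100 * 0.9 + 10)
  ref <- c(110, 110, 110, 100 * 0.9 + 10)
  tr2 <- mk_raw(roi, bg = 10, ref = ref, bleach_index = 4L)
  expect_equal(correct_trace(tr2)$roi[4], 100)
  # reference at or below background is a correction error
  tr3 <- mk_raw(rep(100, 5), bg = 10, ref = c(100, 100, 5, 100, 100))
  expect_error(correct_trace(tr3), "correction error")
})

test_that("normalization fixes the pre-bleach mean at 1 and F0 at 0", {
  tr <- mk_raw(c(100, 100, 100, 40, 55, 70, 70, 70), bg = 0, ref = 1,
               bleach_index = 4L)
  nt <- normalize_trace(correct_trace(tr))
  expect_equal(mean(nt$roi[1:3]), 1)
  expect_equal(nt$roi[4], 0)
  expect_equal(nt$roi[6], 0.5)  # (70 - 40) / (100 - 40)
  # no bleach depth
  flat <- mk_raw(rep(100, 6), bleach_index = 3L)
  expect_error(normalize_trace(correct_trace(flat)), "no bleach depth")
})

test_that("mobile fraction averages the last four normalized frames", {
  tr <- mk_raw(c(100, 100, 100, 40, 70, 70.8, 69.2, 71.2, 70.0),
               bleach_index = 4L)
  nt <- normalize_trace(correct_trace(tr))
  expect_equal(mobile_fraction(nt),
               mean((c(70.8, 69.2, 71.2, 70.0) - 40) / 60))
  expect_equal(mobile_fraction(nt, n_last = 1), 0.5)
  # fully recovered trace
  full <- normalize_trace(correct_trace(
    mk_raw(c(100, 100, 100, 0, 100, 100, 100, 100), bleach_index = 4L)))
  expect_equal(mobile_fraction(full), 1)
  short <- normalize_trace(correct_trace(
    mk_raw(c(100, 100, 100, 0, 50), bleach_index = 4L)))
  expect_error(mobile_fraction(short), "post-bleach")
})

test_that("normalized traces are invariant to affine rescaling of the raw data", {
  gt <- frap_ground_truth(mobile_fraction = 0.4, noise_sd = 0)
  sim <- simulate_frap_trace(gt, seed = 2)
  tr <- sim$trace
  gain <- 3.7; offset <- 25
  tr2 <- frap_trace(tr$time, tr$roi * gain + offset,
                    background = tr$background * gain + offset,
                    reference = tr$reference * gain + offset,
                    bleach_index = attr(tr, "bleach_index"))
  n1 <- normalize_trace(correct_trace(tr))
  n2 <- normalize_trace(correct_trace(tr2))
  expect_equal(n2$roi, n1$roi, tolerance = 1e-10)
})

test_that("the estimator is unbiased on noiseless exponential recoveries", {
  for (M in c(0.1, 0.5, 1.0)) {
    gt <- frap_ground_truth(mobile_fraction = M, tau = 2, noise_sd = 0,
                            post_duration = 60)
    sim <- simulate_frap_trace(gt, seed = 1)
    mf <- mobile_fraction(normalize_trace(correct_trace(sim$trace)))
    expect_equal(mf, sim$truth$expected_mobile_fraction, tolerance = 1e-9)
    # plateau reached (tau << total time): estimate ~ M itself
    expect_equal(mf, M, tolerance = 1e-3)
  }
})

test_that("mobile fraction is recovered within 0.05 across noise and M", {
  set.seed(42)
  for (M in c(0.1, 0.3, 0.5, 0.8)) {
    gt <- frap_ground_truth(mobile_fraction = M, noise_sd = 0.02)
    est <- vapply(1:50, function(s) {
      sim <- simulate_frap_trace(gt, seed = s)
      mobile_fraction(normalize_trace(correct_trace(sim$trace)))
    }, numeric(1))
    expected <- simulate_frap_trace(gt, seed = 1)$truth$expected_mobile_fraction
    expect_lt(abs(mean(est) - expected), 0.05)
  }
})

test_that("frap summary aggregates per ROI and per cell, and round-trips CSV", {
  gt <- frap_ground_truth(mobile_fraction = 0.31, noise_sd = 0.01)
  traces <- list(
    simulate_frap_trace(gt, seed = 1, roi_id = "r1", cell_id = "c1")$trace,
    simulate_frap_trace(gt, seed = 2, roi_id = "r2", cell_id = "c1")$trace,
    simulate_frap_trace(gt, seed = 3, roi_id = "r1", cell_id = "c2")$trace)
  summ <- frap_summary(traces)
  expect_equal(nrow(summ$per_roi), 3L)
  expect_equal(nrow(summ$per_cell), 2L)
  c1 <- summ$per_roi$mobile_fraction[summ$per_roi$cell_id == "c1"]
  expect_equal(summ$per_cell$mobile_fraction[summ$per_cell$cell_id == "c1"],
               mean(c1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_frap_traces(traces, path)
  back <- read_frap_traces(path)
  expect_length(back, 3L)
  s2 <- frap_summary(back)
  expect_equal(sort(s2$per_roi$mobile_fraction),
               sort(summ$per_roi$mobile_fraction))
})

test_that("synaptic enrichment is the ratio of disc-ROI means", {
  img <- widefield_image(matrix(100, 60, 60), 100)  # 6 x 6 um
  img[, 1:30] <- 200  # left half brighter
  syn <- cbind(runif(10, 500, 2500), runif(10, 500, 5500))
  sha <- cbind(runif(10, 3500, 5500), runif(10, 500, 5500))
  enr <- synaptic_enrichment(img, syn, sha, diameter = 250)
  expect_equal(enr$ratio, 2)
  expect_equal(synaptic_enrichment(img, sha, sha)$ratio, 1)
  # background subtraction and degenerate shaft
  expect_equal(synaptic_enrichment(img, syn, sha, background = 50)$ratio, 3)
  expect_error(synaptic_enrichment(img, syn, sha, background = 200), "shaft")
})
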