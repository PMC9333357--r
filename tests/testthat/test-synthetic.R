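test_that("the simulator is deterministic given a seed and echoes its truth", {
  gt <- synapse_ground_truth()
  s1 <- simulate_synapse_pair(gt, seed = 42)
  s2 <- simulate_synapse_pair(gt, seed = 42)
  expect_identical(s1$a, s2$a)
  expect_identical(s1$b, s2$b)
  expect_identical(s1$truth$centers_a, s2$truth$centers_a)
  s3 <- simulate_synapse_pair(gt, seed = 43)
  expect_false(identical(s1$a$x, s3$a$x))
  # echo of the request parameters
  expect_equal(s1$truth$sigma_nm, gt$sigma_nm)
  expect_equal(s1$truth$n_frames, gt$n_frames)
})

test_that("without background, localizations concentrate around the center", {
  gt <- synapse_ground_truth(n_domains_a = 1, n_domains_b = 1,
                             background_density = 0, locs_per_domain = 500,
                             mean_blink_frames = 1, precision_mean = 5,
                             precision_sd = 1)
  sim <- simulate_synapse_pair(gt, seed = 9)
  ctr <- sim$truth$centers_a[1, ]
  # position spread = domain sigma + localization precision in quadrature
  eff_sd <- sqrt(gt$sigma_nm^2 + 6^2)
  r <- sqrt((sim$a$x - ctr[1])^2 + (sim$a$y - ctr[2])^2)
  expect_gte(mean(r <= 4 * eff_sd), 0.99)
})

test_that("simulated frames, photons and precision respect their models", {
  gt <- synapse_ground_truth(locs_per_domain = 3000, mean_blink_frames = 3)
  sim <- simulate_synapse_pair(gt, seed = 4)
  tab <- sim$a
  expect_true(all(tab$frame >= 0 & tab$frame < gt$n_frames))
  expect_true(all(tab$photons > 0))
  expect_true(all(tab$precision > 0))
  # KS tests against the declared distributions
  expect_gt(stats::ks.test(tab$photons,
                           stats::plnorm, gt$photons_meanlog,
                           gt$photons_sdlog)$p.value, 0.01)
  ptrunc <- function(q) {
    (stats::pnorm(q, gt$precision_mean, gt$precision_sd) -
       stats::pnorm(0, gt$precision_mean, gt$precision_sd)) /
      (1 - stats::pnorm(0, gt$precision_mean, gt$precision_sd))
  }
  expect_gt(stats::ks.test(tab$precision, ptrunc)$p.value, 0.01)
})

test_that("blinking runs are consecutive and occasionally exceed 10 frames", {
  gt <- synapse_ground_truth(n_domains_a = 1, background_density = 0,
                             locs_per_domain = 4000, mean_blink_frames = 5,
                             sigma_nm = 1e5, extent_nm = 1e6)
  # huge sigma spreads emitters out so runs are spatially isolated
  sim <- simulate_synapse_pair(gt, seed = 13)
  res <- remove_repeated_localizations(sim$a, radius = 60, max_frames = 1e9)
  # chained localizations exist (runs longer than 1 frame)
  expect_gt(res$report$removed_repeat, 0)
  # and some emitters persist beyond 10 frames
  res2 <- remove_repeated_localizations(sim$a, radius = 60, max_frames = 10)
  expect_gt(nrow(res$table), nrow(res2$table))
})

test_that("widefield simulation is linear and peaks at the localizations", {
  one <- locs_at(1000, 1500)
  img <- simulate_widefield(one, psf_sigma = 150, pix = 100,
                            width_nm = 3000, height_nm = 3000)
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  expect_equal(unname((peak["col"] - 0.5) * 100), 1000, tolerance = 100)
  expect_equal(unname((peak["row"] - 0.5) * 100), 1500, tolerance = 100)
  # doubling the localizations doubles the integrated intensity
  two <- locs_at(c(1000, 1000), c(1500, 1500))
  img2 <- simulate_widefield(two, psf_sigma = 150, pix = 100,
                             width_nm = 3000, height_nm = 3000)
  expect_equal(sum(img2), 2 * sum(img), tolerance = 1e-6)
  # two clusters 3 um apart give two local maxima
  set.seed(2)
  tab <- locs_at(c(rnorm(50, 1000, 30), rnorm(50, 4000, 30)),
                 c(rnorm(100, 1000, 30)))
  img3 <- simulate_widefield(tab, psf_sigma = 150, pix = 100,
                             width_nm = 5000, height_nm = 2000)
  mx <- synloc:::.local_maxima(unclass(img3))
  high <- mx[img3[mx] > max(img3) / 4, , drop = FALSE]
  expect_equal(nrow(high), 2L)
})

test_that("FRAP simulation inverts to its truth in the noiseless case", {
  gt <- frap_ground_truth(mobile_fraction = 0.31, noise_sd = 0,
                          ref_decay_rate = 0.02)
  sim <- simulate_frap_trace(gt, seed = 1)
  nt <- normalize_trace(correct_trace(sim$trace))
  expect_equal(nt$roi, sim$truth$truth_normalized, tolerance = 1e-9)
  # M = 0: post-bleach truth identically 0
  gt0 <- frap_ground_truth(mobile_fraction = 0, noise_sd = 0)
  sim0 <- simulate_frap_trace(gt0, seed = 1)
  post <- seq(attr(sim0$trace, "bleach_index"), nrow(sim0$trace))
  expect_true(all(sim0$truth$truth_normalized[post] == 0))
  # M = 1, tau -> 0: immediate full recovery after the bleach frame
  gt1 <- frap_ground_truth(mobile_fraction = 1, tau = 1e-9, noise_sd = 0)
  sim1 <- simulate_frap_trace(gt1, seed = 1)
  nt1 <- normalize_trace(correct_trace(sim1$trace))
  expect_equal(nt1$roi[post[-1]], rep(1, length(post) - 1), tolerance = 1e-6)
})

test_that("mean CI decreases monotonically with cross-channel offset", {
  offsets <- c(0, 25, 50, 100)
  set.seed(31)
  seeds <- sample.int(1e6, 12)
  mean_ci <- vapply(offsets, function(off) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_synapse_pair(synapse_ground_truth(
        center_offset_nm = off, mean_blink_frames = 1), seed = s)
      cr <- colocalization_index(sim$a, sim$b)
      (cr$mean_ci_a + cr$mean_ci_b) / 2
    }, numeric(1)))
  }, numeric(1))
  expect_equal(order(mean_ci, decreasing = TRUE), seq_along(offsets))
})
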