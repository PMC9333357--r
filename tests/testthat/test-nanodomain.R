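test_that("MNND handles small knowns and degenerate input", {
  expect_equal(mnnd(cbind(c(0, 1, 3), 0)), 4 / 3)
  expect_equal(mnnd(rbind(c(0, 0), c(3, 4))), 5)
  expect_error(mnnd(rbind(c(1, 1))), "fewer than 2")
})

test_that("local density counts neighbors within the radius, self excluded", {
  pts <- cbind(c(0, 10, 20), 0)
  expect_equal(local_density(pts, 10), c(1L, 2L, 1L))
  expect_equal(local_density(rbind(c(0, 0), c(1000, 1000)), 10), c(0L, 0L))
  set.seed(11)
  p <- cbind(runif(500, 0, 1000), runif(500, 0, 1000))
  expect_identical(local_density(p, 60), oracle_local_density(p, 60))
})

test_that("MNND and LD are rigid-motion invariant; MNND scales linearly", {
  set.seed(21)
  pts <- cbind(runif(200, 0, 500), runif(200, 0, 500))
  th <- 0.7
  rot <- pts %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  moved <- sweep(rot, 2, c(1500, -300), "+")
  expect_equal(mnnd(moved), mnnd(pts))
  expect_identical(local_density(moved, 75), local_density(pts, 75))
  expect_equal(mnnd(pts * 3.5), 3.5 * mnnd(pts))
})

test_that("two well-separated simulated nanodomains are both recovered", {
  gt <- synapse_ground_truth(
    n_domains_a = 2, locs_per_domain = 300, sigma_nm = 25,
    background_density = 100 / 0.09,  # ~100 background locs on 300x300 nm
    extent_nm = 300, mean_blink_frames = 1,
    domain_centers_a = rbind(c(70, 150), c(230, 150)))  # 160 nm apart
  sim <- simulate_synapse_pair(gt, seed = 5)
  nd <- detect_nanodomains(sim$a)
  expect_length(nd, 2L)
  centers <- t(vapply(nd, function(d) d$center, numeric(2)))
  centers <- centers[order(centers[, 1]), ]
  truth <- sim$truth$centers_a[order(sim$truth$centers_a[, 1]), ]
  expect_lt(max(abs(centers - truth)), 10)
})

test_that("uniform points below the LD threshold give no nanodomains", {
  set.seed(14)
  pts <- cbind(runif(200, 0, 600), runif(200, 0, 600))
  r <- 5 * mnnd(pts)
  expect_lte(max(oracle_local_density(pts, r)), 40)  # premise of the case
  expect_length(detect_nanodomains(pts), 0L)
})

test_that("retention rules exclude small-fraction and small-diameter domains", {
  set.seed(31)
  # dense cluster carrying ~4% of the synapse localizations
  cluster <- cbind(rnorm(40, 300, 8), rnorm(40, 300, 8))
  bg <- cbind(runif(960, 0, 600), runif(960, 0, 600))
  pts <- rbind(cluster, bg)
  nd <- detect_nanodomains(pts)
  fr <- vapply(nd, function(d) d$member_fraction, 0)
  expect_true(all(fr >= 0.05))
  expect_true(length(nd) == 0 ||
                all(vapply(nd, function(d) d$diameter, 0) >= 30))
  # a tight cluster whose Voronoi footprint is under 30 nm across
  tight <- rbind(cbind(rnorm(60, 100, 4), rnorm(60, 100, 4)),
                 cbind(runif(100, 0, 220), runif(100, 0, 220)))
  nd2 <- detect_nanodomains(tight)
  expect_true(all(vapply(nd2, function(d) d$diameter, 0) >= 30))
})

test_that("retained nanodomains partition their members and pass re-checks", {
  sim <- simulate_synapse_pair(synapse_ground_truth(
    n_domains_a = 3, locs_per_domain = 300, extent_nm = 400,
    mean_blink_frames = 1), seed = 8)
  nd <- detect_nanodomains(sim$a)
  members <- unlist(lapply(nd, function(d) d$members))
  expect_equal(anyDuplicated(members), 0L)
  n <- nrow(sim$a)
  for (d in nd) {
    expect_gte(d$member_fraction, 0.05)
    expect_gte(d$diameter, 30)
    expect_equal(d$member_fraction, length(d$members) / n)
    expect_true(all(point_in_polygon(sim$a$x[d$members], sim$a$y[d$members],
                                     d$boundary, boundary_tol = 1e-6)))
  }
})

test_that("subcluster splitting follows the 80% / 80 nm / 30% rule", {
  # deterministic line of points: peaks at the ends, a valley between
  line_case <- function(sep, peak2_frac, valley_frac) {
    xs <- seq(0, sep, by = 10)
    pts <- cbind(xs, 0)
    ld <- rep(round(100 * valley_frac), length(xs))
    ld[1] <- 100
    ld[length(xs)] <- round(100 * peak2_frac)
    list(pts = pts, ld = ld)
  }
  params <- nanodomain_params()
  # peaks 100 nm apart, second at 90%, valley at 20%: split in two
  cs <- line_case(100, 0.90, 0.20)
  split <- split_nanodomain(cs$pts, cs$ld, params)
  expect_length(split, 2L)
  expect_setequal(unlist(split), seq_len(nrow(cs$pts)))
  # members go to the nearest retained peak
  expect_true(1L %in% split[[1]] && nrow(cs$pts) %in% split[[2]])
  # peaks only 60 nm apart (all else passing): no split
  cs2 <- line_case(60, 0.90, 0.20)
  expect_length(split_nanodomain(cs2$pts, cs2$ld, params), 1L)
  # second peak at 70% of the maximum: no split
  cs3 <- line_case(100, 0.70, 0.20)
  expect_length(split_nanodomain(cs3$pts, cs3$ld, params), 1L)
  # valley at only 40% of the maximum: no split
  cs4 <- line_case(100, 0.90, 0.40)
  expect_length(split_nanodomain(cs4$pts, cs4$ld, params), 1L)
})

test_that("a merged pair of dense peaks is split into two nanodomains", {
  gt <- synapse_ground_truth(
    n_domains_a = 2, locs_per_domain = 400, sigma_nm = 22,
    background_density = 0, extent_nm = 300, mean_blink_frames = 1,
    domain_centers_a = rbind(c(100, 150), c(210, 150)))  # 110 nm apart
  sim <- simulate_synapse_pair(gt, seed = 12)
  nd <- detect_nanodomains(sim$a)
  expect_equal(length(nd), 2L)
})

test_that("PSD centroid via DBSCAN recovers a known cluster center", {
  set.seed(17)
  mu <- c(500, 700)
  core <- cbind(rnorm(800, mu[1], 60), rnorm(800, mu[2], 60))
  outliers <- cbind(runif(20, 0, 2000), runif(20, 0, 2000))
  psd <- psd_centroid(rbind(core, outliers))
  expect_lt(sqrt(sum((psd$center - mu)^2)), 10)
  expect_gt(psd$psd_area, 0)
  # symmetric square
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  psd2 <- psd_centroid(sq, eps = 20, min_pts = 2)
  expect_equal(psd2$center, c(5, 5))
  expect_error(psd_centroid(rbind(c(0, 0), c(1, 1), c(2, 2)), eps = 5,
                            min_pts = 10), "min_pts")
})

test_that("topology metrics give PSD distances and cross-channel distances", {
  mk_nd <- function(cx, cy) structure(
    list(members = 1L, center = c(cx, cy), boundary = NULL, rings = list(),
         cells = list(), area_nm2 = 5000, diameter = 80, diameter_max = 90,
         member_fraction = 0.5), class = "nanodomain")
  nd_a <- list(mk_nd(30, 40))
  nd_b <- list(mk_nd(80, 40), mk_nd(230, 40))
  tm <- topology_metrics(nd_a, nd_b, psd_center = c(0, 0))
  a_row <- tm[tm$channel == "A", ]
  expect_equal(a_row$dist_psd_center, 50)        # 3-4-5
  expect_equal(a_row$dist_other_channel, 50)     # nearest of 50 and 200
  # other channel empty: missing + flagged
  tm2 <- topology_metrics(nd_a, list(), psd_center = c(0, 0))
  expect_true(is.na(tm2$dist_other_channel[1]))
  expect_true(tm2$other_channel_missing[1])
})
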