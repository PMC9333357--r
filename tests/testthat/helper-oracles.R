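# Brute-force oracles, written independently of the package's accelerated
# grid/chaining implementations: plain all-pairs loops.

oracle_local_density <- function(pts, radius) {
  n <- nrow(pts)
  vapply(seq_len(n), function(i) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    sum(d <= radius) - 1L
  }, numeric(1)) |> as.integer()
}

oracle_cross_count <- function(query, ref, radius) {
  vapply(seq_len(nrow(query)), function(i) {
    d <- sqrt((ref[, 1] - query[i, 1])^2 + (ref[, 2] - query[i, 2])^2)
    sum(d <= radius)
  }, numeric(1)) |> as.integer()
}

oracle_mnnd <- function(pts) {
  n <- nrow(pts)
  mean(vapply(seq_len(n), function(i) {
    d <- sqrt((pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2)
    min(d[-i])
  }, numeric(1)))
}

# Per-frame scan chain-removal oracle: walks records frame by frame,
# maintaining chains exactly as specified (join within radius of the chain's
# most recent member, 1 <= frame gap <= frame_gap, or same frame onto an
# established chain; seeds of chains spanning more than max_frames distinct
# frames are removed too). Returns the logical keep vector.
oracle_chain_keep <- function(tab, radius, max_frames, frame_gap) {
  n <- nrow(tab)
  removed <- rep(FALSE, n)
  for (ch in unique(tab$channel)) {
    idx <- which(tab$channel == ch)
    idx <- idx[order(tab$frame[idx], idx)]
    chains <- list()  # each: list(last = c(x, y, frame), seed, frames, size)
    for (i in idx) {
      f <- tab$frame[i]
      best <- 0; best_d <- Inf
      for (k in seq_along(chains)) {
        cc <- chains[[k]]
        df <- f - cc$last[3]
        ok <- (df >= 1 && df <= frame_gap) || (df == 0 && cc$size >= 2)
        if (!ok) next
        d <- sqrt((cc$last[1] - tab$x[i])^2 + (cc$last[2] - tab$y[i])^2)
        if (d <= radius && d < best_d) { best <- k; best_d <- d }
      }
      if (best > 0) {
        removed[i] <- TRUE
        cc <- chains[[best]]
        if (f > cc$last[3]) cc$frames <- cc$frames + 1
        cc$last <- c(tab$x[i], tab$y[i], f)
        cc$size <- cc$size + 1
        chains[[best]] <- cc
      } else {
        chains[[length(chains) + 1]] <-
          list(last = c(tab$x[i], tab$y[i], f), seed = i, frames = 1, size = 1)
      }
    }
    for (cc in chains) if (cc$frames > max_frames) removed[cc$seed] <- TRUE
  }
  !removed
}

# Random localization table for oracle comparisons.
random_loc_table <- function(n, extent = 1000, n_frames = 200,
                             channels = "ch1") {
  loc_table(x = runif(n, 0, extent), y = runif(n, 0, extent),
            frame = sample.int(n_frames, n, replace = TRUE) - 1L,
            photons = runif(n, 301, 29999),
            precision = runif(n, 5, 24),
            channel = sample(channels, n, replace = TRUE),
            n_frames = n_frames)
}
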