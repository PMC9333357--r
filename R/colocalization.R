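# Coordinate-based co-localization index between two channels.
#
# For channel A against B: d_B = sqrt(MNND_B^2 + eps_B^2) is the effective
# resolution of channel B; LD of each B localization is the number of B
# localizations within d_B (zero-distance hits excluded, see below);
# LD_bar_B is their mean; and
#
#   CI_i^A(d_B) = N_{A_i}^B(d_B) / LD_bar_B
#
# with N_{A_i}^B the number of B localizations within d_B of A_i. The
# symmetric definition gives CI_i^B with d_A and LD_bar_A. Per-synapse means
# are arithmetic means over localizations. CI = 1 is the level expected when
# the counted channel is spatially unstructured around the indexed channel.
#
# Zero-distance convention: a point at exactly distance 0 is treated as the
# same physical molecule, so it is excluded from both the within-channel LD
# and the cross-channel numerator. This makes the mean CI of a channel
# against an identical copy of itself exactly 1 and keeps the expectation at
# 1 for spatially independent channels.

#' Effective resolution
#'
#' Quadrature sum of the mean nearest-neighbor distance and the localization
#' error: `sqrt(mnnd^2 + epsilon^2)`.
#'
#' @param mnnd mean nearest-neighbor distance (nm, >= 0).
#' @param epsilon localization error (nm, >= 0); not both zero.
#' @return effective resolution in nm.
#' @export
#' @examples
#' effective_resolution(3, 4)  # 5
effective_resolution <- function(mnnd, epsilon) {
  stopifnot(mnnd >= 0, epsilon >= 0)
  if (mnnd == 0 && epsilon == 0) {
    stop("degenerate input: mnnd and epsilon both zero")
  }
  sqrt(mnnd^2 + epsilon^2)
}

#' Co-localization parameters
#'
#' @param epsilon_a,epsilon_b localization error summary per channel (nm);
#'   `NULL` (default) uses the mean fitted precision of the channel's
#'   localizations within the synapse.
#' @export
coloc_params <- function(epsilon_a = NULL, epsilon_b = NULL) {
  stopifnot(is.null(epsilon_a) || epsilon_a > 0,
            is.null(epsilon_b) || epsilon_b > 0)
  structure(list(epsilon_a = epsilon_a, epsilon_b = epsilon_b),
            class = "coloc_params")
}

#' Coordinate-based co-localization index between two channels
#'
#' @param a,b localization tables ([loc_table()]) or n x 2 coordinate
#'   matrices for the two channels within one synapse; each >= 2 points.
#'   When matrices are given, `params` must carry explicit epsilons.
#' @param params a [coloc_params()].
#' @return list of class `coloc_result`: `ci_a`, `ci_b` (per-localization
#'   indices), `mean_ci_a`, `mean_ci_b`, `d_a`, `d_b` (effective
#'   resolutions, nm), `mnnd_a`, `mnnd_b`, `ld_bar_a`, `ld_bar_b`,
#'   `epsilon_a`, `epsilon_b`.
#' @export
colocalization_index <- function(a, b, params = coloc_params()) {
  pa <- as_points(a); pb <- as_points(b)
  if (nrow(pa) < 2 || nrow(pb) < 2) {
    stop("co-localization needs >= 2 points in each channel")
  }
  eps_a <- params$epsilon_a
  if (is.null(eps_a)) {
    if (!is.data.frame(a)) stop("epsilon_a required for coordinate input")
    eps_a <- mean(a$precision)
  }
  eps_b <- params$epsilon_b
  if (is.null(eps_b)) {
    if (!is.data.frame(b)) stop("epsilon_b required for coordinate input")
    eps_b <- mean(b$precision)
  }
  mnnd_a <- mnnd(pa); mnnd_b <- mnnd(pb)
  d_a <- effective_resolution(mnnd_a, eps_a)
  d_b <- effective_resolution(mnnd_b, eps_b)
  ld_b <- radius_count(pb, d_b, exclude_zero = TRUE)
  ld_a <- radius_count(pa, d_a, exclude_zero = TRUE)
  ld_bar_b <- mean(ld_b)
  ld_bar_a <- mean(ld_a)
  if (ld_bar_b == 0 || ld_bar_a == 0) {
    stop("undefined co-localization index: mean local density is zero")
  }
  num_a <- cross_radius_count(pa, pb, d_b, exclude_zero = TRUE)
  num_b <- cross_radius_count(pb, pa, d_a, exclude_zero = TRUE)
  ci_a <- num_a / ld_bar_b
  ci_b <- num_b / ld_bar_a
  # mean of integer numerators first: a channel against itself gives 1 exactly
  structure(list(ci_a = ci_a, ci_b = ci_b,
                 mean_ci_a = mean(num_a) / ld_bar_b,
                 mean_ci_b = mean(num_b) / ld_bar_a,
                 d_a = d_a, d_b = d_b, mnnd_a = mnnd_a, mnnd_b = mnnd_b,
                 ld_bar_a = ld_bar_a, ld_bar_b = ld_bar_b,
                 epsilon_a = eps_a, epsilon_b = eps_b),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(paste0("<coloc_result> mean CI: A %.3f (d_A %.1f nm), ",
                     "B %.3f (d_B %.1f nm)\n"),
              x$mean_ci_a, x$d_a, x$mean_ci_b, x$d_b))
  invisible(x)
}

#' Nanodomain enrichment of the co-localization index
#'
#' Ratio of the mean CI of localizations inside the given nanodomain regions
#' to the mean CI of localizations outside all of them. A ratio of 1 is the
#' no-enrichment null.
#'
#' @param ci per-localization co-localization indices of one channel.
#' @param inside logical vector: is each localization inside any
#'   other-channel nanodomain boundary (see [in_nanodomain()])?
#' @return list with `ratio`, `mean_inside`, `mean_outside`, `n_inside`,
#'   `n_outside`, and `defined` (FALSE, with `ratio = NA`, when either group
#'   is empty or the outside mean is zero).
#' @export
nanodomain_enrichment <- function(ci, inside) {
  stopifnot(length(ci) == length(inside))
  n_in <- sum(inside); n_out <- sum(!inside)
  if (n_in == 0 || n_out == 0) {
    return(list(ratio = NA_real_, mean_inside = NA_real_,
                mean_outside = NA_real_, n_inside = n_in, n_outside = n_out,
                defined = FALSE))
  }
  mi <- mean(ci[inside]); mo <- mean(ci[!inside])
  if (mo == 0) {
    return(list(ratio = NA_real_, mean_inside = mi, mean_outside = mo,
                n_inside = n_in, n_outside = n_out, defined = FALSE))
  }
  list(ratio = mi / mo, mean_inside = mi, mean_outside = mo,
       n_inside = n_in, n_outside = n_out, defined = TRUE)
}
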