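---
title: "Methods: dual-color SMLM synapse analysis and FRAP with synloc"
author: "synloc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-color SMLM synapse analysis and FRAP with synloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synloc)
```

# Scope and data model

synloc analyzes two-channel single-molecule localization microscopy (dSTORM)
data of synapses — typically a scaffold protein (PSD95) and a receptor
subunit (GluA1) imaged simultaneously — together with the matching widefield
reference images and, separately, FRAP intensity traces. The package starts
from *drift-corrected* localization tables (x, y, frame, photon count,
localization precision, channel; all distances in nm, origin at the image
top-left with y increasing downward). Spot fitting, drift correction and
channel registration are upstream of this package and out of scope.

The central containers are plain data frames with light S3 classes:
`loc_table` (localizations plus acquisition metadata), `widefield_image`
(an intensity matrix with a pixel size), `synapse_record` (an ROI with its
member localizations and PSD geometry), `nanodomain`, `coloc_result` and
`frap_trace`.

# Localization filtering

`apply_quality_filter()` retains a localization iff its precision does not
exceed the per-channel maximum and its photon count lies inside the photon
window. All removals are strict-inequality violations: the defaults remove
precision > 30 nm (GluA1) or > 25 nm (PSD95), photons < 300 or > 30,000, so
a GluA1 localization at exactly 30 nm and 300 photons is retained. These
defaults are the standard operating point for this preparation and are all
configurable through `quality_thresholds()`.

`remove_repeated_localizations()` addresses fluorophore blinking: the same
emitter re-appearing over consecutive frames. Within each channel,
localizations are chained when a record falls within the chaining radius
(default 60 nm) of the chain's most recent member and within `frame_gap`
frames of it (default 1, i.e. strictly consecutive). All chain members after
the first are removed; if the chain persists for more than
`repeat_max_frames` distinct frames (default 10) the initial localization is
removed as well, on the rationale that such long-lived "emitters" are
artifacts. Three conventions here are the package's own, since the procedure
is usually stated without them:

* *Chain linking* uses the distance to the most recent chain member, not the
  chain seed, so a slowly wobbling emitter stays in one chain.
* *Same-frame records* may both join an established chain (two localizations
  in one frame within the radius of a prior member belong to the same
  emitter); a lone pair within a single frame is not "consecutive" and does
  not chain.
* *Chain length* is counted in distinct frames, which equals the member
  count at one localization per frame: a 10-frame chain keeps its seed, an
  11-frame chain loses it.

Removal is deterministic in table order. Applying either filter twice equals
applying it once on data whose emitters are separated by more than twice the
chaining radius; for adversarially dense configurations the
most-recent-member linking rule can in principle leave two surviving records
that a second pass would chain.

# Synapse ROIs

`segment_widefield()` defines synapse ROIs on the widefield reference image
at the full-width half maximum: the image is Gaussian-smoothed (default one
camera pixel), the background is the median of the smoothed image, and every
local maximum higher than `background + min_peak_height` (default 3x the MAD)
seeds one ROI — the marching-squares contour at
`background + (peak − background)/2` that contains the peak. Peaks falling
inside an already-claimed ROI are skipped, which deduplicates plateau
maxima. On an ideal Gaussian spot of width sigma the resulting ROI is a disc
of radius sigma·sqrt(2·ln 2), which the tests verify to within the pixel
discretization.

`assign_localizations()` performs closed-polygon point-in-polygon
assignment (a localization on the boundary belongs to the ROI). Touching or
overlapping ROIs are resolved toward the ROI with the nearest peak, and the
overlap count is logged — how the original analyses separated touching
synapses is not documented anywhere we know of, so this tie-break is the
package's explicit choice.

`select_synapses()` applies the inclusion gate: strictly more than 800
PSD95 and 400 GluA1 localizations, and a PSD area strictly between 0.02 and
0.3 µm². The area bounds are stated in the source protocols as the
disjunction "> 0.02 or < 0.3 µm²", which excludes nothing; the conjunction
is the only reading that filters, and is what the package implements. The
area gate uses the PSD95-cluster area (`psd_centroid()`), falling back to
the ROI area with a message when it is unavailable.

# Nanodomain detection

Per synapse and channel, `detect_nanodomains()` runs:

1. **Local density.** The MNND (mean nearest-neighbor distance) is computed
   within the synapse, and each localization's LD is the number of
   same-channel localizations within a radius of 5 × MNND (boundary
   inclusive). The localization itself is excluded, so an isolated point has
   LD 0 and the threshold reads as a neighbor count.
2. **Thresholding.** Localizations with LD > 40 (strict) are nanodomain
   material.
3. **Grouping.** Kept localizations are grouped by single-linkage
   hierarchical clustering cut at the LD radius. The linkage method and cut
   height are not specified by the source procedure; single linkage at the
   density-support radius was chosen because points within that radius are
   exactly the density-connected ones, and both are configurable.
4. **Subcluster splitting** (`split_nanodomain()`). Peaks are members whose
   LD is maximal within half the peak separation (40 nm) of themselves. Two
   peaks split a group iff both exceed 80% of the group's maximum LD, they
   are more than 80 nm apart, and the minimum LD among members inside a
   40-nm-wide straight corridor between them falls below 30% of the maximum.
   The corridor geometry for the "local minimum" test is the package's
   choice (the rule is usually stated without one); its width is
   configurable. Members are reassigned to the nearest retained peak.
5. **Voronoi boundary.** Each retained group is bounded by the union of its
   members' Voronoi cells, computed against *all* the channel's
   localizations in the synapse and clipped to the synapse ROI (boundary
   cells are otherwise unbounded). Cells are built by nearest-first
   half-plane clipping with an early stop once no remaining bisector can cut
   the cell; the union's outer ring is recovered by cancelling the bisector
   edges shared between member cells.
6. **Retention.** Groups holding fewer than 5% of the synapse's channel
   localizations, or with diameter < 30 nm, are discarded (strict). The
   reported diameter is the equal-area-circle diameter 2·sqrt(area/pi) of
   the Voronoi union; the maximum pairwise member distance is also reported
   (`diameter_max`) since "diameter" is ambiguous in the field.

The PSD center and size come from `psd_centroid()`: DBSCAN over the PSD95
localizations (defaults eps = 5 × MNND, minPts = 5 — unstated in the source
procedure, hence configurable), largest cluster, arithmetic centroid, convex
hull area. `topology_metrics()` reports each nanodomain's distance to the
PSD center and the center-to-center distance to the nearest other-channel
nanodomain, flagged as missing when the other channel has none.

# Co-localization index

For channels A and B within one synapse, the effective resolution of B is
d_B = sqrt(MNND_B² + ε_B²), with ε_B the mean fitted precision of B's
localizations in the synapse (the "localization error" summary; the choice
of the mean is the package's). The co-localization index of an A
localization is

CI_i^A(d_B) = N_i^B(d_B) / LD̄_B,

the number of B localizations within d_B of A_i, normalized by the mean
within-channel LD of B at the same radius; symmetrically for CI_i^B.
Per-synapse means are arithmetic means over localizations. CI = 1 is the
density expected when the counted channel is unstructured around the
indexed one; larger values mean co-enrichment.

**Zero-distance convention.** A point at exactly distance 0 is treated as
the same physical molecule and excluded from both the within-channel LD and
the cross-channel numerator. This is the only convention under which two
desirable properties hold simultaneously and exactly: a channel indexed
against an identical copy of itself has mean CI = 1 (the numerators equal
the LD values pointwise), and spatially independent channels have expected
mean CI = 1 (counting the self-hit instead inflates the normalizer by +1
and biases the CSR mean CI toward LD̄/(LD̄+1)). For real two-channel data
the convention is inert, since cross-channel coincidences have measure zero.

`nanodomain_enrichment()` is the ratio of the mean CI of localizations
inside a set of nanodomain regions to the mean CI outside all of them;
1 = no enrichment. Membership is taken against the *other* channel's
nanodomains in the pipeline. The membership test is exact: a point lies in
the Voronoi union iff its nearest site among the channel's localizations is
a member (no polygon arithmetic involved). Because a uniform channel
produces no detectable nanodomains, the enrichment null is exercised with
fixed membership regions and a uniformly drawn counted channel, under which
the ratio has expectation 1.

# FRAP

`correct_trace()` applies background subtraction and ratio bleaching
correction against an unbleached reference region:
corrected = (roi − bg) · refPre / (ref − bg), with refPre the pre-bleach
mean of the background-subtracted reference. Whether the original analyses
used a reference region or an exponential fit is not documented; the
reference-region ratio is the default here because it is assumption-free
about the bleaching kinetics. `normalize_trace()` maps the pre-bleach mean
to 1 and the first post-bleach frame to 0; `mobile_fraction()` is the mean
of the last four normalized frames (configurable). Each ROI is normalized
independently; per-cell values are ROI means. The whole chain is invariant
to affine rescaling of the raw intensities. `synaptic_enrichment()` is the
background-subtracted ratio of mean synapse-disc to mean shaft-disc
intensity (ten 250-nm discs each by default).

# Synthetic data

The generator provides ground-truth-labeled input for every stage.
`simulate_synapse_pair()` draws emitter positions from a Gaussian-mixture
(nanodomains) plus uniform (background) model; each emitter blinks over a
geometric run of consecutive frames (mean 3; runs beyond 10 frames occur
with positive probability so the long-chain filter branch is exercised),
each localization jittered by its own precision. Defaults emulate the
acquisition regime the analysis targets: 20,000 frames at 50 Hz,
nanodomains of sigma 25 nm with ~300 localizations, precision ~ N(12, 4) nm
truncated positive, log-normal photons with median 2,000 and tails crossing
the 300/30,000 filter bounds, a 300 × 300 nm synapse extent and a
background density of 800 localizations/µm². `simulate_widefield()` renders
a 2-D histogram convolved with a Gaussian PSF (sigma 150 nm on 117-nm
camera pixels by default). `simulate_frap_trace()` builds
M·(1 − e^(−t/τ)) recoveries sampled every 5 min (default M = 0.31,
τ = 8 min, four pre-bleach frames, 30 min post-bleach) and re-applies the
correction pipeline in reverse (reference decay, background, noise).

What the generator does *not* emulate: detector pixelation, structured
(non-uniform) background, emitter re-activation at long lag times, z-drift,
and channel misregistration. Passing tests therefore demonstrate the
correctness of the computations under the stated point-process model, not
robustness to every artifact of real acquisitions.

`simulate_synapse_dataset()` places synapses on a 3-µm grid with the
per-synapse domain counts (2–3 scaffold, 1–2 receptor domains), extents
(280–380 nm) and a raw localization budget of 1,300 per domain so that
typical synapses pass the inclusion gate *after* blink removal — mirroring
the fact that published localization counts refer to filtered tables.

# Pipeline, determinism and problem sizes

`run_pipeline()` composes the stages in protocol order, logs every
threshold actually applied and each stage's in/out/removed counts, and
reports OLS regressions of the per-synapse mean cross-channel nanodomain
distance and the per-synapse mean receptor-channel CI on PSD area — the two
standard size-scaling summaries. Runs are bit-reproducible given the same
config and seed. A thin command-line wrapper
(`inst/scripts/smlmpipe.R`) exposes `simulate`, `filter`, `run` and `frap`
subcommands over these functions.

Numerical choices worth knowing: all threshold comparisons mirror the
strict inequalities of the protocol; radius searches are boundary-inclusive
(distance ≤ d counts); Voronoi ring chaining matches endpoints to 10⁻⁶ nm;
ties in nearest-peak and nearest-site assignments resolve to the lowest
index. Degenerate inputs (one point, no LD-threshold survivors, no DBSCAN
cluster, empty tables) return empty results or typed errors as documented
on each function.

The test-suite simulations are sized to make their statistical guarantees
sharp but cheap: nanodomain recovery uses 100 seeded synapses of 300
localizations per domain, CI discrimination 100 paired simulations, the
enrichment null 200 draws, FRAP recovery 200 traces per mobile fraction,
and the end-to-end determinism check 20 synapses; these are the package's
reference problem sizes and scale linearly if enlarged.
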