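# synloc

Quantitative analysis of dual-color single-molecule localization microscopy
(dSTORM) of synapses, and of FRAP recovery traces.

Super-resolution imaging of endogenously tagged synaptic proteins — a
scaffold such as PSD95 and a receptor subunit such as GluA1 — produces
localization tables: thousands of fitted emitter positions per synapse with
per-localization photon counts and precision. The scientific questions live
at the level of point patterns: do receptor localizations form subsynaptic
*nanodomains*? How are the nanodomains of the two proteins arranged with
respect to each other and to the center of the postsynaptic density (PSD)?
How strongly do the two channels co-localize, and does co-localization
concentrate inside nanodomains? And, from live-cell FRAP experiments, what
fraction of the receptor pool is mobile?

synloc implements this analysis chain for R users:

* **Localization IO and filtering** — delimited localization tables (with
  ThunderSTORM- and DoM-style header dialects), removal of poorly fit
  localizations (precision > 30 nm GluA1 / > 25 nm PSD95, photons outside
  300–30,000; strict inequalities) and of blinking repeats (consecutive
  localizations within 60 nm; chains persisting > 10 frames lose their seed
  too), and 12-nm histogram reconstruction rendering.
* **Synapse ROIs** — full-width-half-maximum segmentation of the widefield
  reference image, point-in-polygon assignment, and the inclusion gate
  (> 800 PSD95 and > 400 GluA1 localizations, PSD area in 0.02–0.3 µm²).
* **Nanodomains** — local density LD at radius 5 × MNND (mean
  nearest-neighbor distance), threshold LD > 40, single-linkage grouping,
  subcluster splitting at multiple density peaks (> 80% of the maximum LD,
  > 80 nm apart, valley < 30%), Voronoi-cell boundaries clipped to the ROI,
  and exclusion of domains with < 5% of the synapse's localizations or
  diameter < 30 nm; PSD center/size from DBSCAN over the PSD95 channel.
* **Co-localization** — the coordinate-based index
  CI_i^A(d) = N_i^B(d) / LD̄_B with d the effective resolution
  √(MNND² + ε²) of the counted channel, per-synapse channel means, and
  nanodomain enrichment (mean CI inside vs outside the other channel's
  nanodomains; 1 = no enrichment).
* **FRAP** — background and reference-ratio bleaching correction,
  normalization (pre-bleach mean → 1, first post-bleach frame → 0), mobile
  fraction as the mean of the last four frames, and synapse/shaft
  enrichment from 250-nm disc ROIs.
* **Synthetic data** — a seeded generator for two-channel synaptic
  localization tables (blinking emitters, 20,000 frames at 50 Hz), matched
  widefield images and FRAP traces, with ground truth echoed back; used by
  the test suite and available for power analyses.

`run_pipeline()` composes all SMLM stages from one config with full
stage-count logging and bit-reproducible outputs;
`inst/scripts/smlmpipe.R` is a small command-line wrapper
(`simulate`, `filter`, `run`, `frap`).

## Worked example

```r
library(synloc)

# one simulated synapse: 2 PSD95 nanodomains, 1 GluA1 nanodomain
sim <- simulate_synapse_pair(synapse_ground_truth(), seed = 7)
sim$a
#> <loc_table> 681 localizations, 1 channel(s): PSD95
#>   acquisition: 20000 frames @ 50 Hz

filt  <- apply_quality_filter(sim$a)
filt$report
#> <filter_report> in 681 -> out 676 (precision -0, photons -5, repeats -0)
blink <- remove_repeated_localizations(filt$table)
blink$report
#> <filter_report> in 676 -> out 222 (precision -0, photons -0, repeats -454)

detect_nanodomains(blink$table)
#> <nanodomain> 53 members (23.9%), center (79, 121) nm, diameter 68 nm
#> <nanodomain> 51 members (23.0%), center (224, 188) nm, diameter 62 nm

colocalization_index(sim$a, sim$b)
#> <coloc_result> mean CI: A 0.562 (d_A 12.6 nm), B 1.021 (d_B 12.7 nm)

frap <- simulate_frap_trace(frap_ground_truth(mobile_fraction = 0.31), seed = 7)
mobile_fraction(normalize_trace(correct_trace(frap$trace)))
#> [1] 0.3227998
```

Reading: the photon filter removed 5 localizations and the blink filter
collapsed 676 localizations onto 222 distinct emitter appearances. Both
simulated PSD95 nanodomains were recovered, each center within a few nm of
its generator mean (truth: (80.7, 121.3) and (219.3, 178.7) nm). The mean
co-localization index of GluA1 against PSD95 (channel B, 1.02) sits at the
chance level 1 for this geometry, while PSD95 against GluA1 is lower (0.56)
because only one of the two PSD95 domains has a GluA1 partner. The FRAP
mobile fraction estimate (0.32) recovers the simulated plateau of 0.31 up
to sampling and noise.

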