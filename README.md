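# ivmotion

Quantification of tumor-cell motility and bone-marrow niche localization
in multichannel intravital two-photon time-lapse imaging.

Intravital imaging of leukemia in the skull bone marrow produces
three-channel movies — tumor cells (green), blood vessels (red), bone
second-harmonic signal (blue) — in which the central biological readouts
are *how much the cells move* and *where they sit relative to bone and
vessels*. `ivmotion` implements that quantification as a tested, fully
reproducible pipeline, together with a synthetic-movie generator with
exact ground truth so every stage can be validated end to end.

## What it computes

* **Displacement-area ratio.** The green-channel MIP frames are pooled
  into one histogram, thresholded once per movie by the Otsu criterion,
  binarized (foreground > threshold) and median-denoised; for successive
  frame pairs the intersection-over-union
  `IoU = |A ∩ B| / |A ∪ B|` is computed and the movie is summarized by the
  mean of `1 − IoU`. Low values mean migration arrest.
* **Mean track speed.** Cells are detected as fixed-scale blobs
  (scale-normalized Laplacian of Gaussian at `σ = D/(2√2)` for diameter
  D = 10 µm, with sub-pixel refinement), linked frame-to-frame by gated
  greedy nearest-neighbour assignment, and each track of ≥ 5 frames
  reports `path length / elapsed time` in µm/min.
* **Distance to niche surfaces.** Bone and vessel channels are segmented
  (Otsu), converted to anisotropic exact Euclidean distance fields (µm),
  and sampled at each detected cell; summaries report mean distances and
  the fraction of cells within 15 µm of bone / 5 µm of vessels.
* **Statistics.** Pooled-variance two-tailed t, one-way ANOVA, two-sample
  Kolmogorov–Smirnov (finite-sample-corrected asymptotic p), and the
  log-rank test — implemented from their formulas and cross-checked
  against independent references in the test suite.
* **Synthetic movies.** Persistent-random-walk cells (motile 1.5 µm/min /
  arrested 0.5 µm/min regimes, hard-core excluded-volume interactions,
  per-frame protrusion lobes) rendered over configurable vessel/bone
  geometry with Poisson noise, plus exponential survival tables — all
  bit-reproducible from one seed.

## Worked example

Simulate a motile (control) and an arrested (treated) cohort, then run
the two motility analyses:

```r
library(ivmotion)

ctrl <- simulation_config(n_cells = 20, regime = "motile",   n_frames = 31, seed = 1)
rx   <- simulation_config(n_cells = 20, regime = "arrested", n_frames = 31, seed = 2)

for (cfg in list(ctrl, rx)) {
  sim    <- simulate_movie(cfg)                     # ground truth + rendered movie
  disp   <- displacement_analysis(sim$movie)        # pooled Otsu -> masks -> 1 - IoU
  spots  <- detect_movie_spots(sim$movie)           # 10 um LoG detection
  gate   <- 3 * cfg$target_speed[[cfg$regime[1]]] * cfg$frame_interval
  speeds <- track_speeds(link_tracks(spots, gate), cfg$frame_interval)
  cat(sprintf("%s: displacement ratio %.3f | mean speed %.2f um/min (n = %d tracks)\n",
              cfg$regime[1], disp$mean_ratio, mean(speeds$mean_speed_um_min),
              nrow(speeds)))
}
```

```
motile: displacement ratio 0.334 | mean speed 1.73 um/min (n = 21 tracks)
arrested: displacement ratio 0.137 | mean speed 0.55 um/min (n = 22 tracks)
```

The arrested cohort shows both the lower displacement-area ratio (its
masks barely change between frames) and a mean speed below the 1 µm/min
boundary that separates active migration from passive displacement for a
10 µm cell, while the motile cohort sits above it. Comparing the
per-track speed distributions:

```r
ks_two_sample(speeds_motile, speeds_arrested)
#> two-sample Kolmogorov-Smirnov: statistic = 1, p = 1.18543e-10
```

The full three-group experiment (untreated / treated / relapse), with 3D
distance analysis and group statistics written as CSV + JSON with a
checksummed manifest, is one call:

```r
groups <- list(untreated = simulation_config(regime = "motile",   seed = 1),
               treated   = simulation_config(regime = "arrested", seed = 2),
               relapse   = simulation_config(regime = "motile",   seed = 3))
run_experiment(groups, "results/")
```

A thin command-line front end with subcommands `simulate`,
`displacement`, `track`, `distance`, `stats` and `run-all` is installed
at `system.file("cli/ivmotion.R", package = "ivmotion")`.

## Package layout

- `R/` — generator (`sim-*.R`), displacement statistic (`iou.R`),
  detection/tracking (`tracking.R`), distance analysis (`distance.R`),
  statistics (`stats.R`), I/O and orchestration (`io.R`, `experiment.R`).
- `tests/testthat/` — unit and property tests per module, brute-force
  oracles (exhaustive Otsu scan, per-pixel median, nearest-voxel distance
  search, pixel-count IoU), and end-to-end acceptance checks.
- `vignettes/ivmotion-methods.Rmd` — models, parameter choices, numerical
  conventions, and limitations.
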