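---
title: "Quantifying leukemia-cell motility and niche localization in intravital imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leukemia-cell motility and niche localization in intravital imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

Intravital two-photon imaging of the bone marrow makes it possible to watch
individual leukemia cells move (or stop moving) through their niche, in
three channels: a cytoplasmic label for the tumor cells (green), an
intravenous vascular dye (red), and the label-free second-harmonic signal
of bone collagen (blue). `ivmotion` implements the downstream
quantification for such movies:

1. a **displacement-area ratio** per movie — one minus the
   intersection-over-union (IoU) of the segmented tumor-cell foreground in
   successive frames — summarizing how much the cell population reshapes
   and translocates between frames;
2. **mean track speeds** from fixed-scale spot detection (cells treated as
   10 µm blobs) and nearest-neighbour centroid linking;
3. **cell-to-niche distances**: anisotropic Euclidean distance fields to
   the segmented bone and vessel surfaces, sampled at each detected cell;
4. the **statistics** these analyses report: pooled-variance two-tailed t,
   one-way ANOVA, two-sample Kolmogorov–Smirnov, and the log-rank test for
   survival tables;
5. a **synthetic movie generator** with exact ground truth, so that every
   stage above can be validated end to end without access to raw imaging
   data.

This vignette explains the models, the defaults and why they were chosen,
the numerical conventions, and the limitations a user should know about.

## The displacement-area ratio

All frames of the green-channel maximum-intensity projection (MIP) are
pooled into a single intensity histogram, and one global Otsu threshold —
the cut minimizing the intra-class intensity variance — is computed per
movie. Pooling is deliberate: a per-frame threshold would absorb
frame-to-frame intensity drift into the masks and confound it with
motility. Foreground is strictly *greater than* the threshold, a
convention stated explicitly so that results are bit-reproducible. The
binary masks are denoised with a square median filter (default 3 × 3; on a
binary image this is a strict-majority vote over the window, clipped at
the image border), and the IoU

$$\mathrm{IoU}_t = \frac{|M_t \cap M_{t+1}|}{|M_t \cup M_{t+1}|}$$

is computed for each successive frame pair. The displacement-area ratio is
$1 - \mathrm{IoU}_t$; a movie is summarized by the mean over its pairs.
Low values mean the foreground barely changes — migration arrest — while
values near 1 mean complete displacement between frames.

Degenerate cases follow fixed conventions: two empty masks have IoU 1
(no cells, no displacement), one empty mask gives IoU 0, and both cases
raise a warning. On a tied Otsu plateau (perfectly separated histogram
classes) the plateau midpoint is returned, so a two-level image thresholds
strictly between its two levels.

The IoU is computed on the *whole* foreground per frame, not per matched
cell: the statistic characterizes collective shape change, and no cell
matching precedes it. Whether the pooled histogram or a temporal
max-projection is the better pooling is genuinely open; the pooled
histogram was chosen because it weighs every frame equally.

## Spot detection and tracking

Cells are detected as blobs at a single fixed scale matched to the nominal
cell diameter $D$ = 10 µm: the image is smoothed with a Gaussian of
physical scale $\sigma = D / (2\sqrt{2})$ (converted to pixels per axis
using the voxel calibration, so anisotropic sampling is handled
correctly), and the scale-normalized negative Laplacian $-\sigma^2
\nabla^2 (G_\sigma * I)$ is computed with physical spacings. Strict local
maxima above a response threshold become centroids, refined per axis by a
three-point quadratic fit (sub-pixel accuracy ~0.02 µm for isolated
cells). Exact response ties — a peak centred on a pixel boundary produces
a two-pixel plateau — are broken deterministically toward the lower linear
index, so each plateau yields exactly one detection. Detection across a
movie uses one movie-global threshold (a fraction, default 0.2, of the
maximum response over all frames) so that detections are comparable over
time.

Tracking is greedy nearest-neighbour assignment between consecutive
frames: candidate links are sorted by distance, with ties broken by
lexicographic coordinate order (making the result invariant to detection
order within a frame), and accepted while both endpoints are free and the
link is shorter than the gate `max_step`. The default gate is three times
the cohort's expected per-frame step; this both bounds the search and
rejects the large jumps produced when two nearby cells transiently merge
into one detection. There is no gap closing and no division handling — the
generator produces neither, and for real data short fragments are the
conservative failure mode. Tracks shorter than 5 frames are excluded from
speed statistics to suppress spurious one-link tracks.

The mean track speed is total path length over elapsed time,
$\sum_t \lVert x_{t+1} - x_t \rVert / (n_\mathrm{steps} \, \Delta t)$,
reported in µm/min. Because the step estimate adds detection jitter in
quadrature, recovered cohort means carry a small positive bias (about
+10–14 % under the default noise model, dominated by cells that pass
within ~12 µm of a neighbour, where the merged intensity profile pulls
both centroids); parameter-recovery tests therefore allow 15 %. Speeds are
invariant to rigid translation of the field.

2D tracking on the MIP is the default for motility analysis; 3D detection
on volumes is used by the distance module. Both are supported because
speed figures in this style of experiment are customarily computed from
the projection while localization requires the volume.

## Distance-to-niche analysis

Bone and vessel channels are segmented by per-channel Otsu thresholding
(optionally keeping only the largest 6-connected component). The occupancy
mask is converted to a **distance field** — for every voxel, the Euclidean
distance in µm to the nearest structure voxel — with a separable
lower-envelope (Felzenszwalb–Huttenlocher) transform run per axis on
squared distances with the axis' physical pitch, so anisotropic voxels
(e.g. 1 × 1 × 2 µm) are handled exactly on the voxel-centre grid.
Distances are unsigned and measured to the occupancy: a cell inside a
vessel lumen is at distance 0. Each detected cell samples the field by
trilinear interpolation at its centroid; spots outside the calibrated
volume are excluded with a counted warning.

Summaries per group report the mean distance, a fixed-width histogram
(default 5 µm bins), and the fraction of cells within a threshold of each
structure — 15 µm for bone and 5 µm for vessels by default, the
thresholds at which bone-marrow localization claims are conventionally
made. Two-group comparisons delegate to the Kolmogorov–Smirnov test.

Two conventions matter when interpreting absolute distances. First,
positions are voxel-centre based: index $i$ sits at $(i - \tfrac12) h$ µm.
Second, because the field measures to occupied voxel *centres* rather than
to the structure's half-voxel-distant face, sampled distances carry a
positive bias of up to half a voxel; at the default 3D sampling of
1 × 1 × 2 µm this is below the cell-position uncertainty and well inside
the ±1 voxel tolerance used in segmentation tests.

## The statistics module

The four tests are implemented directly from their defining formulas and
are cross-checked in the test suite against independent implementations
(`t.test`, `anova`, `ks.test`, `survival::survdiff`):

* **t test**: Student's pooled-variance two-sample t with
  $n_a + n_b - 2$ df, two-sided p. The pooled (not Welch) variant is used
  because the experiments it accompanies report classical t tests. Zero
  pooled variance returns p = 1 for equal means and a flagged p = 0
  otherwise.
* **One-way ANOVA**: $F = \mathrm{MS}_\mathrm{between} /
  \mathrm{MS}_\mathrm{within}$ with $(k-1, N-k)$ df. For $k = 2$,
  $F = t^2$ exactly.
* **Kolmogorov–Smirnov**: $D = \sup_x |\hat F_a(x) - \hat F_b(x)|$ over
  the pooled sample points with right-continuous ECDFs. The p value
  evaluates the asymptotic Kolmogorov distribution at Stephens'
  finite-sample-corrected argument $(\sqrt{n_e} + 0.12 +
  0.11/\sqrt{n_e})\,D$, $n_e = n_a n_b / (n_a + n_b)$; at n = 30 per
  group this reproduces the exact test's rejection behaviour, whereas the
  uncorrected argument under-rejects (size ≈ 0.022 instead of 0.05).
  Note that the two-sample KS test is intrinsically conservative at
  moderate n because D is discrete: even the exact test's true size at
  n = 30/30 and α = 0.05 is ≈ 0.03, and Monte-Carlo size estimates
  fluctuate around that value.
* **Log-rank**: at each distinct event time the observed events in group
  one are compared with their hypergeometric expectation given the risk
  sets; $(\sum O - \sum E)^2 / \sum V$ is referred to $\chi^2_1$. Subjects
  censored at an event time count as at risk at that time; tied event
  times share a risk-table row.

No multiple-testing correction is applied, matching the reporting
conventions of the experiments this package accompanies. Group summaries
emit both mean ± SD and mean ± SEM, labelled, since figure and text
conventions differ.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline is validated.

**Motion.** Each cell performs a persistent random walk in the imaging
plane: the heading is rotated each frame by Gaussian angular noise with
standard deviation $(1 - p)\pi$ (persistence $p$ = 0.7 by default), and
step lengths are Gamma(shape 4) with mean `target_speed × frame_interval`.
The persistent random walk is the standard minimal model for amoeboid
migration; the gamma shape keeps steps strictly positive with realistic
variability. Two regimes are built in: **motile** cells at 1.5 µm/min and
**arrested** cells at 0.5 µm/min, placing the regimes on either side of
the 1 µm/min boundary that separates active migration from passive
displacement for a 10 µm cell. Cells are solid bodies: initial placement
and the walk enforce a hard-core exclusion of one cell diameter in the
imaging plane (a colliding step is deflected through a deterministic
sequence of angles, preserving its length; a fully blocked cell pauses for
that frame). The exclusion acts in-plane, consistent with the planar
motion model, and keeps the true mean speed within ~1 % of the target.
The z coordinate stays at its initial value — cells crawl along vessels
that run parallel to the imaging plane — which makes MIP-measured speeds
agree with the 3D ground truth by construction.

**Geometry.** The bone is a slab occupying $z \le 6$ µm (the imaging
window sits above the bone surface); vessels are cylinders of radius 6 µm
whose axes run parallel to the imaging plane, five of them spaced evenly
across the default 400 × 400 × 40 µm field — a sinusoid density at which
a realistic fraction of cells can sit near a vessel without piling onto a
single tube. Initial positions are drawn so that the realized number of
cells within the configured distance of bone and/or vessel equals
`round(n × fraction)` exactly (default 50 % within 15 µm of bone, 60 %
within 5 µm of vessels); when both constraints are active the joint
counts use the minimal overlap satisfying both marginals.

**Rendering.** The green channel is a sum of quasi-spherical kernels: a
logistic radial profile of radius 5 µm with ~1 µm edge softness, plus a
per-frame protrusion lobe in a random in-plane direction whose amplitude
is drawn up to the regime's `protrusion_amplitude` (2 µm motile, 0.5 µm
arrested). Protrusion perturbs the rendered shape, not the centroid, so
shape activity (which drives the IoU statistic) is partially independent
of translocation (which drives track speeds) — mirroring the biological
distinction between protrusive activity and cell-body movement. The red
and blue channels are blurred occupancy masks of the tubes and slab. Noise
is a constant background (default 10 counts) plus optional Poisson shot
noise on the summed intensity; frames are clipped to the 16-bit range and
integer-valued, which is what makes TIFF round trips bit-exact.

**Calibration defaults.** Frame interval 1 min and 61 frames (a one-hour
movie) — acquisition cadence is a free choice here, not an inference.
Voxels are 2 µm isotropic for MIP motility movies (adequate at the 10 µm
cell scale) and 1 × 1 × 2 µm for 3D localization volumes, matching
typical two-photon in-plane sampling and z-steps; the finer in-plane
pitch also halves the voxel-centre distance bias described above.

**Survival tables.** Exponential event times per group with configurable
hazards, right-censored at end of follow-up.

**Determinism.** All randomness derives from one integer seed; per-cell
sub-streams are derived deterministically, so identical configurations
give bit-identical ground truth, movies, and output files. The
reproducibility contract is tested at the byte level on the full pipeline
output.

**What the generator does not emulate.** Photobleaching, depth-dependent
scattering and excitation falloff, vascular network topology (tubes are
straight and axis-aligned), stromal and immune cells, cell division,
entry/exit through the field boundary, and 3D motion. Consequently,
passing the end-to-end tests shows the *measurement pipeline* is correct
under controlled conditions — it does not certify performance on raw
in-vivo data, where segmentation drift, depth attenuation and crossing
trajectories are harsher.

## Numerical choices and edge cases

* Otsu histograms: integer-valued data use exact integer bins; continuous
  data use 256 equal-width bins. Constant inputs raise a "degenerate
  histogram" error rather than returning an arbitrary threshold.
* Median filter windows are clipped at the border (no padding); ties in
  the even-sized corner windows resolve to background.
* Convolutions are zero-padded; Laplacians replicate the border row, so
  no spurious maxima form at the frame edge.
* The distance transform treats `Inf` background as a large finite
  sentinel (1e30) to keep the lower-envelope recursion well-defined.
* Linking distance ties are broken lexicographically; all orderings in
  output files are deterministic.
* `simulate_tracks` requires at least 2 frames (no displacement is
  definable otherwise) and a positive frame interval.

## Problem sizes used in the test-suite

Unit tests run on small fields (≤ 250 × 250 µm, ≤ 21 frames) and tiny
grids (16³ for distance-transform oracles). The end-to-end
parameter-recovery checks use the full default conditions — 100 cells, 61
frames — for the speed-recovery analysis, five seeded three-regime runs
for the displacement-direction check, and 1000 Monte-Carlo replicates at
n = 30 per group for the statistical-calibration check. The complete
suite runs in about a minute on one CPU.

## Known limitations

* Merged detections: two cells closer than ~12 µm in projection may
  transiently fuse into a single detection; the tracking gate rejects the
  resulting jumps but the affected tracks fragment, and recovered cohort
  speeds retain a ~+10 % bias relative to truth.
* The KS p value is asymptotic (with a finite-sample correction); below
  n = 10 per group it is crude and a warning is raised.
* Distances are voxel-centre based and unsigned; sub-voxel surface
  localization is out of scope.
* The IoU statistic is population-level: it does not attribute shape
  change to individual cells, and no per-cell IoU matching is attempted.
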