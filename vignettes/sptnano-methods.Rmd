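---
title: "Models and methods behind sptnano"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sptnano}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptnano)
```

# Scope

`sptnano` implements the quantitative chain used in sptPALM studies of
plasma-membrane proteins such as the plant Rho GTPase ROP6: simulation
of single-molecule acquisitions with known ground truth, detection and
blinking-tolerant linking of localizations into trajectories, per-track
diffusion estimation with a mobile/immobile classification, Voronoi
nanodomain segmentation, the TIRF/FRET/intensity image readouts, and
the group-comparison statistics used to report them. This vignette
documents the models, the defaults and why they were chosen, and the
known limitations — in particular, what passing the synthetic-data
tests does and does not say about real acquisitions.

# The simulation model

## Trajectories

Molecules perform 2-D Brownian motion in an unbounded plane with
per-axis step variance $2 D \Delta t$; only localizations that fall
inside the square field of view are emitted. The unbounded-plane
choice avoids reflecting-boundary artifacts in MSD statistics at the
cost of letting a few molecules wander out of view (their tracks simply
end, or pause, as in a real acquisition when a molecule leaves the TIRF
footprint).

The mixture is two-population: a molecule is immobile with probability
`f_immobile`, with diffusion coefficients `d_mobile` and `d_immobile`
straddling the conventional 0.01 µm²/s mobility threshold. The
immobile default is 0.001 µm²/s rather than exactly zero so that log-D
histograms remain well defined; exact zero is reserved for analytic
tests.

Photophysics is an explicit per-frame Markov chain per molecule:
*inactive* → (photoactivation, `p_activate`) → *emitting* ⇄ *dark*
(blinking, `p_blink_off` / `p_blink_on`), with an absorbing *bleached*
state reached from the emitting state with probability `p_bleach` per
frame. No published rates exist for mEOS2 in this system; the defaults
(`p_activate` = 0.002, `p_bleach` = 0.05, `p_blink_off` = 0.1,
`p_blink_on` = 0.5) are stated assumptions chosen to give sparse
activation and track lengths of a few tens of frames, matching the
regime the analysis is designed for — they are not measured values.

Acquisition geometry defaults follow the experimental protocol the
package targets: 7000 frames at 30 ms per region of interest, with
isotropic Gaussian localization noise of 20 nm SD. Each reported
position is the true position plus that noise; dark frames emit
nothing. A single RNG stream per run, keyed by `seed`, makes
localization tables byte-reproducible.

What the simulator does *not* model: 3-D diffusion and defocus,
anomalous or confined diffusion, EMCCD gain and read noise beyond
Poisson statistics, drift, and any correlation between mobility and
photophysics. Calibration results on these synthetic data therefore
validate the estimator chain, not the microscope.

## Point patterns

For the tessellation stage the generator emits either complete spatial
randomness (homogeneous Poisson process) or a Thomas-style cluster
pattern: `n_clusters` centres placed uniformly in the region, each with
a Poisson(`points_per_cluster_mean`) number of offspring dispersed by
an isotropic Gaussian of SD `cluster_sigma_um`, over a CSR background.
The centre count is fixed (not Poisson) so that the planted domain
count is an exact, known truth for sensitivity checks; offspring
falling outside the region are discarded (with 40 nm clusters in a
10 µm region the loss is negligible). The default pattern — 30
clusters of ~60 points with σ = 40 nm over a 5 µm⁻² background in
10 × 10 µm — produces nanodomain-like fields of realistic density.

## Rendering

`renderFrames()` draws each localization as a pixel-integrated 2-D
Gaussian PSF scaled to a photon count, over a constant background, with
optional Poisson shot noise. The defaults (σ_PSF = 150 nm, 100 nm
pixels) approximate a 100×/1.46 TIRF setup.

# Detection and linking

`detectSpots()` is a deterministic substitute for interactive TrackMate
detection: difference-of-Gaussians band-pass at (σ, 3σ) of the expected
spot size, strict local maxima above a robust threshold, brightest-first
minimum-separation suppression, and an intensity-weighted subpixel
centroid. Two numerical choices matter:

* **Two-pass background.** The detection threshold is
  `detect_threshold` × MAD above the median of the band-passed frame,
  but in dense frames the spots themselves inflate a naive MAD until it
  reaches the peak level. A first 3-MAD pass flags candidate signal,
  which is dilated by the PSF radius and excluded before the final
  median/MAD estimate. The default `detect_threshold = 8` was
  calibrated on synthetic renders at SNR ≈ 10, where it gives ~95%
  recall at ~1% false positives.
* **Border margin.** The FFT-based blur wraps around image edges, so
  maxima within one filter radius of the border are discarded.

`linkTracks()` performs frame-to-frame assignment, consuming admissible
(track end, localization) pairs globally shortest first — a greedy
scheme that is exact when molecules are well separated and adequate at
sptPALM densities, but deliberately simpler than full LAP tracking (no
splitting/merging, no motion prediction). Dark gaps of up to `max_gap`
frames (default 3, the mEOS2 blinking tolerance used downstream) are
bridged, with the search radius growing linearly as
`max_disp_um`·(gap+1); a √gap alternative is available
(`gap_radius_scaling = "sqrt"`), linear being the more permissive
choice. `max_disp_um` defaults to $3\sqrt{4 D \Delta t}$ for an
expected mobile D of 0.08 µm²/s — the 3-sigma quantile of a diffusive
step. Tracks shorter than 7 steps (8 localizations) are removed by
`filterTracks()` before any diffusion estimate, trading trajectory
count against per-track statistical noise.

On small instances the linker provably matches an exhaustive
minimal-total-displacement assignment (tested); on rendered SNR ≥ 10
fields ~97% of links agree with ground truth.

# Diffusion estimation

For each track the time-averaged MSD uses **all** ordered localization
pairs at each frame lag (overlapping pairs, the standard time-averaged
estimator), with pairs spanning bridged blink gaps contributing at
their true frame difference. Lags with no pairs are skipped, so "the
first four points" of the fit means the four smallest available lags.

The instantaneous diffusion coefficient is the OLS slope of the first
four (τ, MSD) points divided by 4 (2-D motion), with a free intercept:
under Brownian motion with localization noise,
$\mathrm{MSD}(\tau) = 4D\tau + 4\sigma_{loc}^2$, so the intercept
estimates $4\sigma_{loc}^2$ (noisily — at four points its median is
only expected within ~50% of truth). Both the intercept behaviour
(`fit_intercept`) and the dimensionality constant (`msd_dim_factor`)
are configurable, since conventions differ between analysis packages.
Non-positive slopes — common for immobile molecules whose MSD is
noise-dominated — are floored at $10^{-5}$ µm²/s and flagged; floored
tracks are by construction far below the mobility threshold and count
as immobile.

A track is **immobile** when D < 0.01 µm²/s, the conventional
threshold for membrane-protein sptPALM in plants. Histograms of
log₂ D use deterministic bin edges (multiples of the bin width);
whether the original analyses binned in log₂ or merely displayed a
log₂ axis is unknowable from the text, so the base is configurable and
defaults to 2. Bimodality of a mixture is declared when the histogram
has local maxima on both sides of the threshold; a mode must reach 5%
of the tallest bin, which suppresses single-count wiggles in sparse
tails (`histogramModes()`).

Calibration under the default acquisition geometry (500+ tracks of
≥ 20 steps, D = 0.05 µm²/s, σ_loc = 20 nm, Δt = 30 ms): the median
fitted D is within 15% of truth — 4-point fits are slightly biased low
by the noise covariance of overlapping pairs — and per-seed immobile
fractions of two-population mixtures track the simulator's realized
mixture to well under one percentage point.

# Voronoi nanodomain segmentation

Repeated detections of one blinking emitter are first collapsed by
`mergeBlinkingDetections()`: detections within `merge_radius_um`
(default 50 nm) in consecutive or gap-bridged frames (default 3, equal
to the tracking gap tolerance) merge into an intensity-weighted mean
position. Same-frame detections never merge. The defaults follow
SR-Tesseler-style practice; the experimental protocol gives no numbers.

`voronoiDensities()` tessellates the merged positions over a
rectangular analysis region; each cell is clipped to the rectangle so
the clipped areas sum exactly to the region area (verified to 0.1%)
and sparse edge molecules still contribute. The local density of
localization *i* is $\delta_i = 1/A_i$, the inverse of its clipped
polygon area; border-touching cells are flagged for analyses that
prefer to drop them. The reference "average density" is N/region-area
(`avg_mode = "global"`). The alternative mean-of-$\delta_i$
(`"per_point"`) is provided but is a poor segmentation reference: in
clustered fields the dense points dominate the mean, inflating it by
orders of magnitude.

Nanodomain segmentation selects seed localizations with
$\delta_i > f \cdot \delta_{avg}$ (density factor *f* = 50), takes
connected components of the seed set under Voronoi-cell adjacency (the
SR-Tesseler convention for operationalizing a "region of interest"),
and keeps components with at least 25 detections. Domain area is the
sum of member cell areas, size is the equivalent circular diameter
$2\sqrt{A/\pi}$ (no size definition being fixed by the protocol), and
the three per-region metrics are mean equivalent diameter, the
relative number of molecules in domains (Σ detections / N), and domain
density (domains per µm²).

Behaviour at the standard thresholds, measured on the generator's
patterns: CSR fields essentially never produce domains (< 1% of
localizations, typically 0), and Thomas fields recover the planted
domain count within a few percent. One caveat is intrinsic to the
estimator: with $\delta_i = 1/A_i$ and factor 50, only cluster members
within $r^* = \sigma\sqrt{2\ln(\lambda_{peak}/50\,\delta_{avg})}$
(≈ 1.8 σ for the default pattern, i.e. ≤ 81% of members) can exceed
the threshold, so the measured relative molecule count in domains
systematically underestimates the generator's clustered fraction
(≈ 0.57 measured vs ≈ 0.78 planted). This is a property of
hard-thresholded Voronoi segmentation itself, not an implementation
artifact; comparisons between conditions analysed with the same
thresholds remain valid, absolute in-domain fractions do not.

Limitations: regions are axis-aligned rectangles (the clipping window
of the tessellation backend); arbitrary polygons, multi-scale
(second-rank) tessellation and 3-D are out of scope, as are
DBSCAN/Ripley alternatives.

# Image quantification

* `averageStack()` averages the first 100 frames (the standard TIRF
  cluster-density preprocessing; SNR improves by √100, verified on
  synthetic stacks).
* `segmentClusters()` replaces interactive machine-learning
  segmentation with a deterministic pipeline — white-top-hat
  flattening, median + k·MAD global threshold, connected components,
  minimum area. It is validated on synthetic renders (exact count
  recovery at SNR ≥ 8 with subthreshold distractors rejected); no
  claim of equivalence with any trained classifier is made, since
  training labels are unrecoverable.
* `clusterDensity()` counts labels whose centroid falls inside a
  100 × 100 px ROI. The protocol's stated pixel size of "0.102 nm" is
  treated as a units typo for ~0.1 µm, the physically consistent value
  for a 100× EMCCD setup; the pixel size is a free parameter here.
* `fretRatio()` is the plain pixelwise (FRET − bg)/(Venus − bg) with a
  denominator floor and per-ROI means — no spectral bleed-through
  correction, matching ratio-imaging practice for the iROP sensor.
* `meanIntensity()` implements the DHE/ROS readout: background
  subtracted mean over a cell mask. The default background estimator
  is the **histogram mode** of the pixel values, which is unbiased
  when background pixels dominate the image; a low-percentile
  estimator is also provided but sits ~2.3 noise-SDs below the true
  level (a 1st-percentile background under Poisson noise of mean 20
  reads ~10), which visibly compresses fold-changes (1.89 measured
  for a true 2.0). Fold-change accuracy was the deciding criterion
  for the default.

# Statistics

Group summaries report mean ± t-based 95% CI. Group comparisons use
one-way ANOVA with Tukey HSD and a compact letter display computed by
insert-and-absorb: start with one letter column holding all groups;
every significantly different pair splits each column containing both;
columns absorbed by supersets are dropped. Two groups share a letter
**iff** their Tukey-adjusted p ≥ α — verified exhaustively against the
pairwise decisions and cross-checked against an independent
implementation (`multcomp::cld`). Letters are assigned in
decreasing-mean order. α defaults to 0.05 and is configurable per
analysis (published figure captions in this field use both 0.05 and
0.01). Zero-variance degenerate data yield a single shared letter when
identical, exact mean comparisons otherwise. `twoSampleTest()` wraps
the Student (default, matching reported captions) and Welch t-tests;
under a 4-group null the letter display's family-wise error is ≈ α
(0.05 ± binomial CI over 1000 simulated datasets).

Units of replication follow common practice in this literature: cells
are treated as independent units pooled across biological replicates.
The table schema carries replicate ids so a hierarchical analysis can
be bolted on, but none is provided.

# Pipeline and reproducibility

`runPipeline()` orchestrates simulate → link → diffusion + tessellate →
report from a YAML configuration. A single run seed is expanded into
per-stage substreams keyed by fixed labels (`seedForStage()`), so
toggling one stage never perturbs another's randomness. All CSV floats
are written at 9 significant digits, making reruns byte-identical; the
manifest records the configuration hash, the seed and per-file MD5s,
and is itself timestamp-free so identical runs produce identical
manifests. A failing stage leaves a manifest marked `incomplete`.
`makeFixtures()` emits the deterministic toy instances used in the
examples, with expected values computed by brute-force oracles.

Problem sizes used by the packaged checks — 500–600 tracks per
calibration run, 10 seeds for mixture recovery, 100 repetitions of the
20-cell treatment comparison, 20 CSR and 8 Thomas fields, 1000 null
datasets for the letter-display calibration — were chosen so the full
suite characterizes every stage at useful statistical resolution while
remaining comfortably interactive on a laptop.

# Command line

A thin wrapper around the same functions is installed at
`system.file("scripts", "sptnano", package = "sptnano")` with
subcommands `simulate`, `link`, `diffusion`, `tessellate`, `run-all`
and `make-fixtures`; the R functions are the primary interface.
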