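# sptnano

Single-molecule tracking and Voronoi nanodomain analysis of membrane
proteins, in R.

sptPALM (single-particle-tracking photoactivated localization
microscopy) resolves how individual plasma-membrane proteins — such as
the plant Rho GTPase ROP6 during osmotic signaling — diffuse and
cluster into nanodomains. Getting from raw localizations to the
numbers in a figure takes a chain of steps that is usually scattered
across interactive tools: spot detection, blinking-tolerant track
linking, MSD-based diffusion estimation, density-based cluster
segmentation, intensity quantification, group statistics. `sptnano`
packages that chain as tested, scriptable functions, together with a
ground-truthed simulator so every stage can be validated without any
experimental data.

## The core quantities

**Instantaneous diffusion coefficient.** For each track of at least 7
steps (dark blink gaps of up to 3 consecutive frames are bridged), the
time-averaged mean squared displacement over all ordered pairs at lag
τ is fitted on its first four points:

    MSD(τ) = 4 D τ + 4 σ_loc²

so D is the slope/4 and the intercept estimates the localization-noise
floor. Tracks with D < 0.01 µm²/s are classified immobile; the
immobile fraction and the (typically bimodal) log₂ D distribution are
the per-cell readouts.

**Voronoi nanodomains.** Each localization's local density is the
inverse of its Voronoi polygon area, δᵢ = 1/Aᵢ (cells clipped to the
analysis rectangle). Localizations with δᵢ > 50 × the average density
(N/area) seed domains; connected components under Voronoi adjacency
with ≥ 25 detections are nanodomains, reported by equivalent diameter
2√(A/π), relative molecule count and domain density.

**Image readouts.** 100-frame TIRF averages with deterministic
cluster segmentation and counting in a 100 × 100 px ROI; pixelwise
(FRET − bg)/(Venus − bg) ratio maps with per-cell means;
background-subtracted mean gray value for ROS (DHE) imaging.

**Statistics.** Means ± 95% CI, Student/Welch t-tests, and one-way
ANOVA + Tukey HSD with a compact letter display (groups sharing a
letter are not significantly different).

## Worked example

Simulate a two-population acquisition, build tracks, estimate
diffusion, and segment nanodomains from a clustered pattern:

```r
library(sptnano)

## mobile/immobile mixture at the standard acquisition geometry
cfg <- sptSimConfig(n_frames = 25, n_molecules = 600, fov_um = 25,
                    d_mobile = 0.08, d_immobile = 0.001,
                    f_immobile = 0.30, loc_sigma_um = 0.02,
                    p_activate = 1, p_bleach = 0, p_blink_off = 0,
                    seed = 2005)
sim    <- simulateTracks(cfg)
tracks <- filterTracks(trueTracks(sim$localizations), min_steps = 7)
est    <- fitTracksDiffusion(tracks, dt_s = 0.03)
immobileFraction(est, threshold = 0.01)$overall
#> [1] 0.319933
isBimodal(diffusionHistogram(est$d_um2_s, log_base = 2))
#> [1] TRUE

## nanodomain segmentation of a clustered point pattern
pat <- simulatePattern(patternSimConfig(mode = "thomas", seed = 3))
vm  <- voronoiDensities(pat$localizations, region = c(0, 10, 0, 10))
nd  <- segmentNanodomains(vm, tessConfig())   # factor 50, >= 25 detections
nanodomainMetrics(nd, vm)
#>   n_domains mean_diameter_um relative_count domain_density_um2
#> 1        29        0.1350315       0.571304               0.29
```

The simulated field planted 30 clusters; 29 are recovered, covering
0.135 µm equivalent diameter on average, with 57% of molecules inside
domains at a domain density of 0.29 µm⁻². The immobile fraction
recovers the simulated 30% mixture (the remainder reflects the
binomial draw of the mixture itself, not estimator error).

A full configuration-driven run (`runPipeline()`) writes localization,
track, diffusion and nanodomain tables plus a manifest with the seed
and per-file checksums; reruns are byte-identical. A thin CLI with the
same stages is installed at
`system.file("scripts", "sptnano", package = "sptnano")`.

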