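Package: sptnano
Title: Single-Molecule Tracking and Voronoi Nanodomain Analysis of
    Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis chain for sptPALM (single-particle
    tracking photoactivated localization microscopy) studies of plasma-
    membrane proteins. Generates ground-truthed synthetic localization
    data (two-population Brownian motion with photoactivation, blinking
    and bleaching; clustered and completely random spatial point
    patterns; rendered image stacks), detects and links single-molecule
    localizations into blinking-tolerant trajectories, estimates
    per-track instantaneous diffusion coefficients from the first lags
    of the time-averaged mean squared displacement, classifies mobile
    versus immobile populations, segments membrane nanodomains by
    Voronoi-tessellation local density, and quantifies TIRF cluster
    density, ratiometric FRET and background-subtracted intensity,
    with the group-comparison statistics (ANOVA + Tukey compact letter
    display, t-tests, 95% confidence intervals) used to report them.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    deldir,
    igraph,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    digest
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Spatial, CellBiology, Visualization
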