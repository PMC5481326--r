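Package: lightmask
Title: Wavelength-Dependent Light Masking of Vertical Migration in Larval
    Zebrafish: Behavior Tracking and Calcium-Imaging Source Separation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing acute (masking) effects of light on diel
    vertical migration in larval zebrafish, and for decomposing calcium-imaging
    movies into light-evoked response classes. The behavior arm simulates and
    tracks single-larva vertical trajectories over alternating light/dark
    cycles and computes the associated statistical battery: epoch-aligned
    climbing and diving speeds, half-column occurrence rates, inter-individual
    Pearson correlation matrices, Jennrich's chi-square test for equality of
    correlation matrices, Mann-Whitney U tests with rank-biserial effect
    sizes, Kruskal-Wallis tests with Bonferroni correction, confidence bands,
    Shapiro-Wilk checks and photon-intensity conversion. The imaging arm
    performs PCA followed by fixed-point skewness-contrast ICA on movie
    stacks, segments regions of interest from the spatial maps, classifies
    temporal signals against stimulus-locked square and sawtooth templates,
    and registers and averages classified maps across animals. Seeded
    synthetic-data generators (stimulus schedules, drift-diffusion
    trajectories, rendered videos, calcium movies with planted sources) make
    every stage testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Behavior, Visualization
RoxygenNote: 7.3.3
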