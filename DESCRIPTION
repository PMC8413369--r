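Package: fnkit
Title: Projecting Task fMRI onto White Matter Circuits with Tractography Priors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds anatomical connectivity priors (per-voxel or per-region
    probability-of-connection maps) from whole-brain streamline tractograms,
    projects grey-matter BOLD time-series onto white matter circuits as a
    connectivity-weighted average (the "functionnectome" transform), and runs
    simplified activation statistics (double-gamma HRF design, per-voxel OLS,
    group one-sample t, z-transform) plus spatial map-comparison statistics
    (Pearson reproducibility, cross-correlation matrices). Ships a synthetic
    phantom generator (toy brain grid, jittered streamlines, boxcar-times-HRF
    BOLD) so the whole pipeline is testable end to end without any imaging
    download. Reads and writes NIfTI-1 volumes and TRK/TCK streamline files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
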