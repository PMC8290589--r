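Package: ramanpen
Title: Confocal Raman Depth Profiling of Antibody Skin Penetration and
    Anchored Neutralization Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Preprocessing and non-negativity-constrained least-squares
    (NCLS) unmixing of confocal Raman hyperspectral maps of skin
    cryosections, depth profiling of an exogenous tracer species
    (e.g. a single-chain variable fragment versus a full-size antibody),
    and anchored neutralization-percentage analysis of cytokine
    neutralization assays.  Includes Savitzky-Golay smoothing, iterative
    polynomial baseline correction, band-intensity quality filtering,
    cropping and vector normalization; a Lawson-Hanson active-set
    non-negative least-squares solver; depth-profile and
    penetration-depth estimators with replicate aggregation; reporter and
    IL-8 normalization, anchored percent-neutralization tables with
    per-dose summaries and Student's t-tests; and seed-deterministic
    synthetic generators for reference spectra, hyperspectral skin maps
    with known ground truth, and donor-structured assay plates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
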