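Package: rsfpfit
Title: Photoswitching Kinetics and Switching Fatigue of Reversibly
    Switchable Fluorescent Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative characterisation of reversibly
    switchable fluorescent proteins (RSFPs). Computes spectroscopic
    properties (sigmoid pKa titration fits, Ward's-method extinction
    coefficients, Henderson-Hasselbalch extrapolation to the deprotonated
    chromophore, relative quantum yields, scaled molecular brightness),
    extracts fluorescence traces from time-lapse image stacks of colonies
    or cells, globally fits repeated off-switching decays with a shared
    two-emissive-species kinetic model, and models the per-cycle evolution
    of the two species under light-driven interconversion and
    photodestruction, including switching-fatigue metrics. A seeded
    synthetic-data generator emulates colony and live-cell photoswitching
    experiments so the whole pipeline can be exercised and validated
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    minpack.lm,
    igraph,
    EBImage,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
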