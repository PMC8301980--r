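Package: hydrasense
Title: Hydration Sensing of Lipid Membranes from FRAP Lateral Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the hydration state of supported lipid bilayers from
    fluorescence recovery after photobleaching (FRAP). Fits normalized recovery
    curves of a uniformly bleached circular spot with the Soumpasis model to
    obtain lipid lateral diffusion coefficients, builds monotone calibration
    curves of diffusion coefficient against relative humidity, and inverts them
    through literature anchors to report the number of water molecules per
    lipid head group. Includes trace extraction and double normalization for
    confocal image stacks, and a synthetic FRAP generator (analytic traces and
    full 2-D image stacks evolved by spectral diffusion) so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
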