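Package: dkisubsample
Title: Gradient-Scheme Subsampling Effects in Diffusional Kurtosis Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Design and reorder multi-shell diffusion-MRI gradient schemes
    for interruption-robust acquisition, simulate crossing-fiber diffusion
    signals with Rician noise, fit the diffusional kurtosis imaging (DKI)
    model by weighted and positivity-constrained least squares, derive the
    seven standard DTI/DKI scalar parameters, summarize scalar maps with
    normalized-histogram characteristics, and quantify the parameter bias
    introduced by truncating an acquisition under electrostatic-repulsion,
    spherical-code and random volume orderings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    quadprog,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    RNifti,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
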