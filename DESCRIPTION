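Package: gatingspring
Title: Gating-Spring Analysis of Hair-Bundle Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Biophysical analysis of mechanoelectrical transduction in
    sensory hair cells. Fits the gating-spring force-displacement model to
    hair-bundle recordings and extracts the gating force, gating swing and
    linear stiffness; reduces triangular-stimulus recordings to averaged
    force-displacement cycles to quantify gating friction and the channel
    activation time; analyses spontaneous-oscillation traces with
    double-Lorentzian spectra and bimodal position histograms; characterises
    the transepithelial RC circuit; and runs ensemble regressions, paired
    tests, hysteretic state-transition detection and 10-90% kinetics. A
    built-in simulator of hair-bundle mechanics under flexible-fiber
    stimulation generates every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mclust,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
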