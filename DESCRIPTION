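Package: mriwater
Title: Two-Point Quantitative MRI Mapping of Water Content, T1 and T2*
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Voxel-wise quantitative mapping of free water content (H2O),
    longitudinal relaxation time (T1) and effective transverse relaxation
    time (T2*) from two spoiled multi-echo gradient-echo acquisitions at
    different flip angles, with transmit-field (B1+) mapping from an
    actual-flip-angle-imaging (AFI) acquisition, receive-field (B1-) bias
    estimation, and calibration of magnetisation density to 100 percent
    water using ventricular cerebrospinal fluid.  Includes a forward
    signal simulator with digital tube and brain phantoms, Monte Carlo
    optimisation of the flip-angle pair, and tissue-level evaluation
    statistics, so that every processing stage can be validated by
    parameter recovery on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
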