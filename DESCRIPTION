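Package: bbbdmap
Title: Quantifying Blood-Brain Barrier Dysfunction from Dynamic
    Contrast-Enhanced MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Voxelwise quantification of slow blood-brain barrier leakage
    from dynamic contrast-enhanced MRI. Implements variable-flip-angle
    (DESPOT1) T1 mapping, spoiled-gradient-echo signal-to-concentration
    inversion, late-window linear leakage-slope fitting with superior
    sagittal sinus normalization, control-referenced percentile
    thresholding with regional modified z-score classification against a
    124-region atlas, group-level nonparametric statistics with
    Benjamini-Hochberg correction, and a fully deterministic synthetic
    cohort generator for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
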