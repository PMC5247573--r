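Package: rcpscope
Title: Digital Counting and Genotype Scoring of Rolling-Circle Products in
    Mobile-Phone Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detection, machine-learning classification and digital counting
    of rolling-circle amplification products (RCPs) in multi-frame,
    multi-channel fluorescence micrographs such as those produced by
    mobile-phone microscopes. Provides frame averaging, Gaussian denoising
    and phase-correlation channel co-registration; white top-hat spot
    enhancement with size and intensity gating; a 14-feature random-forest
    classifier separating true RCPs from auto-fluorescent artifacts;
    sequencing-by-ligation base calling with anchor gating and double-stain
    rejection; pooled mutant/wild-type genotype scoring against a ratio
    threshold; and dilution-series regression for digital quantification.
    A built-in synthetic micrograph generator with per-object ground truth
    makes every stage testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    randomForest,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
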