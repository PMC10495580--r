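Package: specqc
Title: Automated Quality Control of 3D MRSI Voxel Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quality-control classification of short-echo brain MR
    spectroscopic imaging (MRSI) voxel spectra. Provides the preprocessing
    chain (real-part extraction, ppm-window cropping, z-normalization),
    two-rater consensus labeling, a synthetic Lorentzian-lineshape cohort
    simulator with controllable artifact severity, five classifier variants
    (random forest on raw spectra, a 6-layer 1D convolutional network, an
    inception 1D network, and the two hybrids that feed 64-node penultimate
    deep features into a random forest), subject-grouped cross-validation
    schemes, ROC-AUC / precision-recall-AUC / accuracy evaluation with
    lesion-subset reporting, and integrated-gradients attribution for the
    network models.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rhdf5,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
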