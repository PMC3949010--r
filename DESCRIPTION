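Package: vertefem
Title: Voxel Finite-Element Stiffness Prediction for Fractured and
    Augmented Vertebrae
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Specimen-specific, image-based finite-element pipeline for
    traumatically fractured and cement-augmented vertebral bodies.
    Provides synthetic voxel phantoms with ground-truth component masks
    and simulated axial compression tests; partial-volume down-sampling,
    threshold segmentation, morphological fracture-gap extraction and
    fracture-severity grid scoring; a linear-elastic voxel-hexahedral
    finite-element solver for axial stiffness under a tilting rigid
    plate; grayscale-to-modulus conversion-factor calibration and
    validation, fracture-gap modulus sensitivity, and virtual cement
    augmentation (swap) studies; plus the accompanying agreement and
    group statistics (one-way ANOVA, Tukey-Kramer, unpaired t test,
    Pearson correlation, Lin's concordance, Bland-Altman).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    RNifti,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
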