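Package: uexm
Title: Quantitative Measurement of Expanded Centrioles from
    Ultrastructure Expansion Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measurement toolkit for ultrastructure expansion microscopy
    (U-ExM) of centrioles. Extracts line profiles from multi-channel
    projected images, detects half-maximum signal extents with sub-pixel
    interpolation, measures centriole lengths and diameters with gel
    expansion correction, estimates the procentriole length at which a
    marker is first recruited, quantifies centriolar fluorescence in
    thresholded or square regions with background subtraction and
    internal-control normalization, models centriole inheritance through
    spermatogonial cyst divisions under duplication failure, and provides
    exact Wilcoxon rank-sum and Fisher tests built from first principles.
    A synthetic image generator with known ground truth supports
    end-to-end validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
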