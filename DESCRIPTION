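Package: virtustain
Title: Virtual Staining of Autofluorescence Microscopy: Rendering, Registration QC, Training Losses, and Quantitative Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for developing and evaluating label-free virtual
    staining of hyperspectral tissue autofluorescence. Provides an
    invertible Beer-Lambert pseudo-immunohistochemistry (pIHC) renderer
    between multiplex immunofluorescence (mIF) channels and brightfield
    RGB; normalized-gradient-field registration quality control with a
    micrometre-scaled local warping score; weighted shift-invariant
    regression and adversarial losses with a compact U-Net stainer
    trained natively in R; threshold-based mIF quantification (cell
    segmentation, marker positivity, TPS and CPS, colocalization) under
    multiple region-of-interest definitions; and real-versus-virtual
    concordance statistics (Dice overlap with category merging, Pearson
    correlations with Fisher confidence intervals). A synthetic tissue
    phantom generator with full ground truth makes every stage testable
    without access to clinical slides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
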