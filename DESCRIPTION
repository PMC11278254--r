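Package: segupgrade
Title: Upgrading Low-Quality Cell Segmentation Annotations with
    Perturbation-Trained Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enlarges cell-segmentation training sets at low annotation cost
    by modelling annotation errors as formal perturbations of instance label
    maps (omission of cells, inclusion of non-target objects, and biased
    boundary delineation) and training an upgrade network that maps an image
    paired with a low-quality label to its high-quality counterpart.
    Upgraded labels then augment a small well-annotated set for training a
    final segmentation network. Includes a seeded synthetic microscopy
    generator with two cell populations, an encoder-decoder network with
    Dice loss implemented from first principles, a thresholding baseline, an
    annotation-cost model, and experiment drivers for capacity, perturbation
    mismatch, degraded-reference, and cost trade-off studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
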