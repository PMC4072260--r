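Package: fibroquant
Title: Digital Quantification of Myocardial Fibrosis on Trichrome-Stained Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three independent estimators of the collagen area fraction on
    Masson's-trichrome myocardial tissue images and the agreement statistics
    battery to compare them. Implements colour-deconvolution stain
    colocalization (optical-density unmixing, per-pixel stain-combination
    classification and an eight-colour markup), a trainable per-pixel tissue
    classifier using colour and local texture features, and systematic
    point-grid stereology with the Weibel point-counting uncertainty as the
    reference method. A synthetic-histology generator renders trichrome-like
    tiles with known per-pixel ground truth so the whole pipeline can be
    validated end to end, and the statistics module provides summary tables,
    Pearson correlation, the Friedman test with Wilcoxon signed-rank post-hoc
    comparisons under Bonferroni correction, raw and log-transformed
    regression, and Bland-Altman limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    nnet,
    png,
    tiff,
    jsonlite,
    yaml,
    withr,
    ggplot2,
    rlang,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
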