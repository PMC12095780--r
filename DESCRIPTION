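Package: gisegnet
Title: Segmentation and Hybrid Classification of Gastrointestinal Endoscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting gastrointestinal abnormalities in endoscopy
    images. Implements the GISegNet encoder-decoder segmentation network built
    from asymmetric and atrous convolution primitives, Encoder-Decoder-Residual
    (EDR) blocks and the Efficient Hybrid Attentional Atrous Convolution
    (EHAAC) module, together with a CPU training harness, pixel-level
    segmentation metrics, and a hybrid classification pipeline that fuses
    transformer-style feature sets, selects features by minimum-redundancy
    maximum-relevance (mRMR) ranking, and classifies with a cubic-kernel
    support vector machine. Synthetic endoscopy-like image/mask and feature
    generators make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    e1071,
    jsonlite,
    png,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    EBImage,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
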