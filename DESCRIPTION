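Package: ofml
Title: Online Fusion Mutual Learning for Histopathology Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual-branch image classification for H&E-stained histopathology:
    a residual convolutional branch for local nuclear morphology and a
    multi-view transformer branch with cross-view attention for global tissue
    context, trained jointly by online fusion mutual learning. An ensemble
    classifier (mean of branch logits) and an adaptive fusion classifier
    (pooled-and-concatenated intermediate feature maps through a pointwise
    convolution) exchange temperature-softened probability distributions with
    both backbones via Kullback-Leibler losses. Includes a reverse-mode
    automatic-differentiation core, Mixup training-set expansion, a synthetic
    histology-like image generator so the whole pipeline runs without
    downloads, readers for class-per-directory datasets, evaluation metrics,
    Grad-CAM heatmaps, 2-D feature embeddings, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    MASS,
    stats,
    utils,
    grDevices,
    tibble,
    ggplot2,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster,
    withr
Config/testthat/edition: 3
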