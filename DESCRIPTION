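Package: GaborDBN
Title: Gabor-Filtered Biomedical Image Classification with Deep Belief
    Networks Tuned by an Enhanced Grasshopper Optimizer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for two-class biomedical image
    classification built around oriented texture. Images are denoised and
    enhanced with a bank of complex Gabor filters applied by spatial
    correlation, summarised into fixed-length feature vectors by pooled
    filter-bank statistics (with an optional adapter for pretrained
    convolutional backbones), and classified by a deep belief network of
    stacked restricted Boltzmann machines pretrained with contrastive
    divergence and fine-tuned by backpropagation. Network hyperparameters
    are tuned by a grasshopper optimization algorithm enhanced with
    opposition-based learning. Includes a deterministic synthetic
    two-class texture generator, stratified split evaluation with
    confusion matrices, per-class and macro-averaged metrics, and ROC and
    precision-recall curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    png,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
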