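Package: crynet
Title: Infant Cry Classification with Mixed MFCC Features and an SE-ResNet-Transformer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short infant cry recordings into hungry, uncomfortable and
    pain categories. Implements the full signal chain from WAV input to prediction:
    pre-emphasis, overlapped framing, Hamming windowing, Mel filterbank energies and
    a mixed Mel-frequency cepstral coefficient (MFCC) feature combining static
    cepstra with first- and second-order differential coefficients; a hybrid neural
    network that couples a squeeze-and-excitation multiscale residual convolution
    block with spatial pyramid pooling and a stack of transformer encoders, trained
    by mini-batch Adam with categorical cross-entropy; macro-averaged evaluation
    metrics; an ablation harness over the attention/residual/multiscale design
    choices; and a deterministic generator of class-separable synthetic cries so the
    whole pipeline is testable without access to clinical cry corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
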