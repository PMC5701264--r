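Package: rewnpls
Title: Recursive Exponentially Weighted N-Way Partial Least Squares for
    Streaming Tensor Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online multilinear (tensor) regression for adaptive neural
    decoders and other streaming applications. Implements recursive
    exponentially weighted N-way partial least squares (REW-NPLS): paired
    observation tensors arrive in batches, exponentially weighted covariance
    tensors and running moments are updated under a forgetting factor, and the
    full stack of intermediate models (1..F_max latent factors) is re-extracted
    by a covariance-only kernel recursion with warm-started rank-one PARAFAC
    projectors. The number-of-factors hyper-parameter is selected online by
    recursive validation: every incoming batch first scores all intermediate
    models, then updates them. Also provides complex Morlet wavelet
    time-frequency feature extraction for multichannel signals (frequency x
    time x channel epochs), modality-influence summaries of fitted coefficient
    tensors, and a ground-truth synthetic stream generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    generics,
    tibble,
    withr,
    ggplot2,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
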