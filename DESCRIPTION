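Package: neuromod
Title: Neuromodulation-Inspired Learning Rules, Plastic Traces, and
    Fixed-Point Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learning systems modelled on the neuromodulatory circuit of the
    insect mushroom body. Provides the ModNet shallow classifier (a fixed
    random projection whose hidden-to-output plasticity is gated by an
    error-driven modulatory layer), region-based attention with activity
    pruning and a compartmentalized two-hidden-layer variant with a slow
    covariance rule, a differentiable modulatory-trace readout for N-way
    K-shot episodic learning on top of a small convolutional embedding, and
    fixed-point (Q6.10) inference with a piecewise-linear tanh. Includes
    synthetic generators for separable vector tasks and procedural glyph
    banks so every method is testable offline, plus IDX and image-folder
    readers for the standard benchmark formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
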