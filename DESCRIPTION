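Package: mcfholo
Title: Tailored Computer-Generated Holography for Multi-Core Fiber Phased Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generation and evaluation of phase-only computer-generated holograms
    (CGHs) for randomly distributed multi-core fiber (MCF) phased arrays, as used
    in lensless holographic microendoscopy. Implements a differentiable band-limited
    angular spectrum propagation engine, a fiber-bundle facet model (core-map
    synthesis, per-core phase sampling, circular-mask rendering, simulated
    optical-path-difference distortion with digital phase conjugation), the
    Gerchberg-Saxton and core-constrained Gerchberg-Saxton iterative baselines, an
    unsupervised convolutional phase-encoder network trained end-to-end through the
    physical model with a negative Pearson correlation loss, synthetic glyph and
    binary-pattern target generation, and a correlation-coefficient evaluation
    harness for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    tiff,
    withr,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
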