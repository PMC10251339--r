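Package: triweight
Title: Source Data Reweighting for Transfer Learning by Three-Level
    Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns per-example importance weights for an auxiliary
    (source) image domain used in transfer learning, by nesting three
    optimization stages: importance-weighted source training,
    ranking-based knowledge transfer through cross-domain relative
    similarity (CDRS) with a pairwise hinge penalty, and hypergradient
    descent of the target model's validation loss with respect to the
    weights, realized through one-step virtual updates and
    finite-difference Hessian-vector products. Includes a synthetic
    two-domain image generator with ground-truth corruption masks,
    classification metrics, reweighting diagnostics and command-line
    entry points for reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
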