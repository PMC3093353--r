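Package: epistinfer
Title: Quantitative Epistasis Analysis and Signal-Responsive Pathway Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers the order, architecture and quantitative influences of
    genes acting in signal-responsive pathways from replicate trait
    measurements of wildtype, single- and double-deletion genotypes in two
    signal states. Deletion effects and genetic-interaction terms are
    estimated by saturated multilinear regression on log-transformed traits;
    signal-dependent (masking) epistasis identifies which gene is downstream;
    a Boolean forward model over sixteen hypothetical pathway architectures
    supplies the predicted effect patterns used to match architectures and to
    solve for signal-specific and basal influence parameters. Pairwise
    inferences are assembled into a signed directed network, simplified by
    transitive reduction, and benchmarked against a gold standard via
    TPR/FPR threshold sweeps. A synthetic-data generator reproduces the
    factorial deletion-experiment design for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
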