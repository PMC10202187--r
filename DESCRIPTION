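Package: hopscape
Title: Hopfield Energy Landscapes of Cellular Differentiation Potency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies cellular differentiation potency from gene expression
    matrices with a Hopfield attractor network. Expression profiles are
    z-scored, reduced to highly variable genes and binarized into gene states;
    each cell (or phenotype group) is stored as an attractor via the Hebbian
    rule and scored by its Hopfield energy, a proxy for Waddington landscape
    elevation. The package also models cell-state transitions: asymmetric
    couplings between an old and a new cell state, cell-automaton updates with
    a simple-matching importance score for driver genes, a step-decomposed
    mixing ladder that traces per-step transition energies, robustness scans
    under gene-subset and expression-permutation perturbations, and PC1-energy
    landscape fits. A stage-structured synthetic data generator makes the full
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
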