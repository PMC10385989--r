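Package: pampalfer
Title: Characterization and Comparison of PAMPA Membranes via the
    Abraham Solvation Parameter Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to characterize parallel artificial membrane
    permeability assay (PAMPA) systems and compare them with biological
    permeation and partition processes.  Computes effective permeability
    from raw donor/acceptor concentration measurements, including the
    iterative solution required under gradient-pH conditions; fits the
    Abraham solvation parameter model (a linear free-energy relationship
    in the solute descriptors E, S, A, B, V) by multiple linear
    regression with the standard diagnostics; and quantifies
    inter-system similarity through the D-prime Euclidean distance over
    the fitted coefficients, with hierarchical clustering and principal
    component analysis of the coefficient vectors.  A synthetic-data
    generator provides solute sets and simulated plate reads with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
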