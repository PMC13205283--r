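Package: orthoglue
Title: Quantum Logic by Gluing Boolean Algebras and Inverse Bayesian Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs finite Boolean algebras and glues them at shared least
    and greatest elements, certifying by exhaustive scan that the result is an
    orthomodular, non-distributive lattice (quantum logic) with witness
    extraction and Hasse-diagram export. Implements online Bayesian prior
    updating combined with inverse Bayesian likelihood rewriting for
    prediction in nonstationary binary environments, including free-energy and
    Kullback-Leibler accounting, cumulative mean squared error, and
    moving-average smoothing. A bridge renders a hypothesis model as a glued
    lattice and logs likelihood rewrites as sub-Boolean-algebra replacements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
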