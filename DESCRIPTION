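Package: figp2
Title: Interpretable QSAR Models by Filter-Introduced Genetic Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Symbolic regression for quantitative structure-activity
    relationship (QSAR) modelling by genetic programming over expression
    trees. Constant terms are refined by nonlinear least squares at every
    fitness evaluation. Candidate expressions are screened by structural
    filters (single variable occurrence, no nesting within operator
    groups), a sample-based domain filter, and an optimization-based
    domain filter that certifies the expression's range over a descriptor
    box. A perturbation-based stability penalty on descriptors and
    coefficients regularizes the fitness to discourage overfit
    expressions. Includes a synthetic ground-truth data generator and a
    benchmarking harness against mean-predictor, linear-regression and
    RBF-kernel support-vector-regression baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    ChemmineOB,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
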