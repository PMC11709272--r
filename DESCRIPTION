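Package: semdag
Title: Two-Stage Order-Based Learning of Directed Acyclic Graphs for
    Linear Structural Equation Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns directed acyclic graphs (DAGs) from observational data
    under a linear structural equation model with equal error variances,
    using a two-stage order-based search. Stage one derives a vertex or
    layer ordering of the variables, either from a prior knowledge graph
    (topological vertex or layer ordering via iterative leaf removal) or
    data-driven bottom-up by repeatedly estimating a penalized precision
    matrix with the graphical lasso and peeling off the node with the
    largest full conditional variance. Stage two estimates each node's
    parent set by weighted L1-penalized regressions restricted to the
    ordering. Includes an equal-variance SEM simulator with closed-form
    population covariance, evaluation metrics (structural Hamming
    distance, Matthews correlation coefficient, path-coefficient
    prediction), file import/export for graphs and data matrices, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
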