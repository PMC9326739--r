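Package: serocurve
Title: Generalized Logistic Modelling of Antibody-Antigen Titration Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits four-parameter logistic (4PL), five-parameter logistic
    (5PL) and generalized logistic (Richards) models to antigen-titration
    immunoassay curves by bounded nonlinear least squares, and converts the
    fitted parameters into thermodynamic descriptors of polyclonal serum
    antibody binding: the antigen concentration at the inflection point
    (an apparent equilibrium dissociation constant), the standard chemical
    potential of binding, and the limiting thermodynamic activity
    coefficient of the antigen (the reciprocal of the Richards asymmetry
    exponent), a readout of the clonal heterogeneity of the bound antibody
    pool. Includes a simulator of mono- and polyclonal binding equilibria
    (independent-site Langmuir and shared-epitope competitive mass balance)
    for validating the interpretation of the fitted parameters, plus
    delimited-text input/output and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
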