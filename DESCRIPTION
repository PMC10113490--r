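Package: atheromech
Title: Inverse Estimation of Atherosclerotic Plaque Stiffness from
    Deformation Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: In-silico workflow for predicting the Young's moduli of an
    atherosclerotic plaque's lipid-rich core and fibrotic tissue from
    deformation features of pressurized 2D artery cross-sections.
    Builds idealized and synthetic-realistic plaque geometries, solves
    quasi-static plane-strain hyperelastic inflation (incompressible
    neo-Hookean core/plaque, Gasser-Ogden-Holzapfel media/adventitia)
    with a finite element solver verified against a closed-form
    layered-cylinder solution, assembles factorial feature/target
    databases (finite element or calibrated surrogate backend), selects
    regression inputs by p-value stepwise selection with a variance
    inflation factor audit, trains a deep multilayer perceptron with an
    Adam milestone learning-rate schedule, and adapts it to realistic
    geometries by fine-tuning the last network layers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
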