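Package: greymulti
Title: Multivariate Grey Forecasting Models GM(1,N) and NLS-TNGM(1,N)
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate grey forecasting for short, positive-valued time
    series with driving variables. Implements the linear GM(1,N) model with
    least-squares parameter estimation covering all three rank cases, the
    nonlinear TNGM(1,N) model with per-driver power exponents, and a
    nonlinear least-squares estimator realized as block Gauss-Seidel
    coordinate descent (with a Levenberg-Marquardt cross-check solver).
    Includes the grey generating transforms (initialization, first-order
    accumulation and its inverse, nearest-neighbour background values),
    in-sample and out-of-sample fitted-value conventions, MAPE-based model
    comparison, descriptive trend classification, a synthetic data
    generator for parameter-recovery testing, and a small command-line
    interface. Ships the China 1996-2015 pollutant-versus-GDP dataset used
    as the reference fixture.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
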