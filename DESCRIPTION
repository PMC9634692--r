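Package: glykin
Title: Kinetics of Non-Enzymatic RNA Copying from Aminoacylated Primers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Kinetic analysis of non-enzymatic RNA primer extension and
    template-directed ligation initiated from 2'(3')-aminoacylated RNA
    primers. Implements a three-species competing-pathway pseudo-first-order
    model with closed-form solutions, log-linear estimation of observed rate
    constants and half-lives from gel-band densitometry time courses,
    single-parameter nonlinear estimation of the aminoacyl extension rate
    with Monte Carlo uncertainty propagation, the censoring rule for
    unresolved ligation product bands, lane normalization of band-intensity
    tables, and a synthetic gel-data generator so every estimator is
    testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
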