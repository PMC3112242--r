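Package: recurbreak
Title: Recurrent Copy-Number Breakpoint Detection by Bayesian Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic segmentation of array-CGH copy-number profiles with a
    Bayesian change-point model, exact posterior sampling of breakpoint
    sequences by dynamic programming and stochastic backtrace, and detection of
    breakpoints recurring across individuals at probe, interval (gene) and
    pair-of-interval resolution using a binomial order statistic with
    Benjamini-Hochberg false discovery rate control. Recurrent calls are
    classified into structural variants, gene truncations and fusion genes,
    filtered against catalogues of known germline variants and matched-normal
    cohorts, and ranked by copy-level concordance across the fusion point.
    Includes a synthetic-cohort generator with planted events for calibration
    and power studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
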