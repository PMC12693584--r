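Package: syndfe
Title: Selection on Synonymous Variants and Its Impact on Demographic and
    DFE Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation with linked selection and a
    Poisson random field inference stack for studying how purifying
    selection on synonymous mutations biases site-frequency-spectrum (SFS)
    based demographic inference and, downstream, the inferred gamma
    distribution of fitness effects (DFE) of nonsynonymous mutations.
    Includes an SFS container with diversity summaries (pi, pi/pi0) and
    "fs" text file interchange, expected-SFS engines under one- and
    two-epoch demographies with genic selection, multi-start maximum
    likelihood fitting with likelihood-ratio model choice, gamma-DFE
    inference conditioned on a fitted demography, and an experiment
    orchestrator reproducing the false-expansion artifact and its rescue
    by conditioning on a truly neutral demography.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
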