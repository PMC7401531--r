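Package: ncountr
Title: NanoString nCounter Lane QC, Normalization, Repeated-Measures
    Differential Transcription and Power Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tidyverse-native pipeline for nCounter gene-expression
    studies with repeated measures. Reads and writes RCC lane files,
    applies the four default lane quality-control checks (imaging,
    binding density, positive-control linearity, limit of detection),
    performs background minimisation and positive-control plus
    reference-gene normalization, fits per-gene generalized
    least-squares models with AR1 within-animal correlation by REML
    (group, time, group-by-time fixed effects with a baseline
    covariate), reports least-squares means and contrasts, and provides
    exact noncentral-t power and sample-size calculations for
    two-sample and paired designs. Includes a synthetic RCC data
    generator with known ground truth for a two-group by
    three-timepoint longitudinal design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    nortest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    readr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
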