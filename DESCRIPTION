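Package: prefmap
Title: Comparative-Judgment Preference Measurement and Unfolding Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring implicit and explicit preferences from
    comparative-judgment tasks in which briefly presented primes bias the
    choice between neutral targets (the affect-misattribution family of
    measures). Provides schedule builders for pairwise-choice and
    single-prime judgment tasks, latency filtering and proportion-based
    preference scoring, repeated random split-half reliability with
    Spearman-Brown correction, metric multidimensional unfolding of
    participant-by-stimulus preference-count matrices by stress
    majorization, bias-reduced (Firth) logistic and linear feature axes
    with orthogonal projection scores, and a generative simulator of
    misattribution-based choice behavior with known ground-truth attitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
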