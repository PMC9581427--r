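Package: cueddm
Title: Drift-Diffusion Modelling of Rule- and Stimulus-Cued Auditory Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint choice and response-time analysis of auditory
    frequency discrimination under rule-based and stimulus-based
    expectations. Implements a generalized drift-diffusion model with a
    linearly collapsing bound, cue-dependent starting-point and
    evidence-accumulation biases, an SNR-dependent adaptation term driven
    by recency-weighted tone history, and a lapse mixture; a
    Crank-Nicolson first-passage-time solver; maximum-likelihood fitting
    of a lattice of nested model variants by differential evolution;
    cohort-level model comparison by information criteria and
    random-effects Bayesian model selection (protected exceedance
    probabilities); lapse-limited logistic psychometric models;
    DDM-predicted performance landscapes over bias pairs; and a
    pupillometry pipeline (artifact cleaning, epoching, two-stage
    time-course contrasts with FDR control), exercised on seedable
    synthetic cohorts of behavior and pupil traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
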