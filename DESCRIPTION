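Package: sdecme
Title: SDE-Driven Chemical Master Equation Models of Transcriptional Noise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state joint nascent/mature RNA count distributions for
    transcription models in which the transcription rate follows a continuous
    stochastic process: the gamma Ornstein-Uhlenbeck (jump-driven) and
    Cox-Ingersoll-Ross (diffusion-driven) drivers, plus their constitutive,
    mixture and bursty limiting models.  Provides exact generating-function
    solvers with inverse-FFT distribution recovery, closed-form moments and
    autocorrelation functions, exact hybrid stochastic simulation with
    time-varying transcription propensity, maximum-likelihood fitting, Bayesian
    posterior and Bayes-factor model selection, a gene-screening pipeline for
    spliced/unspliced count matrices, and a seeded synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    deSolve,
    graphics,
    jsonlite,
    lhs,
    methods,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
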