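Package: freqadapt
Title: Context and Sequential Effects in Relative-Frequency Judgment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for the psychophysics of visual
    relative-frequency judgment under manipulated stimulus statistics. Provides
    the four discrete stimulus-distribution conditions (Uniform, Extreme, Small,
    Large), synthetic observers under six generative response models combining
    linear-in-log-odds probability distortion, delta-rule adaptation-level
    learning, and linear or derivative-of-Gaussian non-linear sequential
    effects; closed-form predictors for adaptation-level and Bayesian
    (posterior-mean) theories of context effects; parametric (linear-in-log-odds)
    and non-parametric (Nadaraya-Watson kernel smoothing with curvature and
    elevation metrics) measures of probability distortion; linear and
    kernel-weighted local (WLS) estimates of sequential effects; maximum-likelihood
    model fitting with small-sample-corrected AIC comparison and random-effects
    group-level model selection (protected exceedance probability); and an
    efficient-coding test based on Kullback-Leibler divergence of response
    distributions from uniform.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
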