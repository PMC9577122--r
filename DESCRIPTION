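Package: wsirisk
Title: Patch-Based Whole-Slide Image Risk Classification with Survival Stratification
Version: 0.1.0
Authors@R: person("Morgan", "Hale", email = "morgan.hale@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying urothelial-carcinoma
    whole-slide images into low- and high-risk groups from tissue patches.
    Slides are tiled into fixed-size patches after background and marker
    masking, each patch is scored by four one-vs-rest convolutional
    classifiers (PUNLMP, low-grade, high-grade, invasive), patch labels are
    fused by a confidence rule into per-slide class-ratio vectors, and a
    Gaussian-process classifier maps ratio vectors to a slide-level risk
    probability. Includes Kaplan-Meier, log-rank and univariate Cox
    proportional-hazards routines for stratifying predicted risk groups,
    bootstrap evaluation metrics, ASAP-dialect annotation XML input/output,
    and a seeded synthetic-slide generator so the whole pipeline is
    exercisable without access to clinical slide archives.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    xml2,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
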