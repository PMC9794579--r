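Package: tdprisk
Title: In-Silico Torsadogenic Risk Assessment from Beat-to-Beat Biomarker
    Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A CiPA-style pipeline for classifying the torsades-de-pointes
    (TdP) risk of drugs from in-silico simulation. Dose-inhibition tables for
    seven cardiac ion channels are turned into uncertainty-quantified Hill
    parameter samples by Markov chain Monte Carlo; sampled channel blocks
    drive a paced human ventricular myocyte model; seven per-beat biomarkers
    (qNet, qInward, APD50/90, CaD50/90 and the maximal repolarization slope)
    are extracted over the last 500 of 1,000 beats; and the resulting
    beat-indexed variability series are classified into high, intermediate
    or low TdP risk by a one-dimensional convolutional neural network,
    evaluated with a 10,000-resample test procedure reporting per-class AUC,
    likelihood ratios, accuracy and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    pracma,
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp,
    RcppArmadillo
Config/testthat/edition: 3
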