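Package: sigmakin
Title: Kinetic Inference of Sigma-Factor Regulatory Networks from
    Expression Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs sigma-factor-controlled transcriptional networks
    from dense two-channel microarray time series. Provides per-array
    median/MAD normalization with quantile trimming, replicate outlier
    rejection (Dixon Q test and Peirce's criterion), expression-level and
    coefficient-of-variation gene filters, consensus k-means kinetic
    clustering with Spearman distance and core profiles, a sigmoid ODE
    model of transcription control fitted by multi-restart simulated
    annealing, correlation-thresholded network construction with
    prior-knowledge integration and GEXF export, Fisher exact functional
    enrichment of kinetic clusters, and a synthetic-data generator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
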