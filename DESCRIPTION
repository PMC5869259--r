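Package: rifnet
Title: Regulatory Impact Factors and PCIT Co-Expression Networks for
    Two-State Transcriptome Studies
Version: 0.1.0
Authors@R:
    person("rifnet", "developers", email = "rifnet@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for two-state (e.g. pre- versus
    post-pubertal) RNA-seq designs: RPKM computation and expressed-gene
    filtering, mixed-model (EM-REML) normalization of log2 expression with
    gene and gene-by-animal-by-state-by-tissue random effects,
    differential-expression testing on the model solutions, regulatory
    impact factor (RIF1/RIF2) scoring of transcription factors, gene
    co-expression network inference by the partial correlation and
    information theory (PCIT) algorithm, and exhaustive selection of the
    transcription-factor trio covering the network with minimum
    redundancy. Includes a synthetic-data generator with planted
    differential expression and differential wiring for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
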