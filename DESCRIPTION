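Package: cnahmm
Title: Somatic Copy Number, LOH, Purity and Ploidy Inference from SNP
    Arrays via a Bayesian Hidden Markov Model
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint inference of somatic copy number alterations,
    loss-of-heterozygosity, tumor ploidy (Log R Ratio baseline), genome-wide
    normal-DNA contamination and locus-level intra-tumor heterogeneity from
    SNP genotyping array Log R Ratio (LRR) and B allele frequency (BAF)
    data. Implements a 21-state tumor genotype hidden Markov model with
    Student-t mixture emissions, GC-content wave correction, distance
    dependent transitions, MAP expectation-maximization with baseline
    restarts, Viterbi segmentation with approximate Bayes factor scoring,
    and a synthetic tumor-normal dilution-series simulator with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
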