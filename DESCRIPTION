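Package: tfcensus
Title: Census and Domain-Architecture Promiscuity of Prokaryotic Transcription Factor Families
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A comparative-genomics pipeline for DNA-binding transcription
    factor (TF) families in bacteria and archaea. Starting from per-genome
    structural-domain assignment tables, the package computes per-family TF
    abundance and normalized abundance profiles, genome-size correlations,
    lifestyle-stratified TF content with Kruskal-Wallis comparison and
    Manhattan/average-linkage clustering, companion-domain (CD) repertoires,
    the weighted domain-architecture promiscuity score (WS = IAF x IV) with
    CV-based promiscuity classes and Sturges genome-size binning, and
    one-tailed Fisher DBD-CD enrichment with Benjamini-Hochberg correction.
    A synthetic-data generator with planted statistical structure makes the
    whole pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
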