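Package: gagconnect
Title: Population Connectivity and Historical Demography of Gag Grouper in
    the Gulf of Mexico
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multilocus population-genetic analysis of Gag grouper
    (Mycteroperca microlepis) connectivity across the Gulf of Mexico:
    GENEPOP and FASTA input with tandem-repeat indel recoding, per-locus
    diversity and neutrality screening (Hardy-Weinberg and linkage
    disequilibrium exact tests, Tajima's D, Fu's Fs), differentiation
    testing with simulation-calibrated error rates (Weir-Cockerham
    F-statistics, AMOVA phi-statistics, standardized phi'ST, combined
    chi-squared and Markov-chain exact tests), minimum spanning haplotype
    networks, mismatch-distribution expansion dating with parametric
    bootstrap, two-phase-model bottleneck tests, and scenario-constrained
    migration-model comparison by approximate Bayesian computation with
    Bayes-factor ranking. Includes a structured-coalescent synthetic-data
    generator (stepwise and two-phase microsatellite mutation, finite-sites
    mtDNA with repeat-indel loci, forward-drift divergence experiments) so
    every stage can be exercised and calibrated without the original
    samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
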