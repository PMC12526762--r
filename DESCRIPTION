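Package: steppekit
Title: Ancient-DNA Population-Genetic Inference: f-Statistics, qpAdm,
    Admixture Dating, Kinship and Pseudo-Haploid Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide ancestry analysis of low-coverage
    ancient genomes: EIGENSTRAT genotype I/O, damage-aware pseudo-haploid
    calling from pileup data, f2/f3/f4 statistics with weighted block
    jackknife standard errors, qpWave rank tests and qpAdm admixture
    modelling with rotating outgroups and nested model comparison,
    admixture dating from the exponential decay of ancestry covariance,
    pairwise-mismatch-rate and IBD-segment kinship classification backed
    by pedigree simulation with crossover interference, and least-squares
    PCA projection of high-missingness individuals. A synthetic-data
    generator (admixture graphs with closed-form expected f-statistics,
    ancestry-tract and damaged-read simulators) provides ground truth for
    every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
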