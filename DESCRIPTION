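Package: admixstats
Title: Admixture-Aware Population-Genetic Statistics for SNP Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimators for population-genetic analyses of recently admixed
    cohorts genotyped on SNP arrays. Fits a point-mass/beta mixture to
    admixture proportions and computes admixture-corrected allele
    frequencies; estimates ancestry-specific two-locus haplotype
    frequencies from unphased genotypes by expectation-maximization and
    derives per-ancestry linkage-disequilibrium decay; computes
    maximum-likelihood inbreeding coefficients with ancestry-weighted
    allele frequencies; computes four-population D statistics with a
    weighted delete-m block jackknife and Weir-Cockerham FST; and models
    ancestry-tract lengths with a two-state Markov approximation. Includes
    genotype/Q-matrix/tract readers and writers, site and individual
    quality-control filters, windowed LD pruning, and a synthetic-cohort
    generator reproducing the generative assumptions of every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
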