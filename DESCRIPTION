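Package: admixscan
Title: Admixture Inference and Post-Admixture Selection Scans for
    Two-Way Admixed Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to characterise two-way admixed populations from
    SNP-array-scale genotype data: f3 admixture tests and F4-ratio
    ancestry proportions with block-jackknife standard errors,
    admixture dating from the exponential decay of ancestry-weighted
    linkage disequilibrium, two-way local-ancestry inference on
    unphased genotypes via a diploid hidden Markov model, genome-wide
    ancestry-excess outlier scans calibrated against a neutral
    coalescent null (simulated with a built-in
    coalescent-with-recombination engine and SNP-array-like
    ascertainment), and EHH/iHS scans for recent positive selection on
    phased haplotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    minpack.lm,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
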