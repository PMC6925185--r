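Package: torporscan
Title: Heritability and Mixed-Model GWAS of Hibernation Torpor Onset
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the genetics of hibernation timing from
    body-temperature telemetry and reduced-representation genotyping.
    Calls the first day of autumn torpor from datalogger traces, performs
    multi-caller variant concordance and site-level quality control,
    estimates population structure (KING-robust and ancestry-adjusted
    kinship, PCA, Weir-Cockerham F_ST, first-degree pedigree
    reconstruction), fits the animal model by REML and by a Gibbs sampler
    to estimate narrow-sense heritability, runs score-test genome-wide
    association with simpleM effective-test correction, corroborates hits
    by phenotype permutation (with Harrell-Davis quantile inversion) and
    complementary-pairs stability selection with overlapping subsets,
    partitions phenotypic variance over independent loci, and scans
    cis/trans expression quantitative trait loci. A synthetic cohort
    generator with litter-structured families, Balding-Nichols population
    divergence and block linkage disequilibrium provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
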