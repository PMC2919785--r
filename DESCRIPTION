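Package: breedmapr
Title: Breed-Level Mapping of Morphological Traits from SNP Genotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for breed-level association mapping of
    morphological traits in purebred dog cohorts. Provides PLINK text
    genotype input, a two-state hidden Markov model for autozygosity with
    run-of-homozygosity summaries and a heterozygosity-in-autozygosity SNP
    quality filter, within- and between-population diversity statistics
    (linkage-disequilibrium decay, windowed haplotype counts), per-SNP
    Weir-Cockerham F_ST with outlier-region delineation, breed-average
    mixed-model association (EMMA-style exact restricted likelihood),
    an identity-by-state weighted bootstrap test for dichotomous traits,
    and forward-stepwise multi-SNP predictive models validated on
    individual genotypes. A breed-formation simulator with planted
    quantitative trait loci and autozygous tracts supplies ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
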