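# Shared configuration for the analysis workflow.
#
# Every numbered script sources this file first.  All heavy lifting lives
# in the breedmapr package; these scripts only drive it and write results.

library(breedmapr)

SEED <- 20260101L
CFG <- sim_config(seed = SEED)   # 50 breeds x 10 dogs + 30 village dogs,
                                 # 5,000 SNPs on 5 x 100 Mb chromosomes

RESULTS <- file.path("results")
DATA <- file.path(RESULTS, "data")
dir.create(DATA, recursive = TRUE, showWarnings = FALSE)

ped_path <- file.path(DATA, "cohort.ped")
map_path <- file.path(DATA, "cohort.map")
pheno_path <- file.path(DATA, "phenotypes.tsv")
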