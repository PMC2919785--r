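#!/usr/bin/env Rscript
# 01 -- Simulate the cohort.
#
# A 50-breed cohort (10 dogs per breed) plus 30 mixed-ancestry village
# dogs is simulated with the founder-haplotype model: breed allele
# frequencies drift from a shared ancestral pool (Balding-Nichols,
# F = 0.28), then a small founder population is recombined for a few
# generations so that genotypes carry realistic within-breed LD and runs
# of homozygosity.  Three QTLs with effects 4:2:1 drive the "size" trait
# at heritability ~0.9.
#
# Outputs: PLINK-format genotypes, a phenotype table, and the planted
# truth (QTL positions) for later comparison.

source("analysis/00_config.R")

truth <- simulate_breed_frequencies(CFG)
sim <- simulate_haplotypes(CFG, truth)
ph <- simulate_phenotypes(CFG, sim$genotypes, sim$truth)

write_plink(sim$genotypes, ped_path, map_path)
write_phenotypes(ph$phenotypes, pheno_path)

qtl <- CFG$qtls
qtl$marker_id <- sim$genotypes$map$marker_id[qtl$marker_index]
qtl$chrom <- sim$genotypes$map$chrom[qtl$marker_index]
qtl$pos_bp <- sim$genotypes$map$pos_bp[qtl$marker_index]
write.table(qtl, file.path(DATA, "planted_qtls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("wrote", ped_path, "(", nrow(sim$genotypes$geno), "dogs x",
    ncol(sim$genotypes$geno), "markers )\n")
cat("planted QTLs:", paste(qtl$marker_id, collapse = ", "), "\n")
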