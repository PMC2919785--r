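#!/usr/bin/env Rscript
# 02 -- Autozygosity scan.
#
# A two-state HMM walks each dog's genome and calls segments where the
# posterior probability of autozygosity (both chromosomes descending from
# a recent common ancestor) exceeds 0.5, keeping runs longer than 100 kb
# with at least 25 SNPs.  Breed dogs, whose ancestry funnels through a
# handful of founders, should carry many long runs; village dogs few.
#
# Outputs: per-dog segment calls (BED), a run-length summary table, and a
# het-in-autozygous-tract QC report.

source("analysis/00_config.R")

gm <- read_plink(ped_path, map_path)
scan <- autozygosity_scan(gm)

write_segments_bed(scan$segments, file.path(RESULTS, "roh_segments.bed"))

rs <- roh_summary(scan$segments, gm$individuals$individual_id,
                  genome_bp = CFG$n_chromosomes * CFG$chrom_length_bp)
rs$breed <- gm$individuals$breed[match(rs$individual_id,
                                       gm$individuals$individual_id)]
write.table(rs, file.path(RESULTS, "roh_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

by_breed <- aggregate(rs[c("n_roh_gt_1e+06", "n_roh_gt_1e+07",
                           "genome_fraction")],
                      by = list(breed = rs$breed), FUN = mean)
write.table(by_breed, file.path(RESULTS, "roh_by_breed.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# markers that look heterozygous inside called-autozygous tracts are
# probable genotyping failures
qc <- filter_snps_by_het_in_auto(gm, scan$segments, max_het_rate = 0.10)
write.table(qc$table, file.path(RESULTS, "het_in_auto_qc.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

vil <- by_breed[by_breed$breed == "village", ]
brd <- by_breed[by_breed$breed != "village", ]
cat(sprintf("breed dogs: mean autozygous fraction %.3f, %.1f ROH > 10 Mb\n",
            mean(brd$genome_fraction), mean(brd[["n_roh_gt_1e+07"]])))
cat(sprintf("village dogs: mean autozygous fraction %.3f, %.1f ROH > 10 Mb\n",
            vil$genome_fraction, vil[["n_roh_gt_1e+07"]]))
cat(length(qc$excluded), "markers excluded by the het-in-auto QC filter\n")
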