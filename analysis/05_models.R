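#!/usr/bin/env Rscript
# 05 -- Multi-locus model and validation.
#
# Forward stepwise selection over the LMM-ranked candidates builds a
# small additive model of breed-average size; the first picks should fall
# in the planted QTLs' LD blocks and the three-marker model should
# explain most of the across-breed variance.  The fitted model is then
# used to predict held-out breeds.
#
# Outputs: selected markers with the R^2 trajectory, and leave-out-breeds
# validation statistics.

source("analysis/00_config.R")

gm_all <- read_plink(ped_path, map_path)
phenos <- read_phenotypes(pheno_path)

keep <- gm_all$individuals$breed != "village"
gm <- subset_genotypes(gm_all, individuals = keep)
ba <- breed_averages(phenos[phenos$breed != "village", ], "size")
bf <- breed_freqs(gm)
K <- breed_average_kinship(ibs_kinship(gm), gm$individuals$breed)

assoc <- lmm_assoc(bf, ba, K)
candidates <- assoc$marker_id[order(assoc$p_value)]

fit <- forward_stepwise(candidates, gm, ba, max_k = 3, unit = "breed")
sel <- data.frame(step = seq_along(fit$markers), marker_id = fit$markers,
                  r2 = fit$r2_trajectory, adj_r2 = fit$adj_r2_trajectory)
write.table(sel, file.path(RESULTS, "stepwise_model.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(sel, row.names = FALSE)

qtl <- read.delim(file.path(DATA, "planted_qtls.tsv"))
hit <- vapply(fit$markers, function(mk)
  any(suppressWarnings(
    cor(gm$geno[, mk], gm$geno[, qtl$marker_id, drop = FALSE]))^2 >= 0.5,
    na.rm = TRUE), TRUE)
cat(sum(hit), "of", length(hit), "selections tag a planted QTL\n")

## hold out 10 breeds, refit, and predict their means
set.seed(SEED)
held <- sample(ba$breed, 10)
train <- ba[!ba$breed %in% held, ]
fit_tr <- forward_stepwise(candidates, gm, train, max_k = 3,
                           unit = "breed")
pred_ind <- predict(fit_tr, gm)
pred_breed <- tapply(pred_ind, gm$individuals$breed, mean)
obs <- setNames(ba$mean_value, ba$breed)[held]
val <- validate_predictions(pred_breed[held], obs, label = "held-out")
write.table(data.frame(label = val$label, n = val$n, r = val$correlation,
                       r2 = val$r_squared),
            file.path(RESULTS, "validation.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("held-out breeds: r = %.3f, R^2 = %.3f\n",
            val$correlation, val$r_squared))
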