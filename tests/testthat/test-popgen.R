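# Population-genetic statistics: LD decay, haplotype diversity windows,
# Weir & Cockerham F_ST against an independent oracle, region delineation.

test_that("ld_decay matches directly computed r-squared in each bin", {
  set.seed(41)
  n <- 10; m <- 30
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  gm <- toy_genotypes(g, spacing_bp = 5e4)
  curve <- ld_decay(gm, gm$individuals$individual_id, maf_min = 0,
                    max_missing = 1, sample_n = n, max_dist_bp = 2e6,
                    bin_bp = 1e5, seed = 1, label = "toy")
  # direct oracle over all pairs
  pos <- gm$map$pos_bp
  sums <- numeric(nrow(curve)); cnts <- integer(nrow(curve))
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    d <- abs(pos[j] - pos[i])
    if (d == 0 || d > 2e6) next
    if (var(g[, i]) == 0 || var(g[, j]) == 0) next
    b <- ceiling(d / 1e5)
    sums[b] <- sums[b] + cor(g[, i], g[, j])^2
    cnts[b] <- cnts[b] + 1L
  }
  expect_equal(curve$n_pairs, cnts)
  got <- curve$mean_r2[cnts > 0]
  expect_equal(got, (sums / pmax(cnts, 1))[cnts > 0], tolerance = 1e-12)
  expect_equal(attr(curve, "population_label"), "toy")
})

test_that("ld_decay r-squared is invariant to flipping dosage coding", {
  set.seed(43)
  n <- 12; m <- 40
  g <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  gm1 <- toy_genotypes(g, spacing_bp = 2e4)
  gm2 <- toy_genotypes(2L - g, spacing_bp = 2e4)
  ids <- gm1$individuals$individual_id
  c1 <- ld_decay(gm1, ids, maf_min = 0, sample_n = n, seed = 2)
  c2 <- ld_decay(gm2, ids, maf_min = 0, sample_n = n, seed = 2)
  expect_equal(c1$mean_r2, c2$mean_r2, tolerance = 1e-12)
})

test_that("ld_at returns the containing bin and ld_decay validates input", {
  curve <- data.frame(low_bp = c(0, 1e5), high_bp = c(1e5, 2e5),
                      mean_r2 = c(0.5, 0.2), n_pairs = c(3L, 4L))
  expect_equal(ld_at(curve, 1e5), 0.5)
  expect_equal(ld_at(curve, 100001), 0.2)
  expect_true(is.na(ld_at(curve, 9e5)))
  gm <- toy_genotypes(matrix(0L, 3, 4))
  expect_error(ld_decay(gm, c("d001", "d002"), sample_n = 10),
               "sample_n")
})

test_that("haplotype_diversity counts distinct strings per window", {
  # 3 individuals (6 haplotypes), one chromosome, window 500 kb;
  # 6 SNPs in window 1 (subsampled to 5), 5 in window 2, 3 in window 3
  # (reduced rule: 3 SNPs)
  pos <- c(seq(1e4, by = 5e4, length.out = 6),
           seq(5.1e5, by = 5e4, length.out = 5),
           seq(1.01e6, by = 5e4, length.out = 3))
  m <- length(pos)
  map <- marker_map(sprintf("s%02d", 1:m), rep("chr1", m), pos)
  set.seed(47)
  haps <- matrix(sample(0:1, 6 * m, replace = TRUE), 6, m)
  hp <- haplotype_panel(haps, rep(c("a", "b", "c"), each = 2),
                        rep(1:2, 3), map)
  breeds <- c(a = "x", b = "x", c = "x")
  hd <- haplotype_diversity(hp, breeds, window_bp = 5e5, snps_full = 5,
                            snps_reduced = 3, sample_n = 3, seed = 9)
  expect_equal(nrow(hd$windows), 3L)
  expect_equal(hd$windows$snps_used, c(5L, 5L, 3L))
  expect_equal(hd$windows$start_bp, c(1, 5e5 + 1, 1e6 + 1))
  # oracle: count unique rows over the selected columns
  for (j in 1:3) {
    win <- hd$windows[j, ]
    idx <- which(map$pos_bp >= win$start_bp & map$pos_bp <= win$end_bp)
    # snps actually used are a subset; counting over all window SNPs gives
    # an upper bound, over one SNP a lower bound
    expect_lte(hd$counts["x", j], nrow(unique(haps[, idx, drop = FALSE])))
    expect_gte(hd$counts["x", j], 1L)
  }
  # identical haplotypes give count 1 everywhere
  hp1 <- haplotype_panel(matrix(0L, 6, m), rep(c("a", "b", "c"), each = 2),
                         rep(1:2, 3), map)
  hd1 <- haplotype_diversity(hp1, breeds, window_bp = 5e5, snps_full = 5,
                             snps_reduced = 3, sample_n = 3, seed = 9)
  expect_true(all(hd1$counts == 1L))
  # indicator haplotypes: row r is 1 exactly where the column pattern is r.
  # Full windows separate all 6 rows (any 5 of 6 patterns leave at most one
  # all-zero row); window 3 holds patterns {6, 1, 2} only, so rows 3-5
  # collapse to the all-zero string: 4 distinct
  hpd <- haplotype_panel(diag(6)[, rep(1:6, length.out = m)],
                         rep(c("a", "b", "c"), each = 2), rep(1:2, 3), map)
  hdd <- haplotype_diversity(hpd, breeds, window_bp = 5e5, snps_full = 5,
                             snps_reduced = 3, sample_n = 3, seed = 9)
  expect_equal(unname(hdd$counts["x", ]), c(6L, 6L, 4L))
  # undersized breeds are skipped with a warning (here both breeds are)
  ws <- capture_warnings(
    haplotype_diversity(hp, c(a = "x", b = "x", c = "y"), window_bp = 5e5,
                        snps_full = 5, snps_reduced = 3, sample_n = 3,
                        seed = 9))
  expect_true(any(grepl("skipped", ws)))
})

test_that("weir_fst equals the variance-components oracle", {
  set.seed(61)
  for (rep in 1:40) {
    nb <- sample(2:6, 1)
    nd <- sample(2:8, 1)
    g <- matrix(sample(c(0:2, NA), nb * nd * 12, replace = TRUE,
                       prob = c(0.3, 0.25, 0.3, 0.15)), nb * nd, 12)
    breeds <- rep(sprintf("b%d", 1:nb), each = nd)
    gm <- toy_genotypes(g, breed = breeds)
    res <- weir_fst(gm)
    for (j in 1:12) {
      oracle <- wc_theta_oracle(g[, j], breeds)
      if (is.na(oracle)) {
        expect_true(is.na(res$fst[j]) || res$status[j] != "ok")
      } else {
        expect_equal(res$fst[j], oracle, tolerance = 1e-12)
      }
    }
  }
})

test_that("weir_fst handles the textbook hand cases", {
  # two breeds fixed for opposite alleles: theta-hat = 1
  g <- rbind(matrix(0L, 5, 1), matrix(2L, 5, 1))
  gm <- toy_genotypes(cbind(g, g), breed = rep(c("p", "q"), each = 5))
  res <- weir_fst(gm)
  expect_equal(res$fst, c(1, 1), tolerance = 1e-12)
  # identical breeds in perfect HWE: theta-hat <= 0 (no differentiation)
  block <- matrix(rep(c(0L, 1L, 1L, 2L), 3), 4, 3)
  gm2 <- toy_genotypes(rbind(block, block),
                       breed = rep(c("p", "q"), each = 4))
  res2 <- weir_fst(gm2)
  expect_true(all(res2$fst <= 0))
  # monomorphic marker and single-breed data are flagged, not silently 0
  g3 <- cbind(rep(2L, 6), c(0L, 1L, 2L, NA, NA, NA))
  gm3 <- toy_genotypes(g3, breed = rep(c("p", "q"), each = 3))
  res3 <- weir_fst(gm3)
  expect_equal(res3$status[1], "monomorphic")
  expect_equal(res3$status[2], "fewer than 2 breeds with data")
  expect_true(all(is.na(res3$fst)))
})

test_that("pairwise_fst combination schemes behave as documented", {
  set.seed(67)
  # breeds p and q drift to frequencies 0.2 and 0.8 at every marker
  g <- matrix(rbinom(8 * 20, 2, rep(rep(c(0.2, 0.8), each = 4), 20)), 8, 20)
  gm <- toy_genotypes(g, breed = rep(c("p", "q"), each = 4))
  roa <- pairwise_fst(gm, "p", "q", scheme = "ratio_of_averages")
  aor <- pairwise_fst(gm, "p", "q", scheme = "average_of_ratios")
  expect_true(is.finite(roa) && is.finite(aor))
  expect_gt(roa, 0.2)
  # both schemes must agree on a panel of identical markers
  gm_same <- toy_genotypes(cbind(g[, 1], g[, 1]),
                           breed = rep(c("p", "q"), each = 4))
  expect_equal(pairwise_fst(gm_same, "p", "q", "ratio_of_averages"),
               pairwise_fst(gm_same, "p", "q", "average_of_ratios"),
               tolerance = 1e-12)
})

test_that("fst_regions reproduces a hand-traced 30-marker example", {
  # 30 markers, two chromosomes of 15. Order statistics of the F_ST vector:
  # x(30) = 0.72, x(29) = 0.68, x(28) = 0.58, so the 95th-percentile
  # neighbor threshold (type-7 quantile, h = 1 + 29 * 0.95 = 28.55) is
  # 0.58 + 0.55 * (0.68 - 0.58) = 0.635: only m04 and m05 qualify as
  # extension neighbors.
  fst_vals <- c(0.10, 0.12, 0.09, 0.72, 0.68, 0.20, 0.08, 0.11, 0.50, 0.13,
                0.07, 0.15, 0.18, 0.05, 0.14,
                0.22, 0.10, 0.16, 0.56, 0.14, 0.12, 0.58, 0.09, 0.17, 0.19,
                0.21, 0.06, 0.23, 0.24, 0.13)
  maf <- rep(0.3, 30)
  maf[22] <- 0.05   # m22: high F_ST but fails the MAF gate -> not a peak
  fst <- data.frame(marker_id = sprintf("m%02d", 1:30),
                    chrom = rep(c("chr1", "chr2"), each = 15),
                    pos_bp = rep(seq(1e6, 15e6, by = 1e6), 2),
                    fst = fst_vals, maf_overall = maf,
                    n_breeds_used = 5L, status = "ok",
                    stringsAsFactors = FALSE)
  reg <- fst_regions(fst, peak_min_fst = 0.55, peak_min_maf = 0.15,
                     neighbor_percentile = 0.95)
  # Hand trace: peaks are m04 (0.72), m05 (0.68) and m19 (0.56); m22 is
  # blocked by MAF and, at 0.58 < 0.635, is no qualifying neighbor either.
  # m04 extends right over m05 (0.68 >= 0.635) and stops at m06; m05
  # extends left over m04 and stops at m03; the overlapping spans merge
  # into one region with the higher peak m04. m19's neighbors m18 (0.16)
  # and m20 (0.14) fail, leaving a singleton.
  expect_equal(attr(reg, "neighbor_threshold"), 0.635, tolerance = 1e-10)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$chrom, c("chr1", "chr2"))
  expect_equal(reg$peak_marker, c("m04", "m19"))
  expect_equal(reg$peak_fst, c(0.72, 0.56))
  expect_equal(reg$member_markers, c("m04,m05", "m19"))
  expect_equal(reg$n_markers, c(2L, 1L))
  expect_equal(reg$singleton, c(FALSE, TRUE))
  expect_equal(reg$start_bp, c(4e6, 4e6))
  expect_equal(reg$end_bp, c(5e6, 4e6))

  # no peak at all yields an empty frame that still carries the threshold
  fst0 <- fst; fst0$fst <- rep(0.2, 30)
  reg0 <- fst_regions(fst0, peak_min_fst = 0.55, peak_min_maf = 0.15)
  expect_equal(nrow(reg0), 0L)
  expect_equal(attr(reg0, "neighbor_threshold"), 0.2)

  # regions never extend across a chromosome boundary
  fst3 <- fst
  fst3$fst <- rep(0.6, 30)
  fst3$maf_overall <- 0.3
  reg3 <- fst_regions(fst3, peak_min_fst = 0.55, peak_min_maf = 0.15,
                      neighbor_percentile = 0.5)
  expect_equal(nrow(reg3), 2L)
  expect_equal(reg3$chrom, c("chr1", "chr2"))
  expect_equal(reg3$n_markers, c(15L, 15L))
})
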