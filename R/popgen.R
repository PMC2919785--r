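# Diversity and differentiation statistics: LD decay curves, windowed
# distinct-haplotype counts, per-SNP Weir & Cockerham (1984) F_ST across
# breeds, and outlier-region delineation around high-F_ST peaks.

#' LD decay curve for a population subset
#'
#' Squared Pearson correlation of genotype dosages for all same-chromosome
#' marker pairs within `max_dist_bp`, averaged in distance bins. A random
#' subset of `sample_n` individuals is used (so curves from populations of
#' different size are comparable) and markers are re-filtered inside the
#' subset: MAF at least `maf_min` and missingness below `max_missing`.
#' r-squared is computed complete-case per pair; pairs where either marker
#' has zero variance are skipped.
#'
#' @param genotypes a [genotype_matrix()].
#' @param population character vector of individual ids forming the
#'   population (e.g. one breed, or one dog from each of several breeds).
#' @param maf_min,max_missing within-subset marker filters.
#' @param sample_n dogs sampled from the population.
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_bp distance bin width.
#' @param seed seed for the individual subsample.
#' @param label population label stored on the output.
#' @return `data.frame(low_bp, high_bp, mean_r2, n_pairs)` with attribute
#'   `population_label`.
#' @export
ld_decay <- function(genotypes, population, maf_min = 0.15,
                     max_missing = 0.10, sample_n = 10,
                     max_dist_bp = 5e6, bin_bp = 25e3, seed = 1,
                     label = NA_character_) {
  if (length(population) < sample_n)
    stop("population has ", length(population),
         " individuals; need at least sample_n = ", sample_n)
  set.seed(seed)
  ids <- if (length(population) > sample_n)
    sample(population, sample_n) else population
  sub <- subset_genotypes(genotypes, individuals = ids)
  fr <- marker_freq(sub)
  keep <- !is.na(fr$maf) & fr$maf >= maf_min & fr$missing_rate < max_missing
  sub <- subset_genotypes(sub, markers = keep)
  map <- sub$map
  breaks <- seq(0, max_dist_bp, by = bin_bp)
  nb <- length(breaks) - 1L
  sum_r2 <- numeric(nb); n_pairs <- integer(nb)
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    if (length(idx) < 2L) next
    g <- sub$geno[, idx, drop = FALSE]
    pos <- map$pos_bp[idx]
    r <- suppressWarnings(stats::cor(g, use = "pairwise.complete.obs"))
    r2 <- r^2
    d <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(d)
    ok <- ut & d <= max_dist_bp & d > 0 & !is.na(r2)
    if (!any(ok)) next
    # bins are (low, high]: a distance on a bin edge belongs to the lower
    # bin, matching ld_at()
    bin <- as.integer(ceiling(d[ok] / bin_bp))
    bin[bin > nb] <- nb
    sum_r2 <- sum_r2 + unname(tapply_fill(r2[ok], bin, nb, sum))
    n_pairs <- n_pairs + unname(tapply_fill(rep(1L, sum(ok)), bin, nb, sum))
  }
  out <- data.frame(low_bp = breaks[-length(breaks)], high_bp = breaks[-1L],
                    mean_r2 = ifelse(n_pairs > 0, sum_r2 / n_pairs, NA_real_),
                    n_pairs = n_pairs)
  attr(out, "population_label") <- label
  out
}

# sum (or other fn) of x grouped by integer bin 1..nb, zero-filled
tapply_fill <- function(x, bin, nb, fn) {
  out <- rep(0, nb)
  agg <- tapply(x, bin, fn)
  out[as.integer(names(agg))] <- agg
  out
}

#' Mean r-squared of an LD curve at a given distance
#'
#' @param curve output of [ld_decay()].
#' @param dist_bp distance of interest; the containing bin's mean is
#'   returned.
#' @return numeric scalar (possibly `NA` if the bin is empty).
#' @export
ld_at <- function(curve, dist_bp) {
  i <- which(curve$low_bp < dist_bp & curve$high_bp >= dist_bp)
  if (length(i) == 0L) return(NA_real_)
  curve$mean_r2[i[1L]]
}

#' Windowed haplotype diversity per breed
#'
#' Divides the genome into fixed windows anchored at position 1 of each
#' chromosome, selects a random subset of `snps_full` SNPs from windows with
#' at least that many (windows with fewer but at least `snps_reduced` get
#' `snps_reduced` random SNPs; windows below that are dropped), and counts
#' distinct haplotype strings over the selected SNPs among the `2 *
#' sample_n` chromosomes of a random `sample_n`-dog subset of each breed.
#' The same selected SNPs are used for every breed.
#'
#' @param haps a [haplotype_panel()].
#' @param breeds named character vector mapping individual id to breed.
#' @param window_bp window size in bp.
#' @param snps_full,snps_reduced SNP subsample sizes.
#' @param sample_n dogs sampled per breed; breeds with fewer dogs are
#'   skipped with a warning.
#' @param seed seed for SNP and dog subsampling.
#' @return list with `windows` (`data.frame(chrom, start_bp, end_bp,
#'   snps_used)`) and `counts` (breeds x windows matrix).
#' @export
haplotype_diversity <- function(haps, breeds, window_bp = 500000,
                                snps_full = 15, snps_reduced = 5,
                                sample_n = 10, seed = 1) {
  set.seed(seed)
  map <- haps$map
  win_id <- paste(map$chrom, (map$pos_bp - 1) %/% window_bp, sep = ":")
  wins <- unique(win_id)
  sel <- list(); wmeta <- list()
  for (w in wins) {
    idx <- which(win_id == w)
    ns <- length(idx)
    use <- if (ns >= snps_full) sort(sample(idx, snps_full))
           else if (ns >= snps_reduced) sort(sample(idx, snps_reduced))
           else NULL
    if (is.null(use)) next
    k <- (map$pos_bp[idx[1L]] - 1) %/% window_bp
    sel[[length(sel) + 1L]] <- use
    wmeta[[length(wmeta) + 1L]] <-
      data.frame(chrom = map$chrom[idx[1L]],
                 start_bp = k * window_bp + 1,
                 end_bp = (k + 1) * window_bp,
                 snps_used = length(use), stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, wmeta)
  inds <- unique(haps$phase_of$individual_id)
  breed_of <- breeds[inds]
  ub <- sort(unique(stats::na.omit(breed_of)))
  sampled <- list()
  for (b in ub) {
    members <- inds[!is.na(breed_of) & breed_of == b]
    if (length(members) < sample_n) {
      warning("breed ", b, " has ", length(members),
              " dogs; skipped (need ", sample_n, ")")
      next
    }
    sampled[[b]] <- if (length(members) > sample_n)
      sample(members, sample_n) else members
  }
  counts <- matrix(NA_integer_, length(sampled), length(sel),
                   dimnames = list(names(sampled), NULL))
  for (b in names(sampled)) {
    rows <- which(haps$phase_of$individual_id %in% sampled[[b]])
    h <- haps$haps[rows, , drop = FALSE]
    for (j in seq_along(sel)) {
      str <- apply(h[, sel[[j]], drop = FALSE], 1L, paste, collapse = "")
      counts[b, j] <- length(unique(str))
    }
  }
  list(windows = windows, counts = counts)
}

#' Per-SNP Weir & Cockerham F_ST across breeds
#'
#' The multi-population theta-hat of Weir & Cockerham (1984), computed per
#' marker from breed allele counts and observed heterozygote counts
#' (variance components a, b, c; theta = a / (a + b + c)). Breeds
#' contribute at a marker only if they have at least two non-missing
#' genotypes there; markers with fewer than two contributing breeds, or an
#' undefined estimator (all contributing breeds monomorphic), are excluded
#' with a reason. Negative estimates are reported as computed.
#'
#' @param genotypes a [genotype_matrix()].
#' @param breed_labels optional per-individual breed labels; defaults to
#'   the container's.
#' @return `data.frame(marker_id, chrom, pos_bp, fst, maf_overall,
#'   n_breeds_used, status)` where status is "ok" or an exclusion reason.
#' @export
weir_fst <- function(genotypes, breed_labels = NULL) {
  g <- genotypes$geno
  if (is.null(breed_labels)) breed_labels <- genotypes$individuals$breed
  comp <- .wc_components(g, breed_labels)
  a <- comp$a; denom <- comp$d; r <- comp$r
  fst <- ifelse(!is.na(denom) & denom != 0, a / denom, NA_real_)
  status <- rep("ok", ncol(g))
  status[r < 2L] <- "fewer than 2 breeds with data"
  status[r >= 2L & (is.na(denom) | denom == 0 | !is.finite(denom))] <-
    "monomorphic"
  fst[status != "ok"] <- NA_real_
  fr <- marker_freq(genotypes)
  data.frame(marker_id = genotypes$map$marker_id,
             chrom = genotypes$map$chrom, pos_bp = genotypes$map$pos_bp,
             fst = fst, maf_overall = fr$maf, n_breeds_used = as.integer(r),
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise F_ST between two breeds over all markers
#'
#' Weir & Cockerham components restricted to two populations, combined
#' across markers either as a ratio of averages (default; sums of a over
#' sums of a+b+c) or an average of per-marker ratios.
#'
#' @param genotypes a [genotype_matrix()].
#' @param breed_a,breed_b breed labels.
#' @param scheme marker-combination scheme.
#' @return numeric scalar.
#' @export
pairwise_fst <- function(genotypes, breed_a, breed_b,
                         scheme = c("ratio_of_averages",
                                    "average_of_ratios")) {
  scheme <- match.arg(scheme)
  keep <- genotypes$individuals$breed %in% c(breed_a, breed_b)
  sub <- subset_genotypes(genotypes, individuals = which(keep))
  comp <- .wc_components(sub$geno, sub$individuals$breed)
  if (scheme == "ratio_of_averages") {
    ok <- is.finite(comp$a) & is.finite(comp$d)
    sum(comp$a[ok]) / sum(comp$d[ok])
  } else {
    th <- ifelse(comp$d != 0, comp$a / comp$d, NA_real_)
    mean(th, na.rm = TRUE)
  }
}

# per-marker W&C components a and denominator a+b+c (internal)
.wc_components <- function(g, breed_labels) {
  fb <- factor(breed_labels)
  called <- !is.na(g)
  gz <- g; gz[!called] <- 0L
  N <- rowsum(called + 0, fb); S <- rowsum(gz, fb)
  Hc <- rowsum((called & g == 1L) + 0, fb)
  use <- N >= 2L
  Nu <- N * use
  P <- ifelse(Nu > 0, S / (2 * Nu), 0)
  Hp <- ifelse(Nu > 0, Hc / Nu, 0)
  r <- colSums(use); sumN <- colSums(Nu)
  nbar <- sumN / pmax(r, 1L)
  nc <- (sumN - colSums(Nu^2) / pmax(sumN, 1)) / pmax(r - 1, 1)
  pbar <- colSums(Nu * P) / pmax(sumN, 1)
  s2 <- colSums(Nu * sweep(P, 2L, pbar)^2) / (pmax(r - 1, 1) * pmax(nbar, 1))
  hbar <- colSums(Nu * Hp) / pmax(sumN, 1)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  d <- a + b + hbar / 2
  bad <- r < 2L
  a[bad] <- NA_real_; d[bad] <- NA_real_
  list(a = a, d = d, r = r)
}

#' Delineate F_ST outlier regions
#'
#' Peaks are markers with F_ST at or above `peak_min_fst` and overall MAF
#' at or above `peak_min_maf`. From each peak the region extends left and
#' right over consecutive array markers while each neighbor's F_ST stays at
#' or above the genome-wide `neighbor_percentile` quantile of F_ST. A peak
#' with no qualifying neighbor is a singleton region of one marker.
#' Overlapping regions are merged and the highest peak retained.
#'
#' @param fst a `data.frame` from [weir_fst()] (rows in map order).
#' @param peak_min_fst,peak_min_maf peak thresholds.
#' @param neighbor_percentile quantile defining the extension threshold.
#' @return `data.frame(chrom, start_bp, end_bp, peak_marker, peak_fst,
#'   n_markers, singleton, member_markers)` plus attribute
#'   `neighbor_threshold`.
#' @export
fst_regions <- function(fst, peak_min_fst = 0.55, peak_min_maf = 0.15,
                        neighbor_percentile = 0.95) {
  thr <- stats::quantile(fst$fst, neighbor_percentile, na.rm = TRUE,
                         names = FALSE)
  empty <- data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), peak_marker = character(),
                      peak_fst = numeric(), n_markers = integer(),
                      singleton = logical(), member_markers = character(),
                      stringsAsFactors = FALSE)
  attr(empty, "neighbor_threshold") <- thr
  peaks <- which(!is.na(fst$fst) & fst$fst >= peak_min_fst &
                 !is.na(fst$maf_overall) & fst$maf_overall >= peak_min_maf)
  if (length(peaks) == 0L) return(empty)
  qual <- !is.na(fst$fst) & fst$fst >= thr
  spans <- lapply(peaks, function(i) {
    ch <- fst$chrom[i]
    lo <- i
    while (lo > 1L && fst$chrom[lo - 1L] == ch && qual[lo - 1L]) lo <- lo - 1L
    hi <- i
    n <- nrow(fst)
    while (hi < n && fst$chrom[hi + 1L] == ch && qual[hi + 1L]) hi <- hi + 1L
    c(lo, hi)
  })
  # merge overlapping index spans on the same chromosome
  ord <- order(fst$chrom[peaks], vapply(spans, `[`, 0, 1L))
  spans <- spans[ord]; pk <- peaks[ord]
  merged <- list()
  for (k in seq_along(spans)) {
    s <- spans[[k]]
    if (length(merged) > 0L) {
      last <- merged[[length(merged)]]
      if (fst$chrom[last$lo] == fst$chrom[s[1L]] && s[1L] <= last$hi + 0L) {
        last$hi <- max(last$hi, s[2L])
        last$peaks <- c(last$peaks, pk[k])
        merged[[length(merged)]] <- last
        next
      }
    }
    merged[[length(merged) + 1L]] <- list(lo = s[1L], hi = s[2L],
                                          peaks = pk[k])
  }
  rows <- lapply(merged, function(mr) {
    idx <- mr$lo:mr$hi
    best <- mr$peaks[which.max(fst$fst[mr$peaks])]
    data.frame(chrom = fst$chrom[mr$lo],
               start_bp = fst$pos_bp[mr$lo], end_bp = fst$pos_bp[mr$hi],
               peak_marker = fst$marker_id[best],
               peak_fst = fst$fst[best], n_markers = length(idx),
               singleton = length(idx) == 1L,
               member_markers = paste(fst$marker_id[idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "neighbor_threshold") <- thr
  out
}
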