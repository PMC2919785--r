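# Breed-formation simulator: Balding-Nichols breed frequencies, a
# founder-pool haplotype mechanism giving long within-breed LD, planted
# large-effect QTLs and planted autozygous tracts. Every stage is seeded
# from one master seed via deterministic substreams.

.STAGE_IDS <- c(frequencies = 1L, haplotypes = 2L, phenotypes = 3L,
                planting = 4L, genotypes = 5L, sampling = 6L)

#' Derive a per-stage RNG seed from the master seed
#'
#' Keeps every simulator stage on its own reproducible stream so that, e.g.,
#' re-simulating phenotypes does not perturb the genotypes.
#'
#' @param seed master integer seed.
#' @param stage one of "frequencies", "haplotypes", "phenotypes",
#'   "planting", "genotypes", "sampling".
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, stage) {
  id <- .STAGE_IDS[[stage]]
  as.integer((as.numeric(seed) * 48271 + id * 7919) %% 2147483629)
}

#' Simulation configuration
#'
#' Defaults emulate a purebred-dog cohort at desk scale: 50 breeds of 10
#' dogs genotyped at 5,000 SNPs over five 100-Mb autosomes, strong founder
#' drift (drift coefficient F = 0.28, matching the observed mean per-SNP
#' differentiation among breeds), long within-breed LD from a 10-haplotype
#' founder bottleneck followed by a few generations of closed random mating,
#' an outbred village-dog population drawn straight from the ancestral pool,
#' and three large-effect QTLs with effects in ratio 4:2:1 explaining ~90%
#' of trait variance.
#'
#' @param n_breeds number of breeds.
#' @param dogs_per_breed genotyped dogs per breed.
#' @param n_markers total SNP count (split evenly across chromosomes).
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param ancestral_maf_range ancestral allele frequencies are drawn
#'   Uniform over this range (array ascertainment toward common SNPs).
#' @param breed_F per-breed drift coefficient in [0, 1); scalar recycled.
#' @param n_clades,clade_F optional hierarchical layer: clade frequencies
#'   are drawn Balding-Nichols around the ancestral frequency with
#'   `clade_F`, then breed frequencies around their clade's frequency with
#'   `breed_F`. `n_clades = 1` with `clade_F = 0` disables the layer.
#' @param founder_haplotypes_per_breed haplotypes founding each breed.
#' @param breed_pop_size breeding-population size (dogs) during breed
#'   propagation.
#' @param generations generations of closed random mating after founding.
#' @param recomb_rate_cM_per_Mb genetic map rate.
#' @param ancestral_pool_size haplotypes in the shared ancestral pool.
#' @param ancestral_ld_length_bp correlation length of the first-order
#'   along-chromosome allele process in the ancestral pool.
#' @param village_size outbred village dogs (0 disables).
#' @param qtls `data.frame(marker_index, effect, trait, threshold)`;
#'   `threshold = NA` means a continuous trait. Default: three QTLs for
#'   trait "size" with effects 2, 1, 0.5.
#' @param trait_noise_sd environmental noise sd; if `NULL`, derived from
#'   `trait_h2` and the realized genetic variance.
#' @param trait_h2 target narrow-sense heritability when `trait_noise_sd`
#'   is `NULL`.
#' @param seed master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 50, dogs_per_breed = 10, n_markers = 5000,
                       n_chromosomes = 5, chrom_length_bp = 100e6,
                       ancestral_maf_range = c(0.05, 0.95),
                       breed_F = 0.28, n_clades = 1, clade_F = 0,
                       founder_haplotypes_per_breed = 10,
                       breed_pop_size = 20, generations = 8,
                       recomb_rate_cM_per_Mb = 1.0,
                       ancestral_pool_size = 1000,
                       ancestral_ld_length_bp = 100e3,
                       village_size = 30,
                       qtls = NULL,
                       trait_noise_sd = NULL, trait_h2 = 0.9,
                       seed = 1) {
  breed_F <- rep_len(breed_F, n_breeds)
  if (any(breed_F < 0 | breed_F >= 1)) stop("breed_F must be in [0, 1)")
  if (clade_F < 0 || clade_F >= 1) stop("clade_F must be in [0, 1)")
  if (founder_haplotypes_per_breed < 2)
    stop("need at least 2 founder haplotypes per breed")
  if (!is.null(trait_noise_sd) && trait_noise_sd < 0)
    stop("trait_noise_sd must be non-negative")
  if (is.null(qtls)) {
    idx <- pmax(1L, round(n_markers * c(0.15, 0.45, 0.80)))
    qtls <- data.frame(marker_index = as.integer(idx),
                       effect = c(2, 1, 0.5),
                       trait = "size",
                       threshold = NA_real_,
                       stringsAsFactors = FALSE)
  }
  if (any(qtls$marker_index < 1L | qtls$marker_index > n_markers))
    stop("QTL marker_index out of range")
  structure(list(n_breeds = n_breeds, dogs_per_breed = dogs_per_breed,
                 n_markers = n_markers, n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 ancestral_maf_range = ancestral_maf_range,
                 breed_F = breed_F, n_clades = n_clades, clade_F = clade_F,
                 founder_haplotypes_per_breed = founder_haplotypes_per_breed,
                 breed_pop_size = breed_pop_size, generations = generations,
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 ancestral_pool_size = ancestral_pool_size,
                 ancestral_ld_length_bp = ancestral_ld_length_bp,
                 village_size = village_size, qtls = qtls,
                 trait_noise_sd = trait_noise_sd, trait_h2 = trait_h2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Marker map implied by a simulation configuration
#'
#' Markers are evenly spaced; each chromosome gets an equal share of
#' `n_markers` (the last chromosome absorbs the remainder).
#'
#' @param config a [sim_config()].
#' @return A [marker_map()].
#' @export
sim_marker_map <- function(config) {
  m <- config$n_markers; nc <- config$n_chromosomes
  per <- rep(m %/% nc, nc)
  per[nc] <- per[nc] + m %% nc
  chrom <- rep(sprintf("chr%d", seq_len(nc)), per)
  pos <- unlist(lapply(seq_len(nc), function(i) {
    round(seq(1, config$chrom_length_bp, length.out = per[i]))
  }))
  marker_map(sprintf("snp%05d", seq_len(m)), chrom, pos)
}

#' Simulate breed allele frequencies under the Balding-Nichols model
#'
#' Ancestral frequencies are drawn uniformly over the configured range;
#' each breed's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the
#' ancestral (or clade) frequency p. F = 0 degenerates to the ancestral
#' frequency exactly.
#'
#' @param config a [sim_config()].
#' @return A list of class `synthetic_truth` with elements
#'   `ancestral_freqs` (length m), `breed_allele_freqs` (breeds x markers),
#'   `clade_of` (breed -> clade index), `qtls`, and `map`.
#' @export
simulate_breed_frequencies <- function(config) {
  set.seed(substream_seed(config$seed, "frequencies"))
  m <- config$n_markers; B <- config$n_breeds
  p <- stats::runif(m, config$ancestral_maf_range[1],
                    config$ancestral_maf_range[2])
  rbn <- function(p, F) {
    if (F == 0) return(p)
    stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  clade_of <- rep_len(seq_len(config$n_clades), B)
  clade_freqs <- matrix(p, config$n_clades, m, byrow = TRUE)
  if (config$n_clades > 1 && config$clade_F > 0) {
    for (k in seq_len(config$n_clades))
      clade_freqs[k, ] <- rbn(p, config$clade_F)
  }
  bf <- matrix(NA_real_, B, m,
               dimnames = list(sprintf("breed%02d", seq_len(B)), NULL))
  for (b in seq_len(B))
    bf[b, ] <- rbn(clade_freqs[clade_of[b], ], config$breed_F[b])
  structure(list(ancestral_freqs = p, breed_allele_freqs = bf,
                 clade_of = clade_of, qtls = config$qtls,
                 map = sim_marker_map(config)),
            class = "synthetic_truth")
}

#' Draw Hardy-Weinberg genotypes at given breed frequencies
#'
#' Each dog's dosage at each marker is Binomial(2, breed frequency):
#' independent markers, no LD. This is the substrate for differentiation
#' and association checks where linkage is not at issue; use
#' [simulate_haplotypes()] when LD and runs of homozygosity matter.
#'
#' @param truth a `synthetic_truth` from [simulate_breed_frequencies()].
#' @param config the [sim_config()].
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes_hwe <- function(truth, config) {
  set.seed(substream_seed(config$seed, "genotypes"))
  B <- nrow(truth$breed_allele_freqs); m <- ncol(truth$breed_allele_freqs)
  n <- config$dogs_per_breed
  geno <- matrix(NA_integer_, B * n, m)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * n + seq_len(n)
    geno[rows, ] <- matrix(
      stats::rbinom(n * m, 2L, rep(truth$breed_allele_freqs[b, ], each = n)),
      n, m)
  }
  breeds <- rep(rownames(truth$breed_allele_freqs), each = n)
  ids <- sprintf("%s_d%02d", breeds, rep(seq_len(n), B))
  genotype_matrix(geno,
                  data.frame(individual_id = ids, breed = breeds,
                             stringsAsFactors = FALSE),
                  truth$map)
}

# One gamete from a diploid parent: a crossover mosaic of the parent's two
# haplotype rows. `chrom_idx` is a list of marker-index vectors per
# chromosome; `chrom_pos` the matching positions; `morgans` the genetic
# length of each chromosome.
.meiose <- function(h1, h2, chrom_idx, chrom_pos, morgans) {
  gam <- h1
  for (c in seq_along(chrom_idx)) {
    idx <- chrom_idx[[c]]
    k <- stats::rpois(1L, morgans[c])
    start_second <- stats::runif(1) < 0.5
    if (k == 0L) {
      if (start_second) gam[idx] <- h2[idx]
      next
    }
    pos <- chrom_pos[[c]]
    bp <- sort(stats::runif(k, min = pos[1], max = pos[length(pos)]))
    seg <- findInterval(pos, bp)           # 0..k, constant within segments
    use2 <- (seg + start_second) %% 2L == 1L
    gam[idx[use2]] <- h2[idx[use2]]
  }
  gam
}

#' Simulate phased haplotypes and genotypes by breed formation
#'
#' Builds a shared ancestral haplotype pool by sampling alleles at the
#' ancestral frequencies with a first-order along-chromosome correlation
#' (latent copy process with correlation length
#' `ancestral_ld_length_bp`), founds each breed from a small draw of
#' founder haplotypes, propagates a closed breeding population for
#' `generations` generations of random mating with crossovers at the
#' configured map rate, and finally samples the genotyped dogs as offspring
#' of random final-generation pairs. Village dogs are drawn directly from
#' the ancestral pool (no bottleneck). The founder bottleneck produces long
#' within-breed LD and abundant long runs of homozygosity; the shared pool
#' gives only short-range between-breed LD.
#'
#' Because breed frequencies here arise from founder drift rather than the
#' Balding-Nichols draw, the returned truth's `breed_allele_freqs` are
#' replaced by the final breeding-population haplotype frequencies (the
#' frequencies the genotyped dogs converge to as `dogs_per_breed` grows).
#'
#' @param config a [sim_config()].
#' @param truth a `synthetic_truth` (its `ancestral_freqs` seed the pool).
#' @return list with `haplotypes` (a [haplotype_panel()] of breed dogs and
#'   village dogs), `genotypes` (matching [genotype_matrix()]), and the
#'   updated `truth`.
#' @export
simulate_haplotypes <- function(config, truth) {
  set.seed(substream_seed(config$seed, "haplotypes"))
  map <- truth$map
  m <- nrow(map)
  chroms <- unique(map$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(map$chrom == ch))
  chrom_pos <- lapply(chrom_idx, function(i) map$pos_bp[i])
  morgans <- vapply(chrom_pos, function(p)
    config$recomb_rate_cM_per_Mb * (p[length(p)] - p[1]) * 1e-8, 0)

  # ancestral pool: latent-uniform copy process, exact Bernoulli(p) marginals
  H <- config$ancestral_pool_size
  pool <- matrix(0L, H, m)
  p <- truth$ancestral_freqs
  for (ci in seq_along(chrom_idx)) {
    idx <- chrom_idx[[ci]]; pos <- chrom_pos[[ci]]
    u <- stats::runif(H)
    pool[, idx[1]] <- as.integer(u < p[idx[1]])
    if (length(idx) > 1L) {
      keep_p <- exp(-diff(pos) / config$ancestral_ld_length_bp)
      for (j in 2:length(idx)) {
        fresh <- stats::runif(H) >= keep_p[j - 1L]
        if (any(fresh)) u[fresh] <- stats::runif(sum(fresh))
        pool[, idx[j]] <- as.integer(u < p[idx[j]])
      }
    }
  }

  B <- config$n_breeds; n <- config$dogs_per_breed
  P <- config$breed_pop_size
  n_village <- config$village_size
  total <- B * n + n_village
  haps <- matrix(0L, 2L * total, m)
  ids <- character(total); breeds <- character(total)
  realized <- matrix(NA_real_, B, m,
                     dimnames = list(sprintf("breed%02d", seq_len(B)), NULL))

  row_of <- function(dog, copy) 2L * (dog - 1L) + copy
  dog_counter <- 0L
  for (b in seq_len(B)) {
    founders <- pool[sample.int(H, config$founder_haplotypes_per_breed), ,
                     drop = FALSE]
    nf <- nrow(founders)
    cur <- array(0L, dim = c(P, 2L, m))
    for (d in seq_len(P)) {
      pick <- sample.int(nf, 2L, replace = TRUE)
      cur[d, 1L, ] <- founders[pick[1L], ]
      cur[d, 2L, ] <- founders[pick[2L], ]
    }
    for (g in seq_len(config$generations)) {
      nxt <- array(0L, dim = c(P, 2L, m))
      for (d in seq_len(P)) {
        par <- sample.int(P, 2L, replace = FALSE)
        nxt[d, 1L, ] <- .meiose(cur[par[1L], 1L, ], cur[par[1L], 2L, ],
                                chrom_idx, chrom_pos, morgans)
        nxt[d, 2L, ] <- .meiose(cur[par[2L], 1L, ], cur[par[2L], 2L, ],
                                chrom_idx, chrom_pos, morgans)
      }
      cur <- nxt
    }
    realized[b, ] <- (colSums(cur[, 1L, ]) + colSums(cur[, 2L, ])) / (2 * P)
    for (d in seq_len(n)) {
      dog_counter <- dog_counter + 1L
      par <- sample.int(P, 2L, replace = FALSE)
      haps[row_of(dog_counter, 1L), ] <-
        .meiose(cur[par[1L], 1L, ], cur[par[1L], 2L, ],
                chrom_idx, chrom_pos, morgans)
      haps[row_of(dog_counter, 2L), ] <-
        .meiose(cur[par[2L], 1L, ], cur[par[2L], 2L, ],
                chrom_idx, chrom_pos, morgans)
      ids[dog_counter] <- sprintf("breed%02d_d%02d", b, d)
      breeds[dog_counter] <- sprintf("breed%02d", b)
    }
  }
  if (n_village > 0) {
    for (d in seq_len(n_village)) {
      dog_counter <- dog_counter + 1L
      pick <- sample.int(H, 2L, replace = TRUE)
      haps[row_of(dog_counter, 1L), ] <- pool[pick[1L], ]
      haps[row_of(dog_counter, 2L), ] <- pool[pick[2L], ]
      ids[dog_counter] <- sprintf("village_d%02d", d)
      breeds[dog_counter] <- "village"
    }
  }

  geno <- haps[seq(1L, 2L * total, by = 2L), , drop = FALSE] +
          haps[seq(2L, 2L * total, by = 2L), , drop = FALSE]
  individuals <- data.frame(individual_id = ids, breed = breeds,
                            stringsAsFactors = FALSE)
  gm <- genotype_matrix(geno, individuals, map)
  panel <- haplotype_panel(haps, rep(ids, each = 2L),
                           rep(c(1L, 2L), total), map)
  truth$breed_allele_freqs <- realized
  list(haplotypes = panel, genotypes = gm, truth = truth)
}

#' Simulate phenotypes from planted QTLs
#'
#' Individual value = sum over that trait's QTLs of effect x dosage, plus
#' Normal(0, noise sd) environmental noise. When `trait_noise_sd` is `NULL`
#' the noise sd is set from the realized genetic variance so that the
#' narrow-sense heritability equals `trait_h2`. Traits with a
#' dichotomizing threshold are emitted as 0/1 by thresholding the noisy
#' liability.
#'
#' @param config a [sim_config()].
#' @param genotypes a [genotype_matrix()].
#' @param truth a `synthetic_truth` carrying the QTL table.
#' @return list with `phenotypes` (phenotype `data.frame` with
#'   `age_years = 5` for all dogs) and the `truth` updated with
#'   `true_breed_means` (breed x trait genetic means) and
#'   `trait_noise_sd_used`.
#' @export
simulate_phenotypes <- function(config, genotypes, truth) {
  set.seed(substream_seed(config$seed, "phenotypes"))
  qtls <- truth$qtls
  g <- genotypes$geno
  out <- list(); noise_used <- numeric(0)
  tbm <- list()
  for (tr in unique(qtls$trait)) {
    qt <- qtls[qtls$trait == tr, , drop = FALSE]
    dos <- g[, qt$marker_index, drop = FALSE]
    if (anyNA(dos)) {
      mu <- colMeans(dos, na.rm = TRUE)
      for (j in seq_len(ncol(dos))) dos[is.na(dos[, j]), j] <- mu[j]
    }
    score <- as.vector(dos %*% qt$effect)
    sdv <- config$trait_noise_sd
    if (is.null(sdv)) {
      vg <- stats::var(score)
      sdv <- sqrt(max(vg, .Machine$double.eps) *
                  (1 - config$trait_h2) / config$trait_h2)
    }
    y <- score + stats::rnorm(length(score), 0, sdv)
    thr <- qt$threshold[1]
    if (!is.na(thr)) y <- as.numeric(y > thr)
    out[[tr]] <- data.frame(individual_id = genotypes$individuals$individual_id,
                            breed = genotypes$individuals$breed,
                            trait = tr, value = y, age_years = 5,
                            stringsAsFactors = FALSE)
    noise_used[tr] <- sdv
    tbm[[tr]] <- tapply(score, genotypes$individuals$breed, mean)
  }
  phenos <- do.call(rbind, out)
  rownames(phenos) <- NULL
  truth$true_breed_means <- do.call(cbind, tbm)
  truth$trait_noise_sd_used <- noise_used
  list(phenotypes = phenos, truth = truth)
}

#' Plant autozygous tracts into a genotype matrix
#'
#' Inside each planted segment the individual's genotypes are forced
#' homozygous by copying one allele of the heterozygous pair (the allele is
#' chosen at random), after which each marker in the segment is flipped to
#' heterozygous with probability `error_rate`, emulating genotyping error.
#'
#' @param genotypes a [genotype_matrix()].
#' @param segments `data.frame` with columns `individual_id`, `chrom`,
#'   `start_bp`, `end_bp` (1-based inclusive); segments of one individual
#'   must not overlap.
#' @param error_rate per-marker heterozygous-flip probability.
#' @param seed integer seed.
#' @return The modified [genotype_matrix()].
#' @export
plant_autozygosity <- function(genotypes, segments, error_rate = 0,
                               seed = 1) {
  if (nrow(segments) == 0L) return(genotypes)
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  map <- genotypes$map
  for (ind in unique(segments$individual_id)) {
    s <- segments[segments$individual_id == ind, , drop = FALSE]
    for (ch in unique(s$chrom)) {
      sc <- s[s$chrom == ch, , drop = FALSE]
      sc <- sc[order(sc$start_bp), , drop = FALSE]
      if (nrow(sc) > 1L && any(sc$start_bp[-1L] <= sc$end_bp[-nrow(sc)]))
        stop("overlapping planted segments for individual ", ind,
             " on ", ch)
      if (any(sc$end_bp > max(map$pos_bp[map$chrom == ch])) ||
          any(sc$start_bp < 1))
        stop("planted segment outside chromosome bounds on ", ch)
    }
  }
  set.seed(seed)
  g <- genotypes$geno
  rows <- match(segments$individual_id, genotypes$individuals$individual_id)
  if (anyNA(rows)) stop("unknown individual in planted segments")
  for (k in seq_len(nrow(segments))) {
    cols <- which(map$chrom == segments$chrom[k] &
                  map$pos_bp >= segments$start_bp[k] &
                  map$pos_bp <= segments$end_bp[k])
    if (length(cols) == 0L) next
    gi <- g[rows[k], cols]
    het <- which(!is.na(gi) & gi == 1L)
    if (length(het))
      gi[het] <- 2L * stats::rbinom(length(het), 1L, 0.5)
    err <- which(!is.na(gi) & stats::runif(length(gi)) < error_rate)
    if (length(err)) gi[err] <- 1L
    g[rows[k], cols] <- gi
  }
  genotypes$geno <- g
  genotypes
}

#' Sample non-overlapping segments to plant
#'
#' Draws, for each individual, `n_per_individual` marker runs of random
#' length (in SNPs) and converts them to bp segments; runs are separated by
#' at least `gap_snps` markers so planted tracts are well separated.
#'
#' @param map a [marker_map()].
#' @param individual_ids individuals to plant into.
#' @param n_per_individual segments per individual.
#' @param min_snps,max_snps run length range in markers.
#' @param gap_snps minimum separation between runs, in markers.
#' @param seed integer seed.
#' @return `data.frame(individual_id, chrom, start_bp, end_bp, n_snps)`.
#' @export
sample_planted_segments <- function(map, individual_ids,
                                    n_per_individual = 5,
                                    min_snps = 30, max_snps = 60,
                                    gap_snps = 10, seed = 1) {
  set.seed(seed)
  chroms <- unique(map$chrom)
  idx_by_chrom <- lapply(chroms, function(ch) which(map$chrom == ch))
  out <- list()
  for (ind in individual_ids) {
    placed <- list()
    attempts <- 0L
    while (length(placed) < n_per_individual && attempts < 1000L) {
      attempts <- attempts + 1L
      ci <- sample.int(length(chroms), 1L)
      idx <- idx_by_chrom[[ci]]
      len <- sample(min_snps:max_snps, 1L)
      if (length(idx) < len) next
      start <- sample.int(length(idx) - len + 1L, 1L)
      lo <- start - gap_snps; hi <- start + len - 1L + gap_snps
      clash <- any(vapply(placed, function(p)
        p$ci == ci && !(hi < p$lo || lo > p$hi), TRUE))
      if (clash) next
      placed[[length(placed) + 1L]] <-
        list(ci = ci, lo = lo, hi = hi, start = start, len = len)
    }
    for (p in placed) {
      idx <- idx_by_chrom[[p$ci]]
      cols <- idx[p$start:(p$start + p$len - 1L)]
      out[[length(out) + 1L]] <-
        data.frame(individual_id = ind, chrom = chroms[p$ci],
                   start_bp = map$pos_bp[cols[1L]],
                   end_bp = map$pos_bp[cols[length(cols)]],
                   n_snps = p$len, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
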