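# Two-state HMM for autozygosity along a genome. The autozygous state
# emits a heterozygote only through genotyping error; the non-autozygous
# state emits Hardy-Weinberg genotype probabilities. Transitions honor the
# stated stationary priors and the genetic map rate.

#' HMM parameters for autozygosity detection
#'
#' Defaults follow the field's standard settings for SNP-array data:
#' recombination rate 1.0 cM/Mb, genotyping error rate 0.5%, prior
#' probabilities of autozygosity and non-autozygosity of 20% and 80%
#' (imposed as the stationary distribution of the chain), and a segment
#' filter keeping runs >100 kb spanning at least 25 SNPs.
#'
#' @param prior_auto,prior_non stationary probabilities of the two states;
#'   must sum to 1.
#' @param genotype_error per-genotype error probability.
#' @param recomb_rate_cM_per_Mb genetic map rate used for transitions.
#' @param rate_multiplier multiplier k on the map distance in the switch
#'   probability `1 - exp(-k * d * rho)`.
#' @param min_segment_bp called segments must span more than this many bp.
#' @param min_segment_snps called segments must contain at least this many
#'   markers.
#' @param posterior_threshold markers with posterior above this belong to a
#'   run.
#' @return list of class `hmm_params`.
#' @export
hmm_params <- function(prior_auto = 0.20, prior_non = 0.80,
                       genotype_error = 0.005,
                       recomb_rate_cM_per_Mb = 1.0,
                       rate_multiplier = 1.0,
                       min_segment_bp = 100000L,
                       min_segment_snps = 25L,
                       posterior_threshold = 0.5) {
  if (abs(prior_auto + prior_non - 1) > 1e-12)
    stop("prior_auto + prior_non must equal 1")
  probs <- c(prior_auto, prior_non, genotype_error, posterior_threshold)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  structure(list(prior_auto = prior_auto, prior_non = prior_non,
                 genotype_error = genotype_error,
                 recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
                 rate_multiplier = rate_multiplier,
                 min_segment_bp = as.numeric(min_segment_bp),
                 min_segment_snps = as.integer(min_segment_snps),
                 posterior_threshold = posterior_threshold),
            class = "hmm_params")
}

# Emission likelihoods for a genotype dosage matrix (individuals x markers)
# at allele frequencies `freq` (frequency of the dosage-counted allele).
# Missing genotypes and monomorphic/unknown-frequency markers contribute
# likelihood 1 in both states.
.emissions <- function(g, freq, error) {
  n <- nrow(g); m <- ncol(g)
  p <- matrix(freq, n, m, byrow = TRUE)
  e_non <- matrix(1, n, m); e_auto <- matrix(1, n, m)
  ok <- !is.na(g) & !is.na(p) & p > 0 & p < 1
  gk <- g[ok]; pk <- p[ok]
  en <- ifelse(gk == 1L, 2 * pk * (1 - pk),
               ifelse(gk == 2L, pk^2, (1 - pk)^2))
  ea <- ifelse(gk == 1L, error * 2 * pk * (1 - pk),
               ifelse(gk == 2L, (1 - error) * pk, (1 - error) * (1 - pk)))
  e_non[ok] <- en; e_auto[ok] <- ea
  list(auto = e_auto, non = e_non)
}

# Scaled forward-backward over one chromosome for all individuals at once.
# `t_switch[j]` is the switch intensity 1-exp(-k*d*rho) over the gap
# between markers j and j+1; transitions are stationary-weighted.
.fb_chrom <- function(e_auto, e_non, t_switch, prior_auto, prior_non) {
  n <- nrow(e_auto); m <- ncol(e_auto)
  t_an <- prior_non * t_switch   # auto -> non
  t_na <- prior_auto * t_switch  # non -> auto
  A <- matrix(0, n, m); N <- matrix(0, n, m)
  sc <- matrix(0, n, m)
  a <- prior_auto * e_auto[, 1L]; b <- prior_non * e_non[, 1L]
  s <- a + b; a <- a / s; b <- b / s
  A[, 1L] <- a; N[, 1L] <- b; sc[, 1L] <- s
  if (m > 1L) for (j in 2:m) {
    a2 <- (a * (1 - t_an[j - 1L]) + b * t_na[j - 1L]) * e_auto[, j]
    b2 <- (a * t_an[j - 1L] + b * (1 - t_na[j - 1L])) * e_non[, j]
    s <- a2 + b2
    a <- a2 / s; b <- b2 / s
    A[, j] <- a; N[, j] <- b; sc[, j] <- s
  }
  # backward, using the forward scaling factors
  post <- matrix(0, n, m)
  ba <- rep(1, n); bn <- rep(1, n)
  num_a <- A[, m] * ba; num_n <- N[, m] * bn
  post[, m] <- num_a / (num_a + num_n)
  if (m > 1L) for (j in (m - 1L):1L) {
    ea <- e_auto[, j + 1L] * ba; en <- e_non[, j + 1L] * bn
    ba2 <- ((1 - t_an[j]) * ea + t_an[j] * en) / sc[, j + 1L]
    bn2 <- (t_na[j] * ea + (1 - t_na[j]) * en) / sc[, j + 1L]
    ba <- ba2; bn <- bn2
    num_a <- A[, j] * ba; num_n <- N[, j] * bn
    post[, j] <- num_a / (num_a + num_n)
  }
  post
}

#' Autozygosity posteriors for all individuals
#'
#' Forward-backward posterior probability of the autozygous state at every
#' marker, each chromosome processed independently. Emission allele
#' frequencies default to the full-cohort per-marker frequency.
#'
#' @param genotypes a [genotype_matrix()].
#' @param allele_freqs optional per-marker frequency vector (of the
#'   dosage-counted allele); defaults to cohort frequencies.
#' @param params an [hmm_params()].
#' @return individuals x markers matrix of posterior probabilities.
#' @export
hmm_posteriors_all <- function(genotypes, allele_freqs = NULL,
                               params = hmm_params()) {
  map <- genotypes$map
  for (ch in unique(map$chrom)) {
    p <- map$pos_bp[map$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("marker map not sorted within chromosome ", ch)
  }
  if (is.null(allele_freqs)) allele_freqs <- marker_freq(genotypes)$freq
  if (length(allele_freqs) != ncol(genotypes$geno))
    stop("allele_freqs length != marker count")
  rho <- params$recomb_rate_cM_per_Mb * 1e-8  # Morgans per bp
  post <- matrix(NA_real_, nrow(genotypes$geno), ncol(genotypes$geno),
                 dimnames = dimnames(genotypes$geno))
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    em <- .emissions(genotypes$geno[, idx, drop = FALSE],
                     allele_freqs[idx], params$genotype_error)
    d <- diff(map$pos_bp[idx])
    t_switch <- 1 - exp(-params$rate_multiplier * d * rho)
    post[, idx] <- .fb_chrom(em$auto, em$non, t_switch,
                             params$prior_auto, params$prior_non)
  }
  post
}

#' Autozygosity posteriors for one individual
#'
#' @inheritParams hmm_posteriors_all
#' @param individual_id the individual to decode.
#' @return numeric vector of per-marker posterior probabilities.
#' @export
hmm_posteriors <- function(genotypes, allele_freqs = NULL,
                           params = hmm_params(), individual_id) {
  i <- match(individual_id, genotypes$individuals$individual_id)
  if (is.na(i)) stop("individual not found: ", individual_id)
  if (is.null(allele_freqs)) allele_freqs <- marker_freq(genotypes)$freq
  sub <- genotypes
  sub$geno <- genotypes$geno[i, , drop = FALSE]
  sub$individuals <- genotypes$individuals[i, , drop = FALSE]
  drop(hmm_posteriors_all(sub, allele_freqs, params))
}

#' Call autozygous segments from a posterior vector
#'
#' Maximal runs of consecutive same-chromosome markers with posterior above
#' the threshold; runs are kept if they span more than `min_segment_bp` and
#' contain at least `min_segment_snps` markers. Segment endpoints are the
#' positions of the first and last marker of the run.
#'
#' @param posteriors per-marker posterior vector (aligned to `map`).
#' @param map a [marker_map()].
#' @param params an [hmm_params()].
#' @param individual_id id recorded on the output rows.
#' @return `data.frame(individual_id, chrom, start_bp, end_bp, n_snps,
#'   mean_posterior, span_bp)`.
#' @export
call_segments <- function(posteriors, map, params = hmm_params(),
                          individual_id = NA_character_) {
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    above <- posteriors[idx] > params$posterior_threshold
    above[is.na(above)] <- FALSE
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- idx[starts[k]:ends[k]]
      span <- map$pos_bp[run[length(run)]] - map$pos_bp[run[1L]] + 1
      if (span > params$min_segment_bp &&
          length(run) >= params$min_segment_snps) {
        out[[length(out) + 1L]] <- data.frame(
          individual_id = individual_id, chrom = ch,
          start_bp = map$pos_bp[run[1L]],
          end_bp = map$pos_bp[run[length(run)]],
          n_snps = length(run),
          mean_posterior = mean(posteriors[run]),
          span_bp = span, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(individual_id = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), mean_posterior = numeric(),
                      span_bp = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Posteriors and called segments for a whole cohort
#'
#' Convenience wrapper: runs [hmm_posteriors_all()] then [call_segments()]
#' per individual, and summarizes per-individual autozygosity as the
#' fraction of the mapped genome covered by called segments.
#'
#' @inheritParams hmm_posteriors_all
#' @return list with `posteriors` (matrix), `segments` (`data.frame`), and
#'   `per_individual_autozygosity` (named vector).
#' @export
autozygosity_scan <- function(genotypes, allele_freqs = NULL,
                              params = hmm_params()) {
  post <- hmm_posteriors_all(genotypes, allele_freqs, params)
  map <- genotypes$map
  ids <- genotypes$individuals$individual_id
  segs <- lapply(seq_along(ids), function(i)
    call_segments(post[i, ], map, params, ids[i]))
  segs <- do.call(rbind, segs)
  genome_bp <- sum(tapply(map$pos_bp, map$chrom,
                          function(p) max(p) - min(p) + 1))
  frac <- vapply(ids, function(id) {
    s <- segs[segs$individual_id == id, , drop = FALSE]
    sum(s$span_bp) / genome_bp
  }, 0)
  list(posteriors = post, segments = segs,
       per_individual_autozygosity = frac)
}

#' SNP quality filter: heterozygosity inside autozygous segments
#'
#' Genotypes inside a (correctly inferred) autozygous segment should be
#' homozygous apart from genotyping error, so markers showing an excess of
#' heterozygous calls among segment-covered individuals are flagged as
#' poorly genotyped and excluded. Markers covered by no segment cannot be
#' tested and are kept with status "untested".
#'
#' @param genotypes a [genotype_matrix()].
#' @param segments called segments for the whole cohort (as from
#'   [autozygosity_scan()]).
#' @param max_het_rate markers with het rate above this are excluded.
#' @return list with `kept` and `excluded` marker-id vectors and `table`,
#'   a per-marker `data.frame(marker_id, n_covered, n_het, het_rate,
#'   status)` with status in keep/excluded/untested.
#' @export
filter_snps_by_het_in_auto <- function(genotypes, segments,
                                       max_het_rate = 0.10) {
  map <- genotypes$map
  m <- nrow(map)
  n_cov <- integer(m); n_het <- integer(m)
  if (nrow(segments) > 0L) {
    rows <- match(segments$individual_id,
                  genotypes$individuals$individual_id)
    for (k in seq_len(nrow(segments))) {
      cols <- which(map$chrom == segments$chrom[k] &
                    map$pos_bp >= segments$start_bp[k] &
                    map$pos_bp <= segments$end_bp[k])
      if (length(cols) == 0L) next
      g <- genotypes$geno[rows[k], cols]
      called <- !is.na(g)
      n_cov[cols] <- n_cov[cols] + called
      n_het[cols] <- n_het[cols] + (called & g == 1L)
    }
  }
  rate <- ifelse(n_cov > 0L, n_het / n_cov, NA_real_)
  status <- ifelse(n_cov == 0L, "untested",
                   ifelse(rate > max_het_rate, "excluded", "keep"))
  tab <- data.frame(marker_id = map$marker_id, n_covered = n_cov,
                    n_het = n_het, het_rate = rate, status = status,
                    stringsAsFactors = FALSE)
  list(kept = map$marker_id[status != "excluded"],
       excluded = map$marker_id[status == "excluded"],
       table = tab)
}

#' Per-individual run-of-homozygosity summary
#'
#' Counts, for each individual, called segments whose span exceeds each
#' threshold, and the fraction of the mapped genome covered by segments.
#'
#' @param segments segment `data.frame` (needs `individual_id`, `span_bp`).
#' @param individual_ids full individual list (so dogs with no segments get
#'   zero counts).
#' @param thresholds_bp span thresholds; defaults 1 Mb and 10 Mb.
#' @param genome_bp total mapped genome length for the fraction; `NA` skips
#'   the fraction column.
#' @return `data.frame` with one row per individual.
#' @export
roh_summary <- function(segments, individual_ids,
                        thresholds_bp = c(1e6, 1e7), genome_bp = NA) {
  out <- data.frame(individual_id = individual_ids,
                    stringsAsFactors = FALSE)
  for (t in thresholds_bp) {
    cnt <- vapply(individual_ids, function(id)
      sum(segments$individual_id == id & segments$span_bp > t), 0L)
    out[[sprintf("n_roh_gt_%g", t)]] <- cnt
  }
  if (!is.na(genome_bp)) {
    out$genome_fraction <- vapply(individual_ids, function(id)
      sum(segments$span_bp[segments$individual_id == id]) / genome_bp, 0)
  }
  rownames(out) <- NULL
  out
}
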