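# Independent reference implementations used as oracles. These are written
# directly from the published definitions, in deliberately plain loop form,
# and share no code with the package internals.

# Posterior P(autozygous) at every marker of a single chain, by exhaustive
# enumeration of all 2^m state paths. State 1 = autozygous, 2 = not.
enum_hmm_posterior <- function(g, freq, pos, par) {
  m <- length(g)
  emit <- function(state, j) {
    p <- freq[j]
    if (is.na(g[j]) || is.na(p) || p <= 0 || p >= 1) return(1)
    if (state == 1L) {
      if (g[j] == 1L) par$genotype_error * 2 * p * (1 - p)
      else if (g[j] == 2L) (1 - par$genotype_error) * p
      else (1 - par$genotype_error) * (1 - p)
    } else {
      if (g[j] == 1L) 2 * p * (1 - p)
      else if (g[j] == 2L) p^2
      else (1 - p)^2
    }
  }
  rho <- par$recomb_rate_cM_per_Mb * 1e-8
  sw <- 1 - exp(-par$rate_multiplier * diff(pos) * rho)
  trans <- function(s1, s2, j) {
    if (s1 == 1L) {
      if (s2 == 1L) 1 - par$prior_non * sw[j] else par$prior_non * sw[j]
    } else {
      if (s2 == 1L) par$prior_auto * sw[j] else 1 - par$prior_auto * sw[j]
    }
  }
  prior <- c(par$prior_auto, par$prior_non)
  paths <- as.matrix(expand.grid(rep(list(1:2), m)))
  pr <- apply(paths, 1L, function(s) {
    v <- prior[s[1L]] * emit(s[1L], 1L)
    if (m > 1L) for (j in 2:m) v <- v * trans(s[j - 1L], s[j], j - 1L) *
                                     emit(s[j], j)
    v
  })
  vapply(seq_len(m), function(j) sum(pr[paths[, j] == 1L]) / sum(pr), 0)
}

# Weir & Cockerham (1984) multi-population theta-hat for one marker,
# written directly from the published variance components a, b, c. Populations with
# fewer than two called genotypes are dropped; NA when fewer than two
# populations remain or the denominator vanishes.
wc_theta_oracle <- function(geno_col, pop_labels) {
  sp <- split(geno_col, pop_labels)
  sp <- lapply(sp, function(v) v[!is.na(v)])
  sp <- sp[vapply(sp, length, 0L) >= 2L]
  r <- length(sp)
  if (r < 2L) return(NA_real_)
  ni <- vapply(sp, length, 0)
  pi <- vapply(sp, function(v) sum(v) / (2 * length(v)), 0)
  hi <- vapply(sp, function(v) mean(v == 1L), 0)
  nbar <- mean(ni)
  nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
  pbar <- sum(ni * pi) / sum(ni)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / sum(ni)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  if (!is.finite(denom) || denom == 0) return(NA_real_)
  a / denom
}

# Tiny genotype container on one chromosome with evenly spaced markers.
toy_genotypes <- function(geno, spacing_bp = 1e5, breed = NULL,
                          chrom = "chr1") {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  if (is.null(breed)) breed <- rep("breedA", n)
  map <- marker_map(sprintf("s%03d", seq_len(m)), rep(chrom, m),
                    seq(1, by = spacing_bp, length.out = m))
  genotype_matrix(geno,
                  data.frame(individual_id = sprintf("d%03d", seq_len(n)),
                             breed = breed, stringsAsFactors = FALSE),
                  map)
}

# Overlap in bp of one interval [s, e] with a set of intervals (both
# 1-based inclusive); intervals assumed non-overlapping.
interval_overlap_bp <- function(s, e, starts, ends) {
  lo <- pmax(s, starts); hi <- pmin(e, ends)
  sum(pmax(hi - lo + 1, 0))
}
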