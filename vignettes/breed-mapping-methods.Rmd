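---
title: "Methods: breed-level trait mapping with breedmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breed-level trait mapping with breedmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

breedmapr implements a pipeline for mapping morphological traits across
dog breeds from modest SNP panels. The statistical leverage comes from
breed structure itself: a closed studbook makes each breed nearly
homogeneous for the trait alleles it was selected on, so breed *averages*
regressed on breed *allele frequencies* recover large-effect loci with a
few hundred dogs. The price is that every analysis must account for the
strong, hierarchical relatedness that the same history creates. This
vignette records the models, the default parameters, and the numerical
choices, in pipeline order.

## 1. The cohort simulator (`sim_*`)

All methods are validated against synthetic cohorts with planted truth.
The default design (`sim_config()`) is 50 breeds of 10 dogs plus 30
"village" dogs, genotyped at 5,000 SNPs evenly spaced on five 100-Mb
chromosomes (about 100-kb spacing).

**Allele frequencies.** Breed frequencies drift from a shared ancestral
frequency under the Balding–Nichols model: given ancestral frequency $p$
and differentiation $F$, a breed draws its frequency from
$\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$, which
has mean $p$ and variance $F\,p(1-p)$ — exactly the variance
decomposition that Weir–Cockerham $F_{ST}$ estimates. The default
$F = 0.28$ is the package's reference level of breed differentiation. A
two-level variant (`n_clades`, `clade_F`, then `breed_F` within clade)
produces the hierarchical structure used to stress-test association
calibration.

**Haplotypes.** Genotypes drawn marker-by-marker from Hardy–Weinberg
carry no LD, so a second simulator builds chromosomes by a copying
process: an ancestral haplotype pool is generated with a latent-uniform
copy model (correlation length 100 kb, exact Bernoulli($p$) marginals),
each breed is founded from 10 pool haplotypes, and a population of 20
dogs is recombined for 8 generations with Poisson crossovers at
1 cM/Mb. This yields long within-breed haplotypes, megabase-scale LD,
and runs of homozygosity; village dogs are drawn directly from the pool
and show none of these. The small founder number and short pedigree are
deliberate: they reproduce the qualitative contrast (long LD and long
ROH inside breeds, rapid decay outside) without simulating full
population genetics.

**Phenotypes.** A trait is a sum of planted QTL dosage effects (defaults:
three QTLs with effects in ratio 4:2:1) plus Gaussian noise scaled so
narrow-sense heritability is 0.9 — appropriate for highly heritable
morphology. Dichotomous traits threshold the liability.

**Reproducibility.** Every stage derives its seed from the master seed
via a fixed affine substream map (`substream_seed`), so stages can be
re-run independently and all seeds stay below $2^{31}$.

## 2. Autozygosity HMM (`hmm_*`, `autozygosity_scan`)

Autozygosity is decoded per dog with a two-state HMM (autozygous /
non-autozygous) over ordered markers.

* **Emissions.** Non-autozygous markers emit Hardy–Weinberg genotype
  probabilities from cohort allele frequencies. Autozygous markers emit
  a heterozygote only through genotyping error,
  $P(\text{het}) = \varepsilon \cdot 2pq$, and homozygotes with
  probability $(1-\varepsilon)$ times the allele frequency. Missing
  genotypes emit 1 in both states.
* **Transitions.** Between adjacent markers at recombination distance
  $d$ (bp) the chance of leaving the current state is
  $\pi_{\text{other}}\left(1 - e^{-k d \rho}\right)$ with
  $\rho = 1\,\text{cM/Mb} \times 10^{-8}$ per bp and rate multiplier
  $k$; the stationary weights $\pi = (0.2, 0.8)$ are also the initial
  distribution.
* **Decoding.** Scaled forward–backward, vectorized across dogs;
  correctness is pinned by tests against exhaustive enumeration over all
  $2^m$ state paths on short chains (max error below $10^{-10}$).
* **Segments.** Runs of posterior $> 0.5$ become segments if they span
  more than 100 kb *and* contain at least 25 SNPs. The joint filter
  discards both dense spurious blips and sparse long gaps.

`filter_snps_by_het_in_auto` flags markers that are heterozygous too
often *inside* called autozygous tracts (default: strictly above 10% of
covered dogs) — such markers are almost surely assay failures, since
true autozygosity forbids heterozygosity up to genotyping error.

## 3. Diversity and differentiation (`ld_decay`, `haplotype_diversity`, `weir_fst`)

**LD decay** computes $r^2$ between SNP-pair dosages (MAF $\ge 0.15$,
up to 10 dogs per population) and averages it in distance bins. Bins are
half-open on the left, $(\text{low}, \text{high}]$, so a pair exactly on
a bin edge belongs to the lower bin; `ld_at` uses the same convention,
keeping curve and look-up consistent. With the default ~100-kb marker
spacing, adjacent-pair distances cluster just above multiples of 100 kb,
so bins should be no finer than ~250 kb or some bins are empty.

**Haplotype diversity** counts distinct haplotypes per 500-kb window
(subsampling 15 SNPs, or 5 where fewer are available, and 10 dogs per
breed) — the classic window view in which breeds carry a handful of
haplotypes where village dogs carry many.

**$F_{ST}$** is the Weir–Cockerham (1984) variance-components estimator
$\hat\theta = a / (a + b + c)$ per SNP, requiring at least two breeds
with two called genotypes each; monomorphic or under-called SNPs are
reported with a status rather than silently dropped. Under flat
Balding–Nichols drift the across-marker mean of $\hat\theta$ is close to
the generating $F$, which the tests verify. `fst_regions` flags outlier
SNPs (default $\hat\theta \ge 0.55$, MAF $\ge 0.15$) and extends each
into a region by absorbing flanking SNPs above the 95th percentile of
the genome-wide distribution, merging overlaps; singleton regions are
legitimate output.

## 4. Breed-average association (`lmm_assoc`, `naive_assoc`, `weighted_bootstrap_assoc`)

The quantitative-trait scan regresses breed mean phenotype on breed
allele frequency, one SNP at a time, in a linear mixed model
$y = X\beta + u + e$, $u \sim N(0, \sigma_g^2 K)$ with $K$ the
breed-averaged identity-by-state matrix. The variance ratio
$\delta = \sigma_e^2/\sigma_g^2$ is estimated by exact REML in the
eigenbasis of $K$ (EMMA-style: grid over $10^{-5}$–$10^{5}$ plus local
optimization), and each SNP is tested by generalized least squares.

Numerical choices:

* Eigenvalues of $K$ are clamped at $10^{-8}$; breed-averaged IBS
  matrices are near-singular when breeds are highly differentiated.
* By default $\delta$ is estimated once under the null model and reused
  for every SNP (`delta_method = "null_model"`). Re-estimating per
  marker is available but measurably anti-conservative at $n \approx 50$
  breeds, where each marker's REML fit can absorb polygenic variance.
* `naive_assoc` (plain OLS) is kept as the comparison scan: identical to
  the LMM when $K = I$ (a test pins this to $10^{-8}$), badly inflated
  under clade structure.

For dichotomous traits scored on individuals, the package provides a
relatedness-weighted bootstrap: each replicate rebuilds the phenotype
vector by letting every dog copy the phenotype of a donor drawn with
probability proportional to its kinship row, then recomputes the
association statistic (absolute correlation between phenotype and the
dog-expanded breed frequency); the p-value is $(1 + \#\{ \text{replicate}
\ge \text{observed}\})/(B+1)$. One donor set is shared across markers so
the null ensemble is coherent genome-wide. Because donors are drawn by
raw IBS weights, replicates under exchangeable kinship are mildly
attenuated copies of a null draw and the test runs slightly
conservative at small $\alpha$ — the safe direction. The convention for
using it is that phenotypes vary at the individual level; a phenotype
constant within breeds collapses the replicate ensemble onto the
observed statistic and the test degenerates.

## 5. Multi-SNP models (`forward_stepwise`, `predict`, `validate_predictions`)

`forward_stepwise` greedily adds markers (from a candidate list,
typically all SNPs ranked by LMM p-value) to a linear model of the breed
means, maximizing $R^2$ at each step; collinear additions are skipped.
Fitting at `unit = "breed"` matches the response's resolution — the
trait is a breed average, so fitting on individual dogs only dilutes
the signal with within-breed dosage noise. The $R^2$ trajectory is
non-decreasing by construction. `predict` applies the fitted linear
predictor to individual genotypes (missing dosages imputed with panel
means), and `validate_predictions` reports correlation and $R^2$
against held-out observations.

## 6. Known limitations

* The haplotype simulator is a caricature of breed history: no
  mutation, no migration, one founding event, a uniform recombination
  map. It supports method validation, not demographic inference.
* The HMM uses cohort-level allele frequencies for both states;
  breed-specific frequencies would sharpen segment boundaries.
* The mixed model treats breed means as exchangeable given $K$; it does
  not model unequal within-breed sample sizes beyond the `min_n` filter.
* The weighted bootstrap's donor weights use raw IBS rows, not a
  calibrated coalescent kernel; its p-values are conservative rather
  than exact.

## Reproducing the pipeline

```{r pipeline}
# from the repository root
source("analysis/00_config.R")        # shared seed + paths
# then run the numbered scripts in order:
#   analysis/01_simulate.R      simulate the cohort, write PLINK + phenotypes
#   analysis/02_autozygosity.R  HMM scan, ROH summaries, het-in-auto QC
#   analysis/03_popgen.R        LD decay, haplotype diversity, F_ST regions
#   analysis/04_gwas.R          breed-average LMM vs naive scan
#   analysis/05_models.R        stepwise model + held-out validation
```
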