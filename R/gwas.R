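# Breed-average association mapping: the analysis unit is the breed, the
# predictor is the breed allele frequency, and relatedness among breeds is
# controlled by a breed-averaged identity-by-state matrix, either as the
# random-effect correlation of an exact-REML linear mixed model (continuous
# traits) or as resampling weights of a weighted bootstrap (dichotomous
# traits).

#' Breed-average phenotypes
#'
#' Averages a trait over measured individuals per breed, after an age
#' filter (dogs older than `min_age_years`; records with unknown age are
#' retained). Breeds with fewer than `min_n` measured dogs are dropped. An
#' optional transform (e.g. log) is applied to individual values before
#' averaging.
#'
#' @param phenos phenotype `data.frame` (see [read_phenotypes()]).
#' @param trait trait name to average.
#' @param min_n minimum measured dogs per breed.
#' @param min_age_years strict lower age bound.
#' @param transform `NULL`, "log", or a function applied to values before
#'   averaging.
#' @return `data.frame(breed, mean_value, n_measured)` with attributes
#'   `trait` and `transform`.
#' @export
breed_averages <- function(phenos, trait, min_n = 2, min_age_years = 1.0,
                           transform = NULL) {
  d <- phenos[phenos$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("trait not present: ", trait)
  keep <- is.na(d$age_years) | d$age_years > min_age_years
  d <- d[keep, , drop = FALSE]
  tf <- if (is.null(transform)) identity
        else if (is.character(transform) && transform == "log") log
        else if (is.function(transform)) transform
        else stop("transform must be NULL, 'log', or a function")
  d$value <- tf(d$value)
  n <- tapply(d$value, d$breed, length)
  mu <- tapply(d$value, d$breed, mean)
  ok <- n >= min_n
  if (!any(ok)) stop("no breed has >= ", min_n, " measured dogs for ", trait)
  out <- data.frame(breed = names(mu)[ok], mean_value = as.numeric(mu[ok]),
                    n_measured = as.integer(n[ok]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "trait") <- trait
  attr(out, "transform") <-
    if (is.character(transform)) transform
    else if (is.null(transform)) "none" else "custom"
  out
}

#' Individual-by-individual IBS similarity matrix
#'
#' IBS(i, j) = mean over markers non-missing in both dogs of
#' `(2 - |g_i - g_j|) / 2`; the diagonal is 1 by definition.
#'
#' @param genotypes a [genotype_matrix()].
#' @return symmetric n x n matrix with individual ids as dimnames.
#' @export
ibs_kinship <- function(genotypes) {
  g <- genotypes$geno
  if (nrow(g) < 2L) stop("need at least 2 individuals")
  called <- !is.na(g)
  A0 <- (called & g == 0L) + 0
  A1 <- (called & g == 1L) + 0
  A2 <- (called & g == 2L) + 0
  shared <- tcrossprod(called + 0)
  if (any(shared == 0)) {
    w <- which(shared == 0, arr.ind = TRUE)[1L, ]
    stop("individuals ", rownames(g)[w[1L]], " and ", rownames(g)[w[2L]],
         " share no genotyped marker")
  }
  # sum |g_i - g_j| over shared markers: het-hom pairs differ by 1,
  # opposite homozygotes by 2
  diff01 <- tcrossprod(A0, A1) + tcrossprod(A1, A0)
  diff12 <- tcrossprod(A1, A2) + tcrossprod(A2, A1)
  diff02 <- tcrossprod(A0, A2) + tcrossprod(A2, A0)
  total_diff <- diff01 + diff12 + 2 * diff02
  K <- 1 - total_diff / (2 * shared)
  dimnames(K) <- list(genotypes$individuals$individual_id,
                      genotypes$individuals$individual_id)
  K
}

#' Breed-average IBS matrix
#'
#' Off-diagonal entries average individual IBS over all cross-breed pairs;
#' the diagonal averages within-breed pairs with self-pairs excluded.
#'
#' @param K individual IBS matrix from [ibs_kinship()].
#' @param breed_labels per-individual breed labels aligned to `K` rows.
#' @return symmetric breeds x breeds matrix.
#' @export
breed_average_kinship <- function(K, breed_labels) {
  fb <- factor(breed_labels)
  ub <- levels(fb)
  Kb <- matrix(NA_real_, length(ub), length(ub), dimnames = list(ub, ub))
  idx <- split(seq_along(breed_labels), fb)
  for (i in seq_along(ub)) for (j in i:length(ub)) {
    block <- K[idx[[i]], idx[[j]], drop = FALSE]
    if (i == j) {
      nb <- length(idx[[i]])
      if (nb < 2L) { Kb[i, i] <- 1; next }
      Kb[i, i] <- (sum(block) - sum(diag(block))) / (nb * (nb - 1L))
    } else {
      Kb[i, j] <- Kb[j, i] <- mean(block)
    }
  }
  Kb
}

# REML log-likelihood (up to a delta-free constant) of the rotated model
# y* = X* beta + e, Var(e) = sigma_g^2 (D + delta I). Returns the profile
# value and, on request, the GLS fit.
.reml_ll <- function(delta, d, ystar, Xstar, fit = FALSE) {
  v <- d + delta
  w <- 1 / v
  Xw <- Xstar * w
  XtWX <- crossprod(Xstar, Xw)
  XtWy <- crossprod(Xw, ystar)
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(if (fit) NULL else -Inf)
  beta <- backsolve(ch, backsolve(ch, XtWy, transpose = TRUE))
  res <- ystar - Xstar %*% beta
  rss <- sum(w * res^2)
  n <- length(ystar); p <- ncol(Xstar)
  ll <- -0.5 * ((n - p) * log(max(rss, 1e-300)) + sum(log(v)) +
                2 * sum(log(diag(ch))))
  if (!fit) return(ll)
  sigma2 <- rss / (n - p)
  XtWXinv <- chol2inv(ch)
  list(ll = ll, beta = drop(beta), sigma2 = sigma2,
       se = sqrt(pmax(sigma2 * diag(XtWXinv), 0)), df = n - p)
}

#' Breed-level mixed-model association scan
#'
#' Per marker, fits `y = mu + beta * freq + C gamma + u + e` over breeds,
#' with `u ~ MVN(0, sigma_g^2 K)` and `e ~ MVN(0, sigma_e^2 I)`. The
#' variance ratio `delta = sigma_e^2 / sigma_g^2` is estimated by
#' maximizing the exact restricted likelihood over a log-spaced grid
#' refined by local optimization, reusing one spectral decomposition of
#' `K` across all markers. By default (`delta_method = "null_model"`) the
#' ratio is estimated once under the covariate-only null model and reused
#' for every marker; at breed-level sample sizes this keeps the test
#' calibrated even when marker frequencies themselves correlate with the
#' kinship structure, where re-estimating the ratio per marker
#' (`delta_method = "per_marker"`, the classical exact-REML scan) is
#' measurably anti-conservative. The p-value comes from the t statistic
#' on beta with `n - p` degrees of freedom; when `K` is the identity both
#' variants reduce exactly to ordinary least squares. Eigenvalues of `K`
#' below 1e-8 are clamped to 1e-8 so nearly singular breed-average IBS
#' matrices remain usable.
#'
#' @param breed_freqs breeds x markers allele-frequency matrix with breed
#'   rownames and marker colnames.
#' @param y breed phenotype: a `data.frame` from [breed_averages()] or a
#'   named numeric vector.
#' @param K_breed breed-level kinship (correlation) matrix.
#' @param covariates optional named numeric vector or breeds x q matrix of
#'   per-breed covariates (e.g. log breed-average body weight).
#' @param min_breeds minimum number of phenotyped breeds.
#' @param delta_method estimate the variance ratio once under the null
#'   model ("null_model", default) or separately per marker
#'   ("per_marker").
#' @return `data.frame(marker_id, beta, se, stat, p_value, delta, reml_ll,
#'   method)` with attribute `bonferroni` (0.05 / markers tested). Skipped
#'   (monomorphic) markers carry `NA` statistics.
#' @export
lmm_assoc <- function(breed_freqs, y, K_breed, covariates = NULL,
                      min_breeds = 10,
                      delta_method = c("null_model", "per_marker")) {
  delta_method <- match.arg(delta_method)
  if (is.data.frame(y)) y <- stats::setNames(y$mean_value, y$breed)
  breeds <- intersect(rownames(breed_freqs), names(y))
  breeds <- intersect(breeds, rownames(K_breed))
  if (!is.null(covariates)) {
    if (is.null(dim(covariates)))
      covariates <- matrix(covariates, ncol = 1,
                           dimnames = list(names(covariates), "cov1"))
    breeds <- intersect(breeds, rownames(covariates))
  }
  n <- length(breeds)
  if (n < min_breeds)
    stop("only ", n, " breeds with phenotype, kinship and frequencies; ",
         "need >= ", min_breeds)
  yv <- y[breeds]
  Fq <- breed_freqs[breeds, , drop = FALSE]
  K <- K_breed[breeds, breeds]
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eig$values, 1e-8)
  U <- eig$vectors
  ystar <- drop(crossprod(U, yv))
  X0 <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) X0 <- cbind(X0, covariates[breeds, , drop = FALSE])
  X0star <- crossprod(U, X0)
  m <- ncol(Fq)
  out <- data.frame(marker_id = colnames(Fq) %||% sprintf("m%d", seq_len(m)),
                    beta = NA_real_, se = NA_real_, stat = NA_real_,
                    p_value = NA_real_, delta = NA_real_,
                    reml_ll = NA_real_,
                    method = "lmm", stringsAsFactors = FALSE)
  const_y <- stats::var(yv) == 0
  grid <- 10^seq(-5, 5, length.out = 41)
  reml_max <- function(Xstar) {
    lls <- vapply(grid, .reml_ll, 0, d = d, ystar = ystar, Xstar = Xstar)
    k <- which.max(lls)
    lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
    opt <- stats::optimize(function(ld) .reml_ll(exp(ld), d, ystar, Xstar),
                           lower = log(lo), upper = log(hi), maximum = TRUE,
                           tol = 1e-6)
    if (opt$objective >= lls[k]) exp(opt$maximum) else grid[k]
  }
  delta_null <- if (delta_method == "null_model" && !const_y)
    reml_max(X0star) else NA_real_
  for (j in seq_len(m)) {
    x <- Fq[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (stats::var(x) == 0) next
    if (const_y) {
      out$beta[j] <- 0; out$stat[j] <- 0; out$p_value[j] <- 1
      next
    }
    Xstar <- cbind(X0star, freq = drop(crossprod(U, x)))
    delta <- if (delta_method == "per_marker") reml_max(Xstar)
             else delta_null
    ft <- .reml_ll(delta, d, ystar, Xstar, fit = TRUE)
    if (is.null(ft)) next
    b <- ft$beta[length(ft$beta)]
    se <- ft$se[length(ft$se)]
    tt <- if (se > 0) b / se else 0
    out$beta[j] <- b; out$se[j] <- se; out$stat[j] <- tt
    out$p_value[j] <- 2 * stats::pt(-abs(tt), df = ft$df)
    out$delta[j] <- delta; out$reml_ll[j] <- ft$ll
  }
  attr(out, "bonferroni") <- 0.05 / sum(!is.na(out$p_value))
  attr(out, "breeds_used") <- breeds
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Naive breed-level regression scan
#'
#' Ordinary least-squares regression of breed phenotype on breed allele
#' frequency (plus optional covariates), ignoring breed relatedness. Used
#' as the comparison arm for the mixed model.
#'
#' @inheritParams lmm_assoc
#' @return `data.frame` like [lmm_assoc()] with `method = "naive"`.
#' @export
naive_assoc <- function(breed_freqs, y, covariates = NULL,
                        min_breeds = 10) {
  if (is.data.frame(y)) y <- stats::setNames(y$mean_value, y$breed)
  breeds <- intersect(rownames(breed_freqs), names(y))
  if (!is.null(covariates)) {
    if (is.null(dim(covariates)))
      covariates <- matrix(covariates, ncol = 1,
                           dimnames = list(names(covariates), "cov1"))
    breeds <- intersect(breeds, rownames(covariates))
  }
  n <- length(breeds)
  if (n < min_breeds)
    stop("only ", n, " breeds with phenotype and frequencies; need >= ",
         min_breeds)
  yv <- y[breeds]
  Fq <- breed_freqs[breeds, , drop = FALSE]
  X0 <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) X0 <- cbind(X0, covariates[breeds, , drop = FALSE])
  m <- ncol(Fq)
  out <- data.frame(marker_id = colnames(Fq) %||% sprintf("m%d", seq_len(m)),
                    beta = NA_real_, se = NA_real_, stat = NA_real_,
                    p_value = NA_real_, delta = NA_real_,
                    reml_ll = NA_real_, method = "naive",
                    stringsAsFactors = FALSE)
  const_y <- stats::var(yv) == 0
  for (j in seq_len(m)) {
    x <- Fq[, j]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (stats::var(x) == 0) next
    if (const_y) {
      out$beta[j] <- 0; out$stat[j] <- 0; out$p_value[j] <- 1
      next
    }
    X <- cbind(X0, freq = x)
    fit <- stats::lm.fit(X, yv)
    rss <- sum(fit$residuals^2)
    df <- n - ncol(X)
    XtXinv <- chol2inv(chol(crossprod(X)))
    se <- sqrt(rss / df * XtXinv[ncol(X), ncol(X)])
    b <- fit$coefficients[["freq"]]
    tt <- if (se > 0) b / se else 0
    out$beta[j] <- b; out$se[j] <- se; out$stat[j] <- tt
    out$p_value[j] <- 2 * stats::pt(-abs(tt), df = df)
  }
  attr(out, "bonferroni") <- 0.05 / sum(!is.na(out$p_value))
  attr(out, "breeds_used") <- breeds
  out
}

#' IBS-weighted bootstrap association test for dichotomous traits
#'
#' The test statistic at each marker is the absolute Pearson correlation
#' between the per-individual 0/1 phenotype and the breed allele frequency
#' of each individual's breed. The null distribution is built by
#' resampling: in each replicate the phenotype of individual i is copied
#' from individual j drawn with probability `K[i, j] / sum_j' K[i, j']`,
#' so phenotypes travel preferentially between genetically similar dogs
#' and the breed structure of the trait is (partially) preserved. The
#' empirical p-value is `(1 + #{replicates with statistic >= observed}) /
#' (B + 1)`; setting `plus_one = FALSE` recovers the plain count formula.
#' Passing a constant matrix for `K_ind` makes every donor equally likely,
#' i.e. an unweighted permutation-style test. One replicate set is drawn
#' and shared across markers (the resampling does not depend on the
#' marker).
#'
#' @param breed_freqs breeds x markers allele-frequency matrix.
#' @param y_binary named per-individual 0/1 phenotype vector.
#' @param breed_of named character vector: individual id -> breed.
#' @param K_ind individual-level kinship/weight matrix (rows aligned to
#'   its dimnames; must cover all phenotyped individuals).
#' @param B number of bootstrap replicates (>= 100).
#' @param seed RNG seed for the replicate draws.
#' @param plus_one use the +1 small-sample correction in the p-value.
#' @return `data.frame(marker_id, stat, p_value, method)`.
#' @export
weighted_bootstrap_assoc <- function(breed_freqs, y_binary, breed_of,
                                     K_ind, B = 10000, seed = 1,
                                     plus_one = TRUE) {
  if (B < 100) stop("B must be at least 100")
  ids <- names(y_binary)
  if (is.null(ids)) stop("y_binary must be a named vector")
  if (!all(ids %in% rownames(K_ind)))
    stop("K_ind does not cover all phenotyped individuals")
  K <- K_ind[ids, ids]
  y <- as.numeric(y_binary)
  n <- length(y)
  br <- breed_of[ids]
  if (anyNA(br)) stop("breed_of missing for some individuals")
  X <- t(breed_freqs[br, , drop = FALSE])       # markers x individuals
  m <- nrow(X)
  out <- data.frame(marker_id = rownames(X) %||% sprintf("m%d", seq_len(m)),
                    stat = NA_real_, p_value = NA_real_,
                    method = "bootstrap", stringsAsFactors = FALSE)
  if (stats::var(y) == 0) {
    out$p_value <- 1
    return(out)
  }
  set.seed(seed)
  W <- K / rowSums(K)
  donors <- matrix(0L, n, B)
  for (i in seq_len(n))
    donors[i, ] <- sample.int(n, B, replace = TRUE, prob = W[i, ])
  Yb <- matrix(y[donors], n, B)
  # standardize once; columns with zero variance yield NA stats -> count 0
  xs <- t(scale(t(X)))                           # markers x n
  zero_var <- apply(X, 1L, stats::var) == 0
  ys <- (y - mean(y)) / stats::sd(y)
  obs <- abs(as.vector(xs %*% ys)) / (n - 1)
  Ybs <- scale(Yb)
  const_rep <- attr(Ybs, "scaled:scale") == 0
  Ybs[, const_rep] <- 0
  repstats <- abs(xs %*% Ybs) / (n - 1)          # markers x B
  ge <- rowSums(repstats >= obs - 1e-12)
  p <- if (plus_one) (1 + ge) / (B + 1) else ge / B
  out$stat <- obs
  out$p_value <- p
  out$stat[zero_var] <- NA_real_
  out$p_value[zero_var] <- NA_real_
  out
}
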