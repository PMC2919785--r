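# Breed-average association: phenotype averaging, IBS matrices, exact-REML
# mixed model against an independent likelihood oracle, naive regression,
# weighted bootstrap.

test_that("breed_averages applies age filter, min_n and transform", {
  ph <- data.frame(
    individual_id = sprintf("d%d", 1:7),
    breed = c("a", "a", "a", "b", "b", "c", "c"),
    trait = "size",
    value = c(10, 20, 30, 8, 4, 100, 200),
    age_years = c(5, 5, 0.5, 2, NA, 3, 3),
    stringsAsFactors = FALSE)
  # d3 is too young (age not strictly > 1); d5's unknown age is retained
  ba <- breed_averages(ph, "size", min_n = 2, min_age_years = 1)
  expect_equal(ba$breed, c("a", "b", "c"))
  expect_equal(ba$mean_value, c(15, 6, 150))
  expect_equal(ba$n_measured, c(2L, 2L, 2L))
  expect_equal(attr(ba, "trait"), "size")
  # min_n = 3 drops every breed here
  expect_error(breed_averages(ph, "size", min_n = 3), "no breed")
  # log transform averages on the log scale
  bal <- breed_averages(ph, "size", transform = "log")
  expect_equal(bal$mean_value[bal$breed == "c"], mean(log(c(100, 200))))
  expect_equal(attr(bal, "transform"), "log")
  expect_error(breed_averages(ph, "height"), "not present")
})

test_that("ibs_kinship matches hand-computed sharing", {
  g <- rbind(c(0L, 1L, 2L), c(2L, 1L, 0L), c(0L, 1L, 2L))
  gm <- toy_genotypes(g)
  K <- ibs_kinship(gm)
  expect_equal(unname(diag(K)), rep(1, 3))
  # dogs 1 and 2: |0-2| + |1-1| + |2-0| = 4 -> 1 - 4/6 = 1/3
  expect_equal(K[1, 2], 1 / 3)
  expect_equal(K[1, 3], 1)
  expect_equal(K, t(K))
  # missing genotypes restrict to shared markers
  g2 <- rbind(c(0L, 1L, NA), c(2L, 1L, 0L))
  K2 <- ibs_kinship(toy_genotypes(g2))
  expect_equal(K2[1, 2], 1 - 2 / 4)   # only first two markers shared
  # a pair with no shared marker is an error naming the pair
  g3 <- rbind(c(0L, NA), c(NA, 2L))
  expect_error(ibs_kinship(toy_genotypes(g3)), "share no genotyped")
})

test_that("breed_average_kinship excludes self-pairs on the diagonal", {
  K <- matrix(c(1.0, 0.8, 0.3, 0.4,
                0.8, 1.0, 0.2, 0.5,
                0.3, 0.2, 1.0, 0.9,
                0.4, 0.5, 0.9, 1.0), 4, 4)
  Kb <- breed_average_kinship(K, c("x", "x", "y", "y"))
  expect_equal(Kb["x", "x"], 0.8)    # the one cross pair, not the 1s
  expect_equal(Kb["y", "y"], 0.9)
  expect_equal(Kb["x", "y"], mean(c(0.3, 0.4, 0.2, 0.5)))
  expect_equal(Kb, t(Kb))
  # a single-dog breed gets diagonal 1
  Kb1 <- breed_average_kinship(K[1:3, 1:3], c("x", "x", "z"))
  expect_equal(Kb1["z", "z"], 1)
})

test_that("lmm_assoc reduces exactly to OLS when kinship is identity", {
  set.seed(71)
  nb <- 25; m <- 30
  fq <- matrix(runif(nb * m), nb, m,
               dimnames = list(sprintf("b%02d", 1:nb),
                               sprintf("s%03d", 1:m)))
  y <- setNames(rnorm(nb), rownames(fq))
  K <- diag(nb); dimnames(K) <- list(rownames(fq), rownames(fq))
  ols <- naive_assoc(fq, y)
  for (dm in c("null_model", "per_marker")) {
    lmm <- lmm_assoc(fq, y, K, delta_method = dm)
    expect_lt(max(abs(lmm$p_value - ols$p_value)), 1e-8)
    expect_lt(max(abs(lmm$beta - ols$beta)), 1e-8)
  }
})

test_that("naive_assoc matches lm() per marker", {
  set.seed(73)
  nb <- 20; m <- 10
  fq <- matrix(runif(nb * m), nb, m,
               dimnames = list(sprintf("b%02d", 1:nb),
                               sprintf("s%03d", 1:m)))
  y <- setNames(rnorm(nb), rownames(fq))
  cov <- setNames(rnorm(nb), rownames(fq))
  res <- naive_assoc(fq, y, covariates = cov)
  for (j in 1:m) {
    fit <- summary(lm(y ~ cov + fq[, j]))$coefficients
    expect_equal(res$p_value[j], fit[3, 4], tolerance = 1e-10)
    expect_equal(res$beta[j], fit[3, 1], tolerance = 1e-10)
  }
  expect_equal(attr(res, "bonferroni"), 0.05 / m)
})

test_that("per-marker REML delta maximizes an independent likelihood", {
  # Independent profiled REML log-likelihood, direct matrix formulas
  reml_oracle <- function(delta, yv, Xm, Km) {
    n <- length(yv); p <- ncol(Xm)
    V <- Km + delta * diag(n)
    Vi <- solve(V)
    XtViX <- t(Xm) %*% Vi %*% Xm
    beta <- solve(XtViX, t(Xm) %*% Vi %*% yv)
    r <- yv - Xm %*% beta
    rss <- drop(t(r) %*% Vi %*% r)
    as.numeric(-0.5 * ((n - p) * log(rss) + determinant(V)$modulus +
                       determinant(XtViX)$modulus))
  }
  set.seed(79)
  grid <- 10^seq(-5, 5, length.out = 401)
  for (rep in 1:12) {
    n <- 25
    A <- matrix(rnorm(n * n), n)
    K <- tcrossprod(A) / n
    K <- K / mean(diag(K))
    dimnames(K) <- list(sprintf("b%02d", 1:n), sprintf("b%02d", 1:n))
    x <- runif(n)
    L <- chol(0.7 * K + 0.3 * diag(n))
    y <- setNames(drop(crossprod(L, rnorm(n))) + 0.5 * x, rownames(K))
    fq <- matrix(x, n, 1, dimnames = list(rownames(K), "s1"))
    res <- lmm_assoc(fq, y, K, min_breeds = 5, delta_method = "per_marker")
    X <- cbind(1, x)
    ll_pkg <- reml_oracle(res$delta[1], yv = y, Xm = X, Km = K)
    ll_grid <- max(vapply(grid, reml_oracle, 0, yv = y, Xm = X, Km = K))
    expect_gt(ll_pkg, ll_grid - 1e-4)
    # and the reported test follows from GLS at that delta
    Vi <- solve(K + res$delta[1] * diag(n))
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    sigma2 <- drop(t(r) %*% Vi %*% r) / (n - 2)
    se <- sqrt(sigma2 * solve(XtViX)[2, 2])
    expect_equal(res$beta[1], unname(drop(beta)[2]), tolerance = 1e-6)
    expect_equal(res$se[1], unname(se), tolerance = 1e-6)
    expect_equal(res$p_value[1],
                 2 * pt(-abs(res$beta[1] / se), df = n - 2),
                 tolerance = 1e-6)
  }
})

test_that("lmm_assoc aligns breeds by name and handles edge cases", {
  set.seed(83)
  nb <- 15; m <- 5
  fq <- matrix(runif(nb * m), nb, m,
               dimnames = list(sprintf("b%02d", 1:nb),
                               sprintf("s%03d", 1:m)))
  fq[, 3] <- 0.4                         # monomorphic across breeds
  y <- setNames(rnorm(nb), rownames(fq))
  A <- matrix(rnorm(nb * nb), nb)
  K <- tcrossprod(A) / nb; K <- K / mean(diag(K))
  dimnames(K) <- list(rownames(fq), rownames(fq))
  res <- lmm_assoc(fq, y, K, min_breeds = 5)
  # shuffling row order of every input leaves the result unchanged
  ord <- sample(nb)
  res2 <- lmm_assoc(fq[ord, ], y[sample(nb)], K[rev(ord), rev(ord)],
                    min_breeds = 5)
  expect_equal(res$p_value, res2$p_value, tolerance = 1e-9)
  # monomorphic marker is skipped with NA
  expect_true(is.na(res$p_value[3]))
  expect_equal(attr(res, "bonferroni"), 0.05 / 4)
  # constant phenotype yields p = 1, not an error
  yc <- setNames(rep(2, nb), rownames(fq))
  resc <- lmm_assoc(fq, yc, K, min_breeds = 5)
  expect_true(all(resc$p_value[-3] == 1))
  # too few phenotyped breeds is an error
  expect_error(lmm_assoc(fq[1:4, ], y[1:4], K, min_breeds = 10),
               "need >= 10")
})

test_that("weighted bootstrap separating example hits the floor p-value", {
  nb <- 4; nd <- 5; n <- nb * nd
  breed <- rep(sprintf("b%d", 1:nb), each = nd)
  ids <- sprintf("%s_i%d", breed, rep(1:nd, nb))
  breed_of <- setNames(breed, ids)
  # marker s1 separates breeds b1/b2 from b3/b4 exactly as y does
  fq <- cbind(s1 = c(1, 1, 0, 0), s2 = c(0.5, 0.5, 0.5, 0.5),
              s3 = c(0.4, 0.6, 0.5, 0.5))
  rownames(fq) <- sprintf("b%d", 1:nb)
  y <- setNames(as.numeric(breed %in% c("b1", "b2")), ids)
  K <- matrix(1, n, n, dimnames = list(ids, ids))
  res <- weighted_bootstrap_assoc(fq, y, breed_of, K, B = 500, seed = 5)
  expect_equal(res$stat[1], 1)
  expect_equal(res$p_value[1], 1 / 501)
  # zero-variance marker yields NA
  expect_true(is.na(res$p_value[2]))
  # without the +1 correction the count formula is used
  res0 <- weighted_bootstrap_assoc(fq, y, breed_of, K, B = 500, seed = 5,
                                   plus_one = FALSE)
  expect_equal(res0$p_value[1], 0)
})

test_that("weighted bootstrap is invariant to allele relabeling", {
  set.seed(89)
  nb <- 8; nd <- 4; n <- nb * nd; m <- 20
  breed <- rep(sprintf("b%d", 1:nb), each = nd)
  ids <- sprintf("%s_i%d", breed, rep(1:nd, nb))
  fq <- matrix(runif(nb * m), nb, m,
               dimnames = list(sprintf("b%d", 1:nb), sprintf("s%02d", 1:m)))
  y <- setNames(rbinom(n, 1, 0.5), ids)
  K <- matrix(0.1, n, n) + diag(0.9, n)
  dimnames(K) <- list(ids, ids)
  r1 <- weighted_bootstrap_assoc(fq, y, setNames(breed, ids), K,
                                 B = 300, seed = 11)
  r2 <- weighted_bootstrap_assoc(1 - fq, y, setNames(breed, ids), K,
                                 B = 300, seed = 11)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$stat, r2$stat, tolerance = 1e-12)
})

test_that("weighted bootstrap validates inputs", {
  ids <- c("a", "b", "c")
  fq <- matrix(0.5, 2, 1, dimnames = list(c("x", "y"), "s1"))
  y <- setNames(c(0, 1, 0), ids)
  K <- matrix(1, 3, 3, dimnames = list(ids, ids))
  expect_error(weighted_bootstrap_assoc(fq, y, setNames(c("x", "y", "x"),
                                                        ids), K, B = 50),
               "at least 100")
  expect_error(weighted_bootstrap_assoc(fq, unname(y),
                                        setNames(c("x", "y", "x"), ids), K,
                                        B = 100),
               "named")
  K2 <- K[1:2, 1:2]
  expect_error(weighted_bootstrap_assoc(fq, y,
                                        setNames(c("x", "y", "x"), ids), K2,
                                        B = 100),
               "cover")
  # constant phenotype: p = 1 everywhere
  yc <- setNames(c(1, 1, 1), ids)
  rc <- weighted_bootstrap_assoc(fq, yc, setNames(c("x", "y", "x"), ids), K,
                                 B = 100)
  expect_true(all(rc$p_value == 1))
})
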