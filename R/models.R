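# Forward-stepwise multi-SNP predictive models on breed-average phenotypes
# with an individual-genotype design matrix, and validation on individually
# phenotyped dogs.

#' Forward-stepwise multi-SNP model
#'
#' Builds a multi-SNP linear predictor by forward selection over a ranked
#' candidate list (typically the top markers of an association scan). The
#' response is the breed-average trait value assigned to every individual
#' of the breed; the design matrix holds individual dosages at the chosen
#' markers (missing dosages mean-imputed per marker). At each step the
#' candidate that maximizes the adjusted R-squared of the fit is added;
#' ties are broken by candidate rank (i.e. smaller association p), then
#' marker order. Selection stops at `max_k` markers or when no candidate
#' increases the adjusted R-squared. Candidates collinear with the current
#' design are skipped.
#'
#' @param candidates marker ids, ranked (best first).
#' @param genotypes a [genotype_matrix()] of the training individuals.
#' @param y_breed breed phenotype: `data.frame` from [breed_averages()] or
#'   named numeric vector (breed -> value).
#' @param max_k maximum number of markers.
#' @param unit "individual" (breed value repeated per dog; the default) or
#'   "breed" (one row per breed, breed-mean dosages).
#' @return list of class `predictive_model`: `trait`, `markers`,
#'   `coefficients` (intercept first), `r2_trajectory`,
#'   `adj_r2_trajectory`, `impute_means`, `unit`.
#' @export
forward_stepwise <- function(candidates, genotypes, y_breed, max_k = 6,
                             unit = c("individual", "breed")) {
  unit <- match.arg(unit)
  if (is.data.frame(y_breed))
    y_breed <- stats::setNames(y_breed$mean_value, y_breed$breed)
  candidates <- candidates[candidates %in% genotypes$map$marker_id]
  if (length(candidates) == 0L) stop("no candidate markers in the panel")
  breed <- genotypes$individuals$breed
  keep <- breed %in% names(y_breed)
  if (!any(keep)) stop("no individual belongs to a phenotyped breed")
  g <- genotypes$geno[keep, , drop = FALSE]
  breed <- breed[keep]
  cols <- match(candidates, genotypes$map$marker_id)
  D <- g[, cols, drop = FALSE]
  mu <- colMeans(D, na.rm = TRUE)
  for (j in seq_len(ncol(D))) D[is.na(D[, j]), j] <- mu[j]
  colnames(D) <- candidates
  if (unit == "breed") {
    D <- rowsum(D, breed) / as.vector(table(breed)[sort(unique(breed))])
    y <- y_breed[rownames(D)]
  } else {
    y <- y_breed[breed]
  }
  n <- length(y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("phenotype is constant; nothing to fit")
  chosen <- character(0)
  r2_tr <- numeric(0); adj_tr <- numeric(0)
  cur_adj <- -Inf
  fit_r2 <- function(sel) {
    X <- cbind(1, D[, sel, drop = FALSE])
    q <- qr(X)
    if (q$rank < ncol(X)) return(NULL)
    rss <- sum(qr.resid(q, y)^2)
    r2 <- 1 - rss / tss
    adj <- 1 - (1 - r2) * (n - 1) / (n - ncol(X))
    list(r2 = r2, adj = adj)
  }
  while (length(chosen) < max_k) {
    rem <- setdiff(candidates, chosen)
    if (length(rem) == 0L) break
    best <- NULL; best_adj <- -Inf
    for (cand in rem) {           # candidate order encodes the ranking
      f <- fit_r2(c(chosen, cand))
      if (is.null(f)) next        # collinear with current design
      if (f$adj > best_adj + 1e-12) {
        best <- cand; best_adj <- f$adj; best_r2 <- f$r2
      }
    }
    if (is.null(best) || best_adj <= cur_adj) break
    chosen <- c(chosen, best)
    cur_adj <- best_adj
    r2_tr <- c(r2_tr, best_r2)
    adj_tr <- c(adj_tr, best_adj)
  }
  if (length(chosen) == 0L) stop("no candidate could be fit")
  X <- cbind(intercept = 1, D[, chosen, drop = FALSE])
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  structure(list(trait = attr(y_breed, "trait"),
                 markers = chosen,
                 coefficients = stats::setNames(as.numeric(beta),
                                                colnames(X)),
                 r2_trajectory = r2_tr,
                 adj_r2_trajectory = adj_tr,
                 impute_means = mu[chosen],
                 unit = unit),
            class = "predictive_model")
}

#' @export
print.predictive_model <- function(x, ...) {
  cat("predictive_model:", length(x$markers), "markers; training R2 =",
      round(x$r2_trajectory[length(x$r2_trajectory)], 3), "\n")
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  invisible(x)
}

#' Predict individual phenotypes from a multi-SNP model
#'
#' Applies the model's linear predictor to individual dosages. A missing
#' dosage at a model marker is imputed as the prediction panel's mean
#' dosage at that marker (falling back to the training mean when the
#' whole panel is missing there).
#'
#' @param object a `predictive_model`.
#' @param genotypes a [genotype_matrix()]; must contain every model marker.
#' @param ... unused.
#' @return named numeric vector of predictions per individual.
#' @export
predict.predictive_model <- function(object, genotypes, ...) {
  cols <- match(object$markers, genotypes$map$marker_id)
  if (anyNA(cols))
    stop("model markers absent from panel: ",
         paste(object$markers[is.na(cols)], collapse = ", "))
  D <- genotypes$geno[, cols, drop = FALSE]
  storage.mode(D) <- "double"
  for (j in seq_len(ncol(D))) {
    if (anyNA(D[, j])) {
      mj <- mean(D[, j], na.rm = TRUE)
      if (is.nan(mj)) mj <- object$impute_means[j]
      D[is.na(D[, j]), j] <- mj
    }
  }
  beta <- object$coefficients
  pred <- drop(cbind(1, D) %*% beta)
  stats::setNames(pred, genotypes$individuals$individual_id)
}

#' Compare observed and predicted phenotypes
#'
#' @param predictions named numeric vector (individual id -> prediction).
#' @param observed phenotype `data.frame` (uses `individual_id`, `value`,
#'   optionally filtered by `trait`) or a named numeric vector.
#' @param trait optional trait filter when `observed` is a `data.frame`.
#' @param label population label for the report.
#' @return list of class `validation_report`: `label`, `n`, `correlation`,
#'   `r_squared`, `degenerate`.
#' @export
validate_predictions <- function(predictions, observed, trait = NULL,
                                 label = NA_character_) {
  if (is.data.frame(observed)) {
    d <- observed
    if (!is.null(trait)) d <- d[d$trait == trait, , drop = FALSE]
    obs <- stats::setNames(d$value, d$individual_id)
  } else obs <- observed
  ids <- intersect(names(predictions), names(obs))
  if (length(ids) < 3L)
    stop("need at least 3 individuals with both observed and predicted ",
         "values; have ", length(ids))
  p <- predictions[ids]; o <- obs[ids]
  degen <- stats::sd(p) == 0 || stats::sd(o) == 0
  r <- if (degen) NA_real_ else stats::cor(o, p)
  structure(list(label = label, n = length(ids), correlation = r,
                 r_squared = if (degen) NA_real_ else r^2,
                 degenerate = degen),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report [", x$label, "]: n =", x$n,
      if (x$degenerate) "(degenerate: constant values)"
      else paste0("r = ", round(x$correlation, 3),
                  ", R2 = ", round(x$r_squared, 3)), "\n")
  invisible(x)
}
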