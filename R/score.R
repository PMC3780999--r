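#' @keywords internal
new_allele_score <- function(values, weights, mode, folds = NULL, extra = list()) {
  structure(c(list(values = as.numeric(values), weights = as.numeric(weights),
                   mode = mode, folds = folds), extra),
            class = "allele_score")
}

check_genotypes <- function(genotypes) {
  if (!is.matrix(genotypes)) genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) == 0L || ncol(genotypes) == 0L)
    stop("genotype matrix must have at least one row and one column", call. = FALSE)
  if (!is.numeric(genotypes))
    stop("genotype matrix must be numeric", call. = FALSE)
  genotypes
}

#' Unweighted allele score
#'
#' The total number of risk-factor-increasing alleles carried by each
#' individual: the row sum of the dosage matrix. Assumes alleles are already
#' oriented so the minor allele increases the risk factor (see
#' [reorient_genotypes()] for user data).
#'
#' @param genotypes n x J dosage matrix (entries 0/1/2).
#' @return an `allele_score`: per-individual values, the all-ones weight
#'   vector, and provenance.
#' @export
unweighted_score <- function(genotypes) {
  genotypes <- check_genotypes(genotypes)
  new_allele_score(rowSums(genotypes), rep(1, ncol(genotypes)), "unweighted")
}

#' Internal weights from the multivariable first-stage regression
#'
#' Regresses the risk factor jointly on all genotype columns (plus an
#' intercept) and returns the coefficient vector. These are the weights a
#' naive internally weighted score uses, and they are identical to the
#' first-stage coefficients of the multivariable two-stage least squares
#' analysis: an internally weighted score reproduces that 2SLS estimate
#' exactly. Note that the joint regression, not per-variant marginal
#' regressions, defines these weights.
#'
#' @param genotypes n x J dosage matrix.
#' @param x risk-factor vector, length n.
#' @return numeric weight vector of length J.
#' @export
estimate_weights <- function(genotypes, x) {
  genotypes <- check_genotypes(genotypes)
  if (nrow(genotypes) != length(x))
    stop("genotypes and x must have the same number of rows", call. = FALSE)
  X <- cbind(1, genotypes)
  fit <- stats::lm.fit(X, x)
  if (fit$rank < ncol(X))
    stop("singular design: genotype matrix is rank deficient", call. = FALSE)
  unname(fit$coefficients[-1])
}

#' Weighted allele score with supplied weights
#'
#' @param genotypes n x J dosage matrix.
#' @param weights length-J weight vector.
#' @param mode provenance label stored with the score.
#' @return an `allele_score` with values `genotypes %*% weights`.
#' @export
weighted_score <- function(genotypes, weights, mode = "weighted") {
  genotypes <- check_genotypes(genotypes)
  if (length(weights) != ncol(genotypes))
    stop("need one weight per genotype column", call. = FALSE)
  new_allele_score(drop(genotypes %*% weights), weights, mode)
}

#' Internally weighted allele score
#'
#' Convenience wrapper: weights from [estimate_weights()] on the same data
#' the score is applied to. This is the naive procedure whose IV estimate
#' coincides with multivariable 2SLS, inheriting its weak-instrument bias.
#'
#' @inheritParams estimate_weights
#' @return an `allele_score`.
#' @export
internal_weighted_score <- function(genotypes, x) {
  weighted_score(genotypes, estimate_weights(genotypes, x), mode = "internal")
}

#' Cross-validated weighted allele score
#'
#' Individuals are partitioned at random into `k_folds` folds of near-equal
#' size. For each fold, weights are estimated by [estimate_weights()] on the
#' complement (the other folds), and applied only to individuals in that
#' fold, so no individual's data contribute to the weights used for their own
#' score. With `k_folds = 2` the sample is split into halves and each half is
#' scored with the other half's weights.
#'
#' @inheritParams estimate_weights
#' @param k_folds number of folds (at least 2, at most n).
#' @return an `allele_score`; `$folds` records each individual's fold and
#'   `$fold_weights` the k_folds x J matrix of fold-specific weights.
#' @export
cv_weighted_score <- function(genotypes, x, k_folds = 10) {
  genotypes <- check_genotypes(genotypes)
  n <- nrow(genotypes)
  if (k_folds < 2 || k_folds != round(k_folds))
    stop("k_folds must be a whole number of at least 2", call. = FALSE)
  if (k_folds > n)
    stop("k_folds cannot exceed the number of individuals", call. = FALSE)
  folds <- sample(rep_len(seq_len(k_folds), n))
  W <- matrix(NA_real_, nrow = k_folds, ncol = ncol(genotypes))
  values <- numeric(n)
  for (f in seq_len(k_folds)) {
    hold <- folds == f
    W[f, ] <- estimate_weights(genotypes[!hold, , drop = FALSE], x[!hold])
    values[hold] <- drop(genotypes[hold, , drop = FALSE] %*% W[f, ])
  }
  new_allele_score(values, colMeans(W), mode = sprintf("cv%d", k_folds),
                   folds = folds, extra = list(fold_weights = W))
}

#' Externally weighted allele score
#'
#' Emulates weights estimated in an independent data source by perturbing the
#' true per-variant effects with independent Normal(0, sd^2) noise. With the
#' reference design, `sd = 0.04` corresponds to weights from an external
#' study of about the same size as the analysis sample (imprecise weights)
#' and `sd = 0.01` to one about 16 times larger (precise weights); `sd = 0`
#' gives the true-weight score. Perturbed weights may be negative; no
#' truncation is applied.
#'
#' @param genotypes n x J dosage matrix.
#' @param true_weights length-J vector of generating effects.
#' @param sd standard deviation of the perturbation (>= 0).
#' @return an `allele_score`.
#' @export
external_weighted_score <- function(genotypes, true_weights, sd = 0.04) {
  genotypes <- check_genotypes(genotypes)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  if (length(true_weights) != ncol(genotypes))
    stop("need one weight per genotype column", call. = FALSE)
  w <- true_weights + stats::rnorm(length(true_weights), 0, sd)
  weighted_score(genotypes, w, mode = if (sd == 0) "true" else "external")
}

#' Variant selection rule
#'
#' @param mode `"top_k"` (keep the k variants most strongly associated with
#'   the risk factor) or `"p_threshold"` (keep variants with univariate
#'   P-value below `p_cut`).
#' @param k number of variants to keep under `"top_k"`.
#' @param p_cut significance threshold under `"p_threshold"`, in (0, 1].
#' @return an object of class `selection_rule`.
#' @export
selection_rule <- function(mode = c("top_k", "p_threshold"), k = 5, p_cut = 0.05) {
  mode <- match.arg(mode)
  if (mode == "top_k" && (k < 1 || k != round(k)))
    stop("k must be a positive whole number", call. = FALSE)
  if (mode == "p_threshold" && (p_cut <= 0 || p_cut > 1))
    stop("p_cut must lie in (0, 1]", call. = FALSE)
  structure(list(mode = mode, k = k, p_cut = p_cut), class = "selection_rule")
}

#' Data-driven variant selection by strength of association
#'
#' Ranks variants by the F statistic (equivalently the squared t statistic;
#' the ordering matches the P-value ordering) of the univariate regression of
#' the risk factor on each genotype column, with ties broken by variant
#' index. This is the procedure that induces winner's-curse bias when the
#' same data are then used for IV estimation; it is provided to quantify
#' that bias, not as a recommendation.
#'
#' @inheritParams estimate_weights
#' @param rule a [selection_rule()].
#' @return integer vector of selected column indices (increasing order);
#'   possibly empty under `"p_threshold"`, which callers should treat as a
#'   non-estimable analysis.
#' @export
select_variants <- function(genotypes, x, rule) {
  genotypes <- check_genotypes(genotypes)
  stopifnot(inherits(rule, "selection_rule"))
  n <- nrow(genotypes)
  stats_f <- apply(genotypes, 2, function(g) {
    gc <- g - mean(g)
    sgg <- sum(gc^2)
    if (sgg == 0) return(0)  # monomorphic column: no association
    xc <- x - mean(x)
    r2 <- sum(gc * xc)^2 / (sgg * sum(xc^2))
    (n - 2) * r2 / (1 - r2)
  })
  if (rule$mode == "top_k") {
    k <- min(rule$k, ncol(genotypes))
    sel <- order(-stats_f, seq_along(stats_f))[seq_len(k)]
    return(sort(sel))
  }
  pvals <- stats::pf(stats_f, 1, n - 2, lower.tail = FALSE)
  sort(unname(which(pvals < rule$p_cut)))
}

#' Orient genotype coding so the minor allele increases the risk factor
#'
#' Flips (`g -> 2 - g`) each variant whose univariate association with the
#' risk factor is negative. Simulated data are generated risk-increasing and
#' never need this; for user data, note that reorienting on the analysis
#' sample is itself a data-driven choice and can introduce bias for very weak
#' variants.
#'
#' @inheritParams estimate_weights
#' @return the reoriented genotype matrix, with attribute `flipped` giving
#'   the flipped column indices.
#' @export
reorient_genotypes <- function(genotypes, x) {
  genotypes <- check_genotypes(genotypes)
  slopes <- apply(genotypes, 2, function(g) {
    gc <- g - mean(g)
    s <- sum(gc^2)
    if (s == 0) 0 else sum(gc * (x - mean(x))) / s
  })
  flip <- unname(which(slopes < 0))
  if (length(flip)) {
    warning("reorienting ", length(flip),
            " variant(s) on the analysis data; this is a data-driven choice",
            call. = FALSE)
    genotypes[, flip] <- 2 - genotypes[, flip]
  }
  attr(genotypes, "flipped") <- flip
  genotypes
}

#' @export
print.allele_score <- function(x, ...) {
  cat(sprintf("Allele score (%s weights): %d individuals, %d variants\n",
              x$mode, length(x$values), length(x$weights)))
  invisible(x)
}
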