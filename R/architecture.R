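#' Construct a genetic architecture
#'
#' A genetic architecture collects the per-variant parameters of the
#' generating model: additive effects on the risk factor, validity indicators,
#' heterozygote deviations, pairwise variant-variant interaction coefficients
#' and variant-covariate interaction coefficients. [build_architecture()]
#' draws one according to a scenario; this constructor is exposed for tests
#' and custom generating models.
#'
#' @param J number of variants.
#' @param maf minor allele frequencies, length J (scalars recycled).
#' @param alpha per-variant additive effect on X, length J.
#' @param valid 0/1 validity indicators (1 = variant acts on X, 0 = variant
#'   acts on the confounder), length J.
#' @param het_dev heterozygote deviations, length J.
#' @param gg_inter variant-variant interaction coefficients: a matrix with
#'   columns `j`, `k`, `coef` (j < k), possibly zero rows.
#' @param gx_inter variant-covariate interaction coefficients, length J.
#' @param main indices of "main" variants (major-gene/polygene designs), or
#'   `NULL`.
#' @return an object of class `genetic_architecture`.
#' @export
genetic_architecture <- function(J, maf, alpha,
                                 valid = rep(1, J),
                                 het_dev = rep(0, J),
                                 gg_inter = empty_gg(),
                                 gx_inter = rep(0, J),
                                 main = NULL) {
  maf <- rep_len(maf, J)
  alpha <- rep_len(alpha, J)
  stopifnot(J >= 1, length(valid) == J, all(valid %in% c(0, 1)),
            length(het_dev) == J, length(gx_inter) == J,
            is.matrix(gg_inter), ncol(gg_inter) == 3)
  if (any(maf <= 0 | maf >= 1))
    stop("minor allele frequencies must lie strictly inside (0, 1)", call. = FALSE)
  if (nrow(gg_inter) && any(gg_inter[, 1] >= gg_inter[, 2]))
    stop("gg_inter rows must have j < k", call. = FALSE)
  structure(list(J = J, maf = maf, alpha = alpha, valid = valid,
                 het_dev = het_dev, gg_inter = gg_inter,
                 gx_inter = gx_inter, main = main),
            class = "genetic_architecture")
}

empty_gg <- function() {
  matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("j", "k", "coef")))
}

#' Draw a genetic architecture for a scenario
#'
#' Materializes the per-variant parameters implied by `config$scenario`,
#' consuming the current RNG stream for the randomized architectures:
#'
#' * `initial` / `selected`: constant effect `alpha` for every variant.
#' * `unequal`: effects drawn from Normal(alpha, effect_sd^2)
#'   (0.06 and 0.018 at J = 25).
#' * `major_polygene`: `n_main` main variants with `main_ratio` times the
#'   secondary effect; magnitudes solved so the variance explained by the
#'   score matches the equal-effects design with the same `alpha`.
#' * `nonlinear`: heterozygote deviations drawn from Normal(0, het_sd^2).
#' * `gg_interaction`: each of the J(J-1)/2 variant pairs interacts with
#'   probability `gg_prob`, coefficient Normal(0, gg_sd^2).
#' * `gx_interaction`: each variant interacts with the covariate with
#'   probability `gx_prob`, coefficient Normal(0, gx_sd^2).
#' * `invalid`: each variant is a valid instrument with probability
#'   `p_valid`; invalid variants act on the confounder with the same
#'   coefficient.
#'
#' @param config a [sim_config()].
#' @return a [genetic_architecture()].
#' @export
build_architecture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  J <- config$J
  maf <- rep_len(config$maf, J)
  alpha <- rep_len(config$alpha, J)
  arch <- switch(config$scenario,
    initial = ,
    selected = ,
    nonlinear = ,
    gg_interaction = ,
    gx_interaction = genetic_architecture(J, maf, alpha),
    unequal = genetic_architecture(
      J, maf, stats::rnorm(J, mean = alpha, sd = config$effect_sd)),
    major_polygene = {
      n_main <- config$n_main
      r <- config$main_ratio
      # Hold the unweighted score's variance explained at the equal-effects
      # level: n_main * r * a_s + (J - n_main) * a_s = sum(alpha).
      a_s <- sum(alpha) / (n_main * r + J - n_main)
      a <- rep(a_s, J)
      main <- seq_len(n_main)
      a[main] <- r * a_s
      genetic_architecture(J, maf, a, main = main)
    },
    invalid = genetic_architecture(
      J, maf, alpha,
      valid = stats::rbinom(J, 1, config$p_valid)),
    stop("unknown scenario: ", config$scenario, call. = FALSE)
  )
  if (config$scenario == "nonlinear")
    arch$het_dev <- stats::rnorm(J, 0, config$het_sd)
  if (config$scenario == "gg_interaction") {
    pairs <- which(upper.tri(matrix(0, J, J)), arr.ind = TRUE)
    on <- stats::runif(nrow(pairs)) < config$gg_prob
    if (any(on)) {
      arch$gg_inter <- cbind(j = pairs[on, 1], k = pairs[on, 2],
                             coef = stats::rnorm(sum(on), 0, config$gg_sd))
    }
  }
  if (config$scenario == "gx_interaction") {
    on <- stats::runif(J) < config$gx_prob
    arch$gx_inter <- ifelse(on, stats::rnorm(J, 0, config$gx_sd), 0)
  }
  arch
}

#' @export
print.genetic_architecture <- function(x, ...) {
  cat(sprintf("Genetic architecture: %d variants, %d valid, MAF %s\n",
              x$J, sum(x$valid), paste(signif(unique(x$maf), 3), collapse = "/")))
  cat(sprintf("  alpha: %s\n", paste(signif(unique(round(x$alpha, 6)), 3)[1:min(4, length(unique(round(x$alpha, 6))))], collapse = ", ")))
  if (any(x$het_dev != 0)) cat("  heterozygote deviations present\n")
  if (nrow(x$gg_inter)) cat(sprintf("  %d variant-variant interactions\n", nrow(x$gg_inter)))
  if (any(x$gx_inter != 0)) cat(sprintf("  %d variant-covariate interactions\n", sum(x$gx_inter != 0)))
  invisible(x)
}
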