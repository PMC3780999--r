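#' Simulate a genotype dosage matrix under Hardy-Weinberg equilibrium
#'
#' Each entry is the number of minor alleles (0, 1 or 2) carried by an
#' individual at a variant, drawn as the sum of two independent
#' Bernoulli(maf_j) alleles; columns (variants) are mutually independent and
#' in linkage equilibrium.
#'
#' @param n number of individuals (rows).
#' @param J number of variants (columns).
#' @param maf minor allele frequency per variant, scalar or length-J vector,
#'   strictly inside (0, 1). Degenerate frequencies of exactly 0 or 1 would
#'   produce constant columns that break weighting and first-stage
#'   regressions, and are rejected.
#' @return an n x J integer matrix of dosages with columns `g1..gJ`.
#' @examples
#' G <- simulate_genotypes(100, 3, 0.3)
#' colMeans(G) / 2  # empirical allele frequencies
#' @export
simulate_genotypes <- function(n, J, maf) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n))
    stop("n must be a positive whole number", call. = FALSE)
  if (length(J) != 1L || !is.finite(J) || J < 1 || J != round(J))
    stop("J must be a positive whole number", call. = FALSE)
  maf <- rep_len(maf, J)
  if (any(!is.finite(maf)) || any(maf <= 0 | maf >= 1))
    stop("minor allele frequencies must lie strictly inside (0, 1)", call. = FALSE)
  G <- matrix(stats::rbinom(n * J, size = 2L, prob = rep(maf, each = n)),
              nrow = n, ncol = J)
  colnames(G) <- paste0("g", seq_len(J))
  G
}

#' Simulate one genotype-phenotype dataset
#'
#' Generates genotypes, the latent confounder U, the covariate V (scenario
#' `gx_interaction` only), the risk factor X and the outcome Y under the
#' generating model
#'
#' \deqn{X_i = \sum_j \delta_j \alpha_j G_{ij} + \sum_j \gamma_j 1[G_{ij}=1]
#'   + \sum_{j<k} \delta_{jk} G_{ij} G_{ik} + \sum_j \kappa_j G_{ij} V_i
#'   + \theta_V V_i + c_X U_i + \epsilon_{Xi}}
#' \deqn{Y_i = \beta_X X_i + c_Y U_i + \epsilon_{Yi}}
#'
#' with U, V, and the errors independent standard normal (errors scaled by
#' `err_sd_x` / `err_sd_y`). Under the `invalid` scenario, variants with
#' validity indicator 0 are moved into the confounder:
#' U_i gains \eqn{\sum_j (1 - \delta_j) \alpha_j G_{ij}}, so each invalid
#' variant is associated with U with the same strength it would have had
#' on X.
#'
#' @param config a [sim_config()].
#' @param arch a [genetic_architecture()] consistent with `config`; by
#'   default a fresh draw from [build_architecture()].
#' @return an object of class `sim_dataset`: list with `genotypes` (n x J),
#'   `x`, `y`, `u`, `v` (`NULL` unless scenario uses a covariate) and `truth`
#'   (the architecture and configuration used).
#' @examples
#' set.seed(1)
#' dat <- simulate_dataset(sim_config(n = 200, J = 5))
#' cor(dat$x, dat$y)  # positive even under the null: confounding
#' @export
simulate_dataset <- function(config, arch = build_architecture(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(arch, "genetic_architecture"))
  if (arch$J != config$J)
    stop("architecture has ", arch$J, " variants but config requires ", config$J,
         call. = FALSE)
  n <- config$n
  G <- simulate_genotypes(n, arch$J, arch$maf)
  u <- stats::rnorm(n)
  v <- NULL
  if (config$scenario == "gx_interaction") v <- stats::rnorm(n)
  if (any(arch$valid == 0))
    u <- u + drop(G %*% ((1 - arch$valid) * arch$alpha))
  signal <- drop(G %*% (arch$valid * arch$alpha))
  if (any(arch$het_dev != 0))
    signal <- signal + drop((G == 1L) %*% arch$het_dev)
  if (nrow(arch$gg_inter)) {
    gg <- arch$gg_inter
    for (r in seq_len(nrow(gg)))
      signal <- signal + gg[r, "coef"] * G[, gg[r, "j"]] * G[, gg[r, "k"]]
  }
  if (!is.null(v)) {
    if (any(arch$gx_inter != 0))
      signal <- signal + drop((G * v) %*% arch$gx_inter)
    signal <- signal + config$theta_v * v
  }
  x <- signal + config$conf_coef_x * u + config$err_sd_x * stats::rnorm(n)
  y <- config$beta_x * x + config$conf_coef_y * u + config$err_sd_y * stats::rnorm(n)
  structure(list(genotypes = G, x = x, y = y, u = u, v = v,
                 truth = list(arch = arch, config = config)),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d individuals, %d variants (scenario: %s)\n",
              length(x$x), ncol(x$genotypes), x$truth$config$scenario))
  invisible(x)
}
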