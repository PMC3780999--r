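#' @keywords internal
SCENARIOS <- c("initial", "unequal", "major_polygene", "selected",
               "nonlinear", "gg_interaction", "gx_interaction", "invalid")

#' Default per-variant effect size for a given number of variants
#'
#' The per-allele effect on the risk factor is scaled with the number of
#' variants J so that the proportion of risk-factor variance explained by the
#' score stays constant (approximately 1.9% with the default confounder and
#' error scales): alpha(J) = 0.3 / sqrt(J), giving 0.10 for J = 9, 0.06 for
#' J = 25 and 0.03 for J = 100 at MAF 0.3.
#'
#' @param J number of genetic variants.
#' @return scalar per-allele effect (risk-factor units per minor allele).
#' @export
default_alpha <- function(J) 0.3 / sqrt(J)

#' Simulation configuration
#'
#' Builds a validated configuration for the genotype-phenotype generating
#' model. The defaults describe the reference design: n = 3000 individuals,
#' J = 25 independent biallelic variants with minor allele frequency 0.3 under
#' Hardy-Weinberg equilibrium, a standard-normal unmeasured confounder entering
#' both the risk factor X and the outcome Y with coefficient 1, unit-variance
#' normal errors, and a null causal effect. Scenario-specific parameters are
#' ignored by scenarios that do not use them.
#'
#' @param scenario one of `"initial"` (equal effects, valid instruments),
#'   `"unequal"` (normally distributed effect sizes), `"major_polygene"`
#'   (two main variants with 5x the secondary effect), `"selected"`
#'   (generating model as `"initial"`; selection happens at analysis),
#'   `"nonlinear"` (heterozygote deviations), `"gg_interaction"`
#'   (pairwise variant-variant interactions), `"gx_interaction"`
#'   (variant-covariate interactions) or `"invalid"` (a random subset of
#'   variants acts on the confounder instead of the risk factor).
#' @param n number of individuals per dataset.
#' @param J number of genetic variants.
#' @param beta_x causal effect of the risk factor on the outcome.
#' @param maf minor allele frequency, scalar or length-J vector, in (0, 0.5].
#' @param alpha per-variant effect on X; scalar or length-J vector. Default
#'   [default_alpha()] of `J`.
#' @param conf_coef_x,conf_coef_y coefficients of the confounder U in the X
#'   and Y equations.
#' @param err_sd_x,err_sd_y standard deviations of the independent normal
#'   errors of X and Y.
#' @param effect_sd standard deviation of the per-variant effects under
#'   `"unequal"`; default `0.3 * alpha` (0.018 at J = 25).
#' @param n_main,main_ratio number of main variants and the ratio of main to
#'   secondary effect size under `"major_polygene"`.
#' @param het_sd standard deviation of heterozygote deviations under
#'   `"nonlinear"`.
#' @param gg_prob,gg_sd probability that a variant pair interacts and the
#'   standard deviation of its coefficient under `"gg_interaction"`.
#' @param gx_prob,gx_sd probability that a variant interacts with the
#'   covariate and the standard deviation of its coefficient under
#'   `"gx_interaction"`.
#' @param theta_v main effect of the covariate V on X under
#'   `"gx_interaction"`.
#' @param p_valid probability that a variant is a valid instrument under
#'   `"invalid"`.
#' @param n_reps number of Monte Carlo replicates for study runs.
#' @param seed master seed; all replicate-level randomness derives from it.
#' @return an object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(scenario = "invalid", p_valid = 0.7, beta_x = 0.2)
#' cfg$alpha
#' @export
sim_config <- function(scenario = "initial",
                       n = 3000,
                       J = 25,
                       beta_x = 0,
                       maf = 0.3,
                       alpha = NULL,
                       conf_coef_x = 1,
                       conf_coef_y = 1,
                       err_sd_x = 1,
                       err_sd_y = 1,
                       effect_sd = NULL,
                       n_main = 2,
                       main_ratio = 5,
                       het_sd = 0.036,
                       gg_prob = 0.1,
                       gg_sd = 0.036,
                       gx_prob = 0.5,
                       gx_sd = 0.036,
                       theta_v = 1,
                       p_valid = 0.9,
                       n_reps = 1000,
                       seed = 1) {
  if (is.null(alpha)) alpha <- default_alpha(J)
  if (is.null(effect_sd)) effect_sd <- 0.3 * mean(alpha)
  cfg <- structure(list(
    scenario = scenario, n = n, J = J, beta_x = beta_x, maf = maf,
    alpha = alpha, conf_coef_x = conf_coef_x, conf_coef_y = conf_coef_y,
    err_sd_x = err_sd_x, err_sd_y = err_sd_y, effect_sd = effect_sd,
    n_main = n_main, main_ratio = main_ratio, het_sd = het_sd,
    gg_prob = gg_prob, gg_sd = gg_sd, gx_prob = gx_prob, gx_sd = gx_sd,
    theta_v = theta_v, p_valid = p_valid, n_reps = n_reps, seed = seed
  ), class = "sim_config")
  validate_config(cfg)
}

#' @keywords internal
validate_config <- function(cfg) {
  stop_key <- function(key, msg) {
    stop(sprintf("invalid configuration key '%s': %s", key, msg), call. = FALSE)
  }
  if (length(cfg$scenario) != 1L || !cfg$scenario %in% SCENARIOS)
    stop_key("scenario", paste("must be one of", paste(SCENARIOS, collapse = ", ")))
  num_scalar <- function(key, lo = -Inf, hi = Inf, integer = FALSE) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop_key(key, "must be a single number")
    if (v < lo || v > hi)
      stop_key(key, sprintf("must be in [%s, %s]", lo, hi))
    if (integer && v != round(v)) stop_key(key, "must be a whole number")
    invisible(v)
  }
  num_scalar("n", lo = 1, integer = TRUE)
  num_scalar("J", lo = 1, integer = TRUE)
  num_scalar("beta_x")
  num_scalar("conf_coef_x"); num_scalar("conf_coef_y")
  num_scalar("err_sd_x", lo = 0); num_scalar("err_sd_y", lo = 0)
  num_scalar("effect_sd", lo = 0)
  num_scalar("n_main", lo = 0, integer = TRUE)
  num_scalar("main_ratio", lo = 0)
  num_scalar("het_sd", lo = 0)
  num_scalar("gg_prob", lo = 0, hi = 1); num_scalar("gg_sd", lo = 0)
  num_scalar("gx_prob", lo = 0, hi = 1); num_scalar("gx_sd", lo = 0)
  num_scalar("theta_v")
  num_scalar("p_valid", lo = 0, hi = 1)
  num_scalar("n_reps", lo = 1, integer = TRUE)
  num_scalar("seed", integer = TRUE)
  if (!is.numeric(cfg$maf) || !length(cfg$maf) %in% c(1L, cfg$J))
    stop_key("maf", "must be a scalar or one value per variant")
  if (any(cfg$maf <= 0 | cfg$maf > 0.5))
    stop_key("maf", "minor allele frequencies must lie in (0, 0.5]")
  if (!is.numeric(cfg$alpha) || !length(cfg$alpha) %in% c(1L, cfg$J))
    stop_key("alpha", "must be a scalar or one value per variant")
  if (cfg$scenario == "major_polygene" && cfg$n_main > cfg$J)
    stop_key("n_main", "cannot exceed the number of variants J")
  cfg
}

#' Load a simulation configuration from a YAML (or JSON) file
#'
#' The file holds key-value overrides of [sim_config()] defaults. Unknown keys
#' are rejected by name; an empty file yields the full default configuration.
#'
#' @param path path to a YAML/JSON key-value file.
#' @return a validated `sim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration file must hold key: value pairs", call. = FALSE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (scenario: ", x$scenario, ")\n", sep = "")
  cat(sprintf("  n = %d individuals, J = %d variants, MAF = %s\n",
              x$n, x$J, paste(signif(unique(x$maf), 3), collapse = "/")))
  cat(sprintf("  beta_x = %g, alpha = %s, confounder coef (X, Y) = (%g, %g)\n",
              x$beta_x, paste(signif(unique(x$alpha), 3), collapse = "/"),
              x$conf_coef_x, x$conf_coef_y))
  cat(sprintf("  n_reps = %d, seed = %d\n", x$n_reps, as.integer(x$seed)))
  invisible(x)
}
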