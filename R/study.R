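#' Specify an analysis method for a Monte Carlo study
#'
#' A method spec names the estimator and, for score-based methods, how the
#' score is weighted and whether variants are pre-selected from the data.
#'
#' @param estimator `"score"` (allele-score IV), `"ols"` (observational),
#'   `"tsls"` (multivariable 2SLS, one coefficient per variant), `"liml"`,
#'   or `"composite"` (main variants plus secondary unweighted score).
#' @param weights for `estimator = "score"`: `"unweighted"`, `"internal"`
#'   (naive, estimated on the analysis data), `"cv"` (cross-validated),
#'   `"external"` (true weights perturbed by Normal(0, external_sd^2)), or
#'   `"true"` (generating coefficients).
#' @param k_folds folds for `weights = "cv"`.
#' @param external_sd perturbation SD for `weights = "external"`.
#' @param selection optional [selection_rule()] applied before scoring
#'   (the selected set is scored unweighted unless `weights` says otherwise).
#' @param label display label; a readable default is derived.
#' @return an object of class `mr_method`.
#' @export
mr_method <- function(estimator = c("score", "ols", "tsls", "liml", "composite"),
                      weights = c("unweighted", "internal", "cv", "external", "true"),
                      k_folds = 10, external_sd = 0.04, selection = NULL,
                      label = NULL) {
  estimator <- match.arg(estimator)
  weights <- match.arg(weights)
  if (!is.null(selection)) stopifnot(inherits(selection, "selection_rule"))
  if (is.null(label)) {
    label <- switch(estimator,
      ols = "OLS (observational)",
      tsls = "All variants (2SLS)",
      liml = "All variants (LIML)",
      composite = "Composite (main variants + score)",
      score = {
        base <- switch(weights,
          unweighted = "Unweighted score",
          internal = "Internal weights",
          cv = sprintf("Cross-validated weights (%d-fold)", k_folds),
          external = sprintf("External weights (sd=%g)", external_sd),
          true = "True weights")
        if (!is.null(selection)) {
          sel <- if (selection$mode == "top_k")
            sprintf("top %d variants", selection$k)
          else sprintf("P<%g variants", selection$p_cut)
          base <- paste0(base, ", ", sel)
        }
        base
      })
  }
  structure(list(estimator = estimator, weights = weights, k_folds = k_folds,
                 external_sd = external_sd, selection = selection,
                 label = label),
            class = "mr_method")
}

#' Apply a method spec to one dataset
#'
#' @param method an [mr_method()].
#' @param dataset a `sim_dataset` (or compatible list with `genotypes`, `x`,
#'   `y` and, for `"external"`/`"true"` weights and `"composite"`, the
#'   generating `truth`).
#' @return an `iv_estimate`.
#' @export
apply_method <- function(method, dataset) {
  stopifnot(inherits(method, "mr_method"))
  G <- dataset$genotypes
  x <- dataset$x
  y <- dataset$y
  arch <- dataset$truth$arch
  switch(method$estimator,
    ols = ols_estimate(x, y),
    tsls = two_stage_least_squares(G, x, y),
    liml = liml_estimate(G, x, y),
    composite = {
      main <- arch$main
      if (is.null(main) || length(main) == 0L)
        return(score_iv(unweighted_score(G), x, y))
      sec <- unweighted_score(G[, -main, drop = FALSE])
      composite_iv(G[, main, drop = FALSE], sec, x, y)
    },
    score = {
      if (!is.null(method$selection)) {
        sel <- select_variants(G, x, method$selection)
        if (length(sel) == 0L)
          return(non_estimable("score_iv", length(x)))
        G <- G[, sel, drop = FALSE]
        arch_alpha <- if (!is.null(arch)) arch$alpha[sel] else NULL
      } else {
        arch_alpha <- if (!is.null(arch)) arch$alpha else NULL
      }
      sc <- switch(method$weights,
        unweighted = unweighted_score(G),
        internal = internal_weighted_score(G, x),
        cv = cv_weighted_score(G, x, method$k_folds),
        external = {
          if (is.null(arch_alpha))
            stop("external weights need generating truth on the dataset", call. = FALSE)
          external_weighted_score(G, arch_alpha, method$external_sd)
        },
        true = {
          if (is.null(arch_alpha))
            stop("true weights need generating truth on the dataset", call. = FALSE)
          weighted_score(G, arch_alpha, mode = "true")
        })
      score_iv(sc, x, y)
    })
}

# Deterministic 31-bit stream mixing: replicate seeds depend on the master
# seed and the cell's data-generating coordinates (scenario, beta, n, J,
# p_valid, replicate) but NOT on the analysis method, so every method within
# a cell consumes identical datasets (paired comparison).
mix31 <- function(seed, values) {
  m <- 2147483647
  h <- (abs(seed) %% m)
  for (v in values) {
    h <- (h * 48271 + (abs(v) %% m) + 1) %% m
  }
  as.integer(h %% (m - 1L)) + 1L
}

replicate_seed <- function(config, rep) {
  mix31(config$seed, c(match(config$scenario, SCENARIOS),
                       round(config$beta_x * 1e6), config$n, config$J,
                       round(config$p_valid * 1e6), rep))
}

#' Run one Monte Carlo study cell
#'
#' For each of `n_reps` replicates: seed the RNG with a deterministic child
#' seed derived from the master seed and the cell's generating coordinates,
#' redraw the genetic architecture (so randomized architectures vary across
#' replicates), simulate a dataset, apply the method, and record the
#' estimate. Replicate seeds do not involve the method, so methods compared
#' on the same configuration see identical datasets. Non-estimable
#' replicates (e.g. empty variant selection) are dropped from summaries with
#' their count reported.
#'
#' @param config a [sim_config()].
#' @param method an [mr_method()].
#' @param n_reps number of replicates; default `config$n_reps`.
#' @param redraw_architecture redraw the architecture each replicate
#'   (default) or fix the first draw for all replicates.
#' @param details if `TRUE`, attach the per-replicate estimates as attribute
#'   `"replicates"` (a data frame including a dataset checksum).
#' @return a one-row data frame (a "study cell"): `scenario`, `method`,
#'   `beta`, `mean_F`, `median`, `IQR`, `coverage_pct`, `power_pct`,
#'   `n_reps_used`, `mc_se_median`, `mc_se_coverage`.
#' @export
run_cell <- function(config, method, n_reps = config$n_reps,
                     redraw_architecture = TRUE, details = FALSE) {
  stopifnot(inherits(config, "sim_config"), inherits(method, "mr_method"))
  fixed_arch <- NULL
  if (!redraw_architecture) {
    set.seed(replicate_seed(config, 0L))
    fixed_arch <- build_architecture(config)
  }
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(replicate_seed(config, r))
    arch <- if (redraw_architecture) build_architecture(config) else fixed_arch
    dat <- simulate_dataset(config, arch)
    est <- apply_method(method, dat)
    reps[[r]] <- data.frame(
      rep = r,
      beta_hat = est$beta_hat, se = est$se,
      ci_low = est$ci_low, ci_high = est$ci_high,
      f_stat = est$f_stat, estimable = est$estimable,
      checksum = sum(dat$x) + 2 * sum(dat$y) + sum(dat$genotypes))
  }
  reps <- do.call(rbind, reps)
  cell <- summarize_estimates(reps, config$beta_x)
  cell <- cbind(data.frame(scenario = config$scenario, method = method$label,
                           beta = config$beta_x, stringsAsFactors = FALSE),
                cell)
  if (details) attr(cell, "replicates") <- reps
  cell
}

#' Summarize replicate estimates into a study cell
#'
#' Medians are reported rather than means because IV estimate distributions
#' have heavy tails (under weak instruments the mean need not exist).
#' Quartiles use linear interpolation (R's default type 7). Coverage is the
#' percentage of 95% Wald intervals containing the true effect; power is the
#' percentage of replicates with |estimate| / SE > 1.96. Monte Carlo SEs:
#' for coverage, sqrt(p(1-p)/R) x 100; for the median, the asymptotic
#' density-based formula 1.2533 sigma / sqrt(R) with sigma estimated as
#' IQR / 1.349.
#'
#' @param estimates data frame with columns `beta_hat`, `se`, `ci_low`,
#'   `ci_high`, `f_stat`, `estimable` (or a list of `iv_estimate` objects).
#' @param beta_true the generating causal effect.
#' @return a one-row data frame with columns `mean_F`, `median`, `IQR`,
#'   `coverage_pct`, `power_pct`, `n_reps_used`, `mc_se_median`,
#'   `mc_se_coverage`.
#' @export
summarize_estimates <- function(estimates, beta_true) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- do.call(rbind, lapply(estimates, function(e)
      data.frame(beta_hat = e$beta_hat, se = e$se, ci_low = e$ci_low,
                 ci_high = e$ci_high, f_stat = e$f_stat,
                 estimable = e$estimable)))
  }
  ok <- estimates[estimates$estimable & is.finite(estimates$beta_hat), , drop = FALSE]
  r_used <- nrow(ok)
  if (r_used == 0L)
    stop("empty cell: no estimable replicates", call. = FALSE)
  q <- stats::quantile(ok$beta_hat, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  cover <- mean(ok$ci_low <= beta_true & beta_true <= ok$ci_high)
  z <- stats::qnorm(0.975)
  power <- mean(ok$se > 0 & abs(ok$beta_hat) / ok$se > z)
  sigma <- iqr / (2 * stats::qnorm(0.75))
  data.frame(
    mean_F = mean(ok$f_stat[is.finite(ok$f_stat)]),
    median = q[2],
    IQR = iqr,
    coverage_pct = 100 * cover,
    power_pct = 100 * power,
    n_reps_used = r_used,
    mc_se_median = sqrt(pi / 2) * sigma / sqrt(r_used),
    mc_se_coverage = 100 * sqrt(cover * (1 - cover) / r_used))
}

#' Run a grid of study cells
#'
#' Crosses scenarios, methods and causal-effect values, running [run_cell()]
#' for each combination with the shared master seed. Within a
#' (scenario, beta) row all methods see identical simulated datasets.
#'
#' @param config base [sim_config()]; `scenario` and `beta_x` are overridden
#'   by the grid.
#' @param scenarios character vector of scenario names.
#' @param methods list of [mr_method()] specs (a single spec is accepted).
#' @param betas numeric vector of causal effects (default `c(0, 0.2, 0.4)`).
#' @param n_reps replicates per cell; default `config$n_reps`.
#' @param redraw_architecture see [run_cell()].
#' @return a data frame with one row per cell, columns
#'   `scenario,method,beta,mean_F,median,IQR,coverage_pct,power_pct,n_reps_used,mc_se_median,mc_se_coverage`.
#' @export
run_table <- function(config, scenarios = config$scenario, methods,
                      betas = c(0, 0.2, 0.4), n_reps = config$n_reps,
                      redraw_architecture = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(methods, "mr_method")) methods <- list(methods)
  stopifnot(length(scenarios) >= 1, length(methods) >= 1, length(betas) >= 1)
  rows <- list()
  for (sc in scenarios) {
    for (b in betas) {
      cfg <- config
      cfg$scenario <- sc
      cfg$beta_x <- b
      cfg <- validate_config(cfg)
      for (m in methods) {
        rows[[length(rows) + 1L]] <-
          run_cell(cfg, m, n_reps = n_reps,
                   redraw_architecture = redraw_architecture)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a run manifest
#'
#' Records the fully resolved configuration, grid, package version, master
#' seed and per-cell replicate seed heads as JSON, so a run can be reproduced
#' bit-for-bit with [run_table_from_manifest()].
#'
#' @param path output JSON path.
#' @inheritParams run_table
#' @return the manifest (invisibly).
#' @export
write_manifest <- function(path, config, scenarios = config$scenario, methods,
                           betas = c(0, 0.2, 0.4), n_reps = config$n_reps,
                           redraw_architecture = TRUE) {
  if (inherits(methods, "mr_method")) methods <- list(methods)
  manifest <- list(
    package = "allelescore",
    version = as.character(utils::packageVersion("allelescore")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    master_seed = as.integer(config$seed),
    config = unclass(config),
    scenarios = scenarios,
    betas = betas,
    n_reps = n_reps,
    redraw_architecture = redraw_architecture,
    methods = lapply(methods, function(m) {
      m <- unclass(m)
      if (!is.null(m$selection)) m$selection <- unclass(m$selection)
      m
    }),
    cell_seed_heads = {
      heads <- list()
      for (sc in scenarios) for (b in betas) {
        cfg <- config; cfg$scenario <- sc; cfg$beta_x <- b
        heads[[paste(sc, b, sep = "|")]] <- replicate_seed(cfg, 1L)
      }
      heads
    })
  # I(17) = 17 significant digits, enough for doubles to round-trip exactly
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null")
  invisible(manifest)
}

#' Re-run a study from a manifest
#'
#' @param path path to a JSON manifest written by [write_manifest()].
#' @return the [run_table()] result the manifest describes.
#' @export
run_table_from_manifest <- function(path) {
  m <- jsonlite::read_json(path)
  cfg_args <- m$config[names(m$config) %in% names(formals(sim_config))]
  cfg_args <- lapply(cfg_args, function(v) if (is.list(v)) unlist(v) else v)
  config <- do.call(sim_config, cfg_args)
  methods <- lapply(m$methods, function(spec) {
    sel <- spec$selection
    do.call(mr_method, c(
      list(estimator = spec$estimator, weights = spec$weights,
           k_folds = spec$k_folds, external_sd = spec$external_sd,
           label = spec$label),
      if (!is.null(sel) && length(sel))
        list(selection = selection_rule(sel$mode, sel$k, sel$p_cut))))
  })
  run_table(config, scenarios = unlist(m$scenarios), methods = methods,
            betas = as.numeric(unlist(m$betas)), n_reps = m$n_reps,
            redraw_architecture = isTRUE(m$redraw_architecture))
}
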