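test_that("genotype dosages follow Hardy-Weinberg proportions", {
  set.seed(101)
  n <- 3000
  G <- simulate_genotypes(n, 25, 0.3)
  expect_equal(dim(G), c(n, 25))
  expect_true(all(G %in% 0:2))

  # P(dosage = 1) = 2 * 0.3 * 0.7 = 0.42; allow 3 binomial SDs
  p1 <- mean(G == 1)
  expect_lt(abs(p1 - 0.42), 3 * sqrt(0.42 * 0.58 / (n * 25)))

  # empirical allele frequency per column within sampling error of its MAF
  freq <- colMeans(G) / 2
  expect_true(all(abs(freq - 0.3) < 4 * sqrt(0.3 * 0.7 / (2 * n))))

  # mean of row sums: oracle by brute-force enumeration of the two-allele
  # dosage distribution, independent of rbinom
  p <- 0.3
  dosage_pmf <- sapply(0:2, function(d) {
    alleles <- expand.grid(a1 = 0:1, a2 = 0:1)
    sum(apply(alleles, 1, function(a) {
      prod(ifelse(a == 1, p, 1 - p)) * (sum(a) == d)
    }))
  })
  expected_mean <- 25 * sum((0:2) * dosage_pmf)
  expect_equal(expected_mean, 15)  # frozen from the enumeration oracle
  sd_rowsum <- sqrt(25 * 2 * p * (1 - p))
  expect_lt(abs(mean(rowSums(G)) - expected_mean), 3 * sd_rowsum / sqrt(n))
})

test_that("degenerate or invalid genotype arguments are rejected", {
  expect_error(simulate_genotypes(0, 5, 0.3), "positive whole number")
  expect_error(simulate_genotypes(10, 0, 0.3), "positive whole number")
  expect_error(simulate_genotypes(10, 2, c(0.3, 0)), "inside \\(0, 1\\)")
  expect_error(simulate_genotypes(10, 1, 1), "inside \\(0, 1\\)")
  expect_error(simulate_genotypes(10, 1, 1.5), "inside \\(0, 1\\)")
  expect_error(sim_config(maf = 0.6), "maf")
})

test_that("architectures carry the scenario's random structure", {
  set.seed(7)
  cfg <- sim_config()
  arch <- build_architecture(cfg)
  expect_true(all(arch$valid == 1))
  expect_true(all(arch$het_dev == 0))
  expect_identical(nrow(arch$gg_inter), 0L)
  expect_true(all(arch$gx_inter == 0))
  expect_equal(arch$alpha, rep(0.06, 25))

  # variant-variant interactions: on average 0.1 * choose(25, 2) = 30 pairs
  n_gg <- replicate(300, nrow(build_architecture(sim_config(scenario = "gg_interaction"))$gg_inter))
  expect_lt(abs(mean(n_gg) - 30), 3 * sqrt(300 * 0.1 * 0.9) / sqrt(300))

  # variant-covariate interactions: on average 0.5 * 25 = 12.5 variants
  n_gx <- replicate(300, sum(build_architecture(sim_config(scenario = "gx_interaction"))$gx_inter != 0))
  expect_lt(abs(mean(n_gx) - 12.5), 3 * sqrt(25 * 0.25) / sqrt(300))

  # invalid scenario draws validity flags at the requested rate
  v <- replicate(300, mean(build_architecture(sim_config(scenario = "invalid", p_valid = 0.7))$valid))
  expect_lt(abs(mean(v) - 0.7), 0.05)

  # major-gene/polygene: 5x ratio, unweighted-score strength preserved
  arch2 <- build_architecture(sim_config(scenario = "major_polygene"))
  expect_equal(arch2$main, 1:2)
  expect_equal(arch2$alpha[1] / arch2$alpha[3], 5)
  expect_equal(sum(arch2$alpha), 25 * 0.06)
})

test_that("the generating model confounds X and Y positively under the null", {
  set.seed(11)
  slopes <- replicate(20, {
    d <- simulate_dataset(sim_config(n = 1000))
    ols_estimate(d$x, d$y)$beta_hat
  })
  expect_true(all(slopes > 0))
  # closed form: cov(X,Y)/var(X) = 1 / (25*0.06^2*0.42 + 2) under the null
  expect_lt(abs(mean(slopes) - 1 / (25 * 0.06^2 * 0.42 + 2)), 0.03)

  # no causal path and no confounding: OLS slope near zero
  set.seed(12)
  d0 <- simulate_dataset(sim_config(n = 4000, conf_coef_x = 0, conf_coef_y = 0))
  e <- ols_estimate(d0$x, d0$y)
  expect_lt(abs(e$beta_hat), 3 * e$se)
})

test_that("heterozygote deviations reproduce recessive and dominant codings", {
  cfg <- sim_config(n = 500, J = 4, conf_coef_x = 0, conf_coef_y = 0,
                    err_sd_x = 0, err_sd_y = 0)
  base <- genetic_architecture(4, 0.3, cfg$alpha)

  set.seed(33)
  rec <- base; rec$het_dev <- -rec$alpha
  d <- simulate_dataset(cfg, rec)
  G <- d$genotypes
  # recessive: heterozygotes contribute nothing, only minor homozygotes count
  expect_equal(d$x, drop((G == 2) %*% (2 * rec$alpha)))

  set.seed(33)
  dom <- base; dom$het_dev <- +dom$alpha
  d2 <- simulate_dataset(cfg, dom)
  G2 <- d2$genotypes
  # dominant: carrying one or two minor alleles contributes equally
  expect_equal(d2$x, drop((G2 >= 1) %*% (2 * dom$alpha)))
})

test_that("invalid instruments bias the score IV along the confounder pathway", {
  # With an invalid fraction f and unit confounder coefficients, the score
  # IV estimand under the null is f (derivation: cov(S, Y) = f * sum(alpha) * 2pq,
  # cov(S, X) = sum(alpha) * 2pq). At f = 1 every variant acts only through
  # U and the estimand is the confounder-pathway ratio c_Y / c_X = 1.
  set.seed(55)
  cfg <- sim_config(scenario = "invalid", p_valid = 0, n = 60000)
  d <- simulate_dataset(cfg)
  iv <- score_iv(unweighted_score(d$genotypes), d$x, d$y)
  expect_lt(abs(iv$beta_hat - 1), 4 * iv$se)

  set.seed(56)
  cfg3 <- sim_config(scenario = "invalid", p_valid = 0.7, n = 60000)
  d3 <- simulate_dataset(cfg3)
  iv3 <- score_iv(unweighted_score(d3$genotypes), d3$x, d3$y)
  expect_lt(abs(iv3$beta_hat - 0.3), 5 * iv3$se)
})

test_that("dataset structure matches the configuration", {
  set.seed(2)
  d <- simulate_dataset(sim_config(scenario = "gx_interaction", n = 150, J = 3))
  expect_s3_class(d, "sim_dataset")
  expect_equal(length(d$x), 150)
  expect_equal(length(d$y), 150)
  expect_equal(length(d$u), 150)
  expect_equal(length(d$v), 150)
  expect_null(simulate_dataset(sim_config(n = 50, J = 2))$v)
  expect_error(simulate_dataset(sim_config(J = 3),
                                genetic_architecture(2, 0.3, 0.1)),
               "variants")
})
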