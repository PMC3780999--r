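test_that("unweighted score is the allele count", {
  G <- matrix(c(0, 1, 2, 2, 0, 1), ncol = 2)
  s <- unweighted_score(G)
  expect_equal(s$values, rowSums(G))
  expect_equal(s$weights, c(1, 1))

  g1 <- matrix(c(0, 2, 1, 1), ncol = 1)
  expect_equal(unweighted_score(g1)$values, drop(g1))

  sat <- matrix(2, nrow = 4, ncol = 7)
  expect_equal(unweighted_score(sat)$values, rep(14, 4))

  expect_error(unweighted_score(matrix(numeric(0), 0, 0)), "at least one")
})

test_that("internal weights solve the joint first-stage normal equations", {
  # 10-row fixture; oracle solves the normal equations directly with solve()
  G <- matrix(c(0, 1, 2, 1, 0, 2, 1, 0, 1, 2,
                1, 0, 1, 2, 0, 1, 2, 1, 0, 0,
                2, 1, 0, 0, 1, 2, 0, 1, 2, 1), ncol = 3)
  x <- c(0.4, 0.8, 1.9, 1.5, 0.1, 2.2, 1.6, 0.6, 0.9, 1.1)
  X <- cbind(1, G)
  oracle <- drop(solve(t(X) %*% X, t(X) %*% x))[-1]
  expect_equal(estimate_weights(G, x), oracle, tolerance = 1e-12)

  # exact linear relation: single variant, x = 2 g
  g <- matrix(c(0, 1, 2, 1, 0, 2), ncol = 1)
  expect_equal(estimate_weights(g, drop(2 * g)), 2)

  # consistency: no confounding, large n -> weights near true alpha
  set.seed(9)
  d <- simulate_dataset(sim_config(n = 20000, J = 5, conf_coef_x = 0,
                                   conf_coef_y = 0))
  w <- estimate_weights(d$genotypes, d$x)
  expect_true(all(abs(w - d$truth$arch$alpha) < 4 * 1 / sqrt(20000 * 0.42)))

  # duplicated column -> singular design
  Gdup <- cbind(G, G[, 1])
  expect_error(estimate_weights(Gdup, x), "singular design")
})

test_that("cross-validated weights never see the scored individual's fold", {
  set.seed(21)
  d <- small_sim(n = 3000, J = 6)
  sc <- cv_weighted_score(d$genotypes, d$x, k_folds = 2)
  expect_equal(sort(as.integer(table(sc$folds))), c(1500L, 1500L))

  # each half is scored with weights estimated on the other half only,
  # recomputed here independently from the recorded fold assignment
  for (f in 1:2) {
    hold <- sc$folds == f
    w_other <- estimate_weights(d$genotypes[!hold, , drop = FALSE], d$x[!hold])
    expect_equal(sc$fold_weights[f, ], w_other, tolerance = 1e-12)
    expect_equal(sc$values[hold],
                 drop(d$genotypes[hold, , drop = FALSE] %*% w_other),
                 tolerance = 1e-12)
  }

  # no-leakage audit: deleting any held-out individual's row from their own
  # fold-complement fit changes nothing (their row never entered the fit)
  set.seed(22)
  d2 <- small_sim(n = 60, J = 3, seed = 23)
  sc2 <- cv_weighted_score(d2$genotypes, d2$x, k_folds = 3)
  for (i in c(1, 17, 60)) {
    f <- sc2$folds[i]
    keep <- sc2$folds != f
    expect_false(keep[i])
    w_del <- estimate_weights(d2$genotypes[keep & seq_len(60) != i, , drop = FALSE],
                              d2$x[keep & seq_len(60) != i])
    expect_equal(sc2$fold_weights[f, ], w_del, tolerance = 1e-12)
  }

  expect_error(cv_weighted_score(d2$genotypes, d2$x, k_folds = 61),
               "cannot exceed")
  expect_error(cv_weighted_score(d2$genotypes, d2$x, k_folds = 1), "at least 2")
})

test_that("noise-free equal-weight data make CV and unweighted scores equivalent", {
  set.seed(31)
  G <- simulate_genotypes(200, 4, 0.3)
  x <- rowSums(G) * 0.25          # exact equal-weight sum, no noise
  y <- 2 * x + rnorm(200)
  sc_cv <- cv_weighted_score(G, x, k_folds = 2)
  expect_equal(cor(sc_cv$values, unweighted_score(G)$values), 1, tolerance = 1e-9)
  est_cv <- score_iv(sc_cv, x, y)
  est_uw <- score_iv(unweighted_score(G), x, y)
  expect_equal(est_cv$beta_hat, est_uw$beta_hat, tolerance = 1e-9)
})

test_that("external weights perturb the truth and sd = 0 recovers it", {
  set.seed(41)
  G <- simulate_genotypes(100, 8, 0.3)
  w_true <- rep(0.06, 8)
  s0 <- external_weighted_score(G, w_true, sd = 0)
  expect_equal(s0$weights, w_true)
  expect_equal(s0$mode, "true")
  s1 <- external_weighted_score(G, w_true, sd = 0.04)
  expect_false(any(s1$weights == w_true))
  devs <- replicate(500, external_weighted_score(G, w_true, 0.04)$weights - w_true)
  expect_lt(abs(sd(devs) - 0.04), 0.003)
  expect_error(external_weighted_score(G, w_true, sd = -1), "non-negative")
})

test_that("variant selection ranks by univariate association strength", {
  set.seed(51)
  G <- simulate_genotypes(500, 4, 0.3)
  x <- 1.0 * G[, 3] + 0.5 * G[, 1] + rnorm(500, sd = 0.2)

  expect_equal(select_variants(G, x, selection_rule("top_k", k = 1)), 3L)
  expect_equal(select_variants(G, x, selection_rule("top_k", k = 2)), c(1L, 3L))
  expect_equal(select_variants(G, x, selection_rule("top_k", k = 4)), 1:4)
  expect_equal(select_variants(G, x, selection_rule("p_threshold", p_cut = 1)), 1:4)

  # threshold agrees with per-variant lm() P-values computed independently
  p_lm <- apply(G, 2, function(g) summary(lm(x ~ g))$coefficients[2, 4])
  expect_equal(select_variants(G, x, selection_rule("p_threshold", p_cut = 0.01)),
               sort(unname(which(p_lm < 0.01))))

  # an unassociated pure-noise x can select nothing at a strict threshold
  x0 <- rnorm(500)
  strict <- selection_rule("p_threshold", p_cut = 1e-12)
  expect_length(select_variants(G, x0, strict), 0)

  expect_error(selection_rule("top_k", k = 0), "positive whole number")
  expect_error(selection_rule("p_threshold", p_cut = 0), "in \\(0, 1\\]")
})

test_that("reorientation flips risk-decreasing variants", {
  set.seed(61)
  G <- simulate_genotypes(400, 3, 0.3)
  x <- 0.5 * G[, 1] - 0.5 * G[, 2] + 0.5 * G[, 3] + rnorm(400, sd = 0.3)
  expect_warning(G2 <- reorient_genotypes(G, x), "data-driven")
  expect_equal(attr(G2, "flipped"), 2L)
  expect_equal(G2[, 2], 2 - G[, 2])
  expect_equal(G2[, 1], G[, 1])
})

test_that("score-based IV estimates are invariant to positive weight rescaling", {
  set.seed(71)
  d <- small_sim(n = 500, J = 5, seed = 72)
  w <- estimate_weights(d$genotypes, d$x)
  s1 <- weighted_score(d$genotypes, w)
  s2 <- weighted_score(d$genotypes, 13.7 * w)
  e1 <- score_iv(s1, d$x, d$y)
  e2 <- score_iv(s2, d$x, d$y)
  expect_equal(e1$beta_hat, e2$beta_hat, tolerance = 1e-10)
  expect_equal(e1$se, e2$se, tolerance = 1e-10)
  expect_equal(e1$f_stat, e2$f_stat, tolerance = 1e-8)
})
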