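# Small deterministic fixtures shared across test files.

# A fixed 8-row single-instrument table for covariance-ratio checks.
iv_fixture_8 <- function() {
  list(
    z = c(0, 1, 2, 1, 0, 2, 1, 0),
    x = c(0.3, 1.1, 2.4, 0.9, -0.2, 2.1, 1.4, 0.1),
    y = c(0.5, 1.0, 2.2, 1.3, 0.1, 1.9, 1.2, -0.3)
  )
}

# A fixed n = 12 dataset with two instruments for LIML oracle checks.
liml_fixture_12 <- function() {
  Z <- cbind(c(0, 1, 2, 0, 1, 2, 0, 1, 2, 0, 1, 2),
             c(1, 0, 1, 2, 0, 1, 0, 2, 1, 1, 2, 0))
  x <- c(0.2, 0.9, 2.1, 1.0, 0.3, 1.8, -0.1, 1.6, 1.9, 0.7, 1.5, 0.8)
  y <- c(0.4, 0.7, 1.6, 1.2, 0.2, 1.5, 0.1, 1.4, 1.3, 0.8, 1.6, 0.5)
  list(Z = Z, x = x, y = y)
}

# Independent first-stage F oracle via explicit ANOVA sums of squares.
f_oracle <- function(Z, x) {
  fit <- lm(x ~ Z)
  rss <- sum(residuals(fit)^2)
  tss <- sum((x - mean(x))^2)
  J <- qr(cbind(1, Z))$rank - 1
  ((tss - rss) / J) / (rss / (length(x) - J - 1))
}

# Random-but-reproducible small dataset for identity/property checks.
small_sim <- function(n = 400, J = 6, seed = 42, ...) {
  set.seed(seed)
  simulate_dataset(sim_config(n = n, J = J, ...))
}
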