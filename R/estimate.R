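#' @keywords internal
new_iv_estimate <- function(beta_hat, se, f_stat, n_instruments, method, n,
                            kappa = NA_real_, estimable = TRUE) {
  z <- stats::qnorm(0.975)
  structure(list(beta_hat = beta_hat, se = se,
                 ci_low = beta_hat - z * se, ci_high = beta_hat + z * se,
                 f_stat = f_stat, n_instruments = n_instruments,
                 method = method, n = n, kappa = kappa, estimable = estimable),
            class = "iv_estimate")
}

non_estimable <- function(method, n, n_instruments = NA_integer_, f_stat = NA_real_) {
  est <- new_iv_estimate(NA_real_, NA_real_, f_stat, n_instruments, method, n,
                         estimable = FALSE)
  est$ci_low <- est$ci_high <- NA_real_
  est
}

as_instrument_matrix <- function(instruments) {
  if (inherits(instruments, "allele_score")) instruments <- instruments$values
  Z <- as.matrix(instruments)
  if (!is.numeric(Z)) stop("instruments must be numeric", call. = FALSE)
  Z
}

#' Observational (ordinary least squares) estimate
#'
#' The least-squares slope of the outcome on the risk factor with an
#' intercept: the confounded observational association that IV analysis is
#' designed to correct. Serves as the reference direction for
#' weak-instrument and invalid-instrument bias.
#'
#' @param x risk-factor vector.
#' @param y outcome vector, same length.
#' @return an `iv_estimate` with method `"ols"` (`f_stat` is `NA`).
#' @export
ols_estimate <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have the same length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2)
  if (sxx <= 0) stop("singular design: x has zero variance", call. = FALSE)
  beta <- sum(xc * yc) / sxx
  resid <- yc - beta * xc
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  new_iv_estimate(beta, se, NA_real_, 0L, "ols", n)
}

# Demeaned first-stage workspace shared by the IV estimators.
iv_workspace <- function(instruments, x, y) {
  Z <- as_instrument_matrix(instruments)
  n <- nrow(Z)
  if (length(x) != n || length(y) != n)
    stop("instruments, x and y must have the same number of rows", call. = FALSE)
  J <- ncol(Z)
  if (n <= J + 1)
    stop("need more observations than instruments plus intercept", call. = FALSE)
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  qz <- qr(Zc)
  if (qz$rank < J)
    stop("singular design: instrument matrix is rank deficient", call. = FALSE)
  xc <- x - mean(x); yc <- y - mean(y)
  xhat <- qr.fitted(qz, xc)
  sxx <- sum(xc^2)
  r2 <- if (sxx > 0) sum(xhat^2) / sxx else 0
  f <- if (r2 < 1) (r2 / (1 - r2)) * (n - J - 1) / J else Inf
  list(n = n, J = J, qz = qz, xc = xc, yc = yc, xhat = xhat,
       yhat = qr.fitted(qz, yc), f = f)
}

#' First-stage F statistic for instrument strength
#'
#' The overall F statistic from the least-squares regression of the risk
#' factor on the instruments with an intercept:
#' F = (R^2 / (1 - R^2)) (n - J - 1) / J. The expected (not the realized) F
#' governs weak-instrument bias; values near 1 indicate instruments
#' explaining no more variance than chance.
#'
#' @param instruments numeric matrix (or vector, or `allele_score`) of
#'   instruments.
#' @param x risk-factor vector.
#' @return the F statistic (non-negative scalar).
#' @export
first_stage_f <- function(instruments, x) {
  iv_workspace(instruments, x, x * 0)$f
}

#' Two-stage least squares
#'
#' Stage one regresses the risk factor on the instruments (with intercept);
#' stage two regresses the outcome on the fitted risk factor. The standard
#' error is the conventional homoskedastic 2SLS asymptotic SE, with
#' second-stage residuals computed using the observed (not fitted) risk
#' factor. Confidence intervals are Wald: estimate +/- 1.96 SE. With many
#' instruments that are individually weak, this estimator is biased towards
#' the confounded observational association.
#'
#' @inheritParams first_stage_f
#' @param y outcome vector.
#' @return an `iv_estimate` with method `"tsls"` and the first-stage F.
#' @export
two_stage_least_squares <- function(instruments, x, y) {
  w <- iv_workspace(instruments, x, y)
  bx <- sum(w$xhat * w$xc)          # x'P x on demeaned data
  if (abs(bx) < .Machine$double.eps * w$n)
    return(non_estimable("tsls", w$n, w$J, w$f))
  beta <- sum(w$xhat * w$yc) / bx
  resid <- w$yc - beta * w$xc
  sigma2 <- sum(resid^2) / (w$n - 2)
  new_iv_estimate(beta, sqrt(sigma2 / bx), w$f, w$J, "tsls", w$n)
}

#' k-class instrumental-variable estimator
#'
#' The k-class family interpolates between OLS and IV fits:
#' \deqn{\hat\beta(k) = [x'(I - k M_Z)x]^{-1} x'(I - k M_Z)y}
#' on intercept-residualized data, where M_Z is the residual maker of the
#' instruments. `k = 0` reproduces OLS, `k = 1` reproduces 2SLS, and
#' [liml_estimate()] sets k to the smallest root of the LIML determinantal
#' equation. The SE is the homoskedastic k-class asymptotic SE.
#'
#' @inheritParams two_stage_least_squares
#' @param k the k-class parameter.
#' @return an `iv_estimate` with method `"kclass"` (`$kappa` records k).
#' @export
k_class <- function(instruments, x, y, k) {
  w <- iv_workspace(instruments, x, y)
  kclass_from_workspace(w, k, "kclass")
}

kclass_from_workspace <- function(w, k, method) {
  ex <- w$xc - w$xhat; ey <- w$yc - w$yhat   # M_Z residuals
  xkx <- sum(w$xc^2) - k * sum(ex^2)
  if (abs(xkx) < .Machine$double.eps * w$n)
    return(non_estimable(method, w$n, w$J, w$f))
  xky <- sum(w$xc * w$yc) - k * sum(ex * ey)
  beta <- xky / xkx
  resid <- w$yc - beta * w$xc
  sigma2 <- sum(resid^2) / (w$n - 2)
  est <- new_iv_estimate(beta, sqrt(sigma2 / xkx), w$f, w$J, method, w$n,
                         kappa = k)
  est
}

#' Limited information maximum likelihood (LIML) estimator
#'
#' The k-class estimator with k set to the smallest root \eqn{\lambda_{min}}
#' of the determinantal equation \eqn{det(W'M_1 W - \lambda W' M_Z W) = 0},
#' where W = [y, x] and M_1, M_Z are the residual makers of the intercept and
#' of intercept plus instruments. Because W has two columns the equation is a
#' quadratic and \eqn{\lambda_{min}} is computed in closed form. In
#' overidentified models \eqn{\lambda_{min} \ge 1}; with a single instrument
#' it equals 1 and LIML coincides with 2SLS. LIML is approximately
#' median-unbiased under many weak instruments, though its default
#' (non-Bekker) standard errors under-cover as the instrument count grows.
#'
#' @inheritParams two_stage_least_squares
#' @return an `iv_estimate` with method `"liml"`; `$kappa` holds
#'   \eqn{\lambda_{min}}.
#' @export
liml_estimate <- function(instruments, x, y) {
  w <- iv_workspace(instruments, x, y)
  ex <- w$xc - w$xhat; ey <- w$yc - w$yhat
  # 2x2 cross-product matrices of W = [y, x]: A = W'M_1 W, B = W'M_Z W
  a11 <- sum(w$yc^2); a12 <- sum(w$yc * w$xc); a22 <- sum(w$xc^2)
  b11 <- sum(ey^2);   b12 <- sum(ey * ex);     b22 <- sum(ex^2)
  # det(A - lambda B) = qa lambda^2 - qb lambda + qc
  qa <- b11 * b22 - b12^2
  qb <- a11 * b22 + a22 * b11 - 2 * a12 * b12
  qc <- a11 * a22 - a12^2
  disc <- qb^2 - 4 * qa * qc
  if (!is.finite(qa) || qa <= 0 || disc < -1e-8 * max(qb^2, 1))
    stop("LIML lambda_min computation failed: degenerate cross-product matrices",
         call. = FALSE)
  lambda <- (qb - sqrt(max(disc, 0))) / (2 * qa)
  kclass_from_workspace(w, lambda, "liml")
}

#' Allele-score instrumental-variable estimate
#'
#' Two-stage least squares with the allele score as the single instrument
#' (with one instrument, 2SLS, LIML and the ratio-of-coefficients estimator
#' coincide). Records the score's first-stage F statistic. The estimate is
#' invariant to rescaling the score weights by any positive constant.
#'
#' @param score an `allele_score` (or numeric score vector).
#' @inheritParams two_stage_least_squares
#' @return an `iv_estimate` with method `"score_iv"`.
#' @export
score_iv <- function(score, x, y) {
  est <- two_stage_least_squares(as_instrument_matrix(score), x, y)
  est$method <- "score_iv"
  est
}

#' Composite estimator: main variants plus secondary-score instrument
#'
#' For major-gene/polygene architectures: 2SLS with one instrument per main
#' variant plus the unweighted score of the remaining (secondary) variants
#' (e.g. 3 instruments for 2 main variants). With zero main variants this
#' reduces to [score_iv()]. Main variants must not also contribute to the
#' secondary score.
#'
#' @param main_genotypes n x m dosage matrix of the main variants (m >= 0
#'   columns).
#' @param secondary_score an `allele_score` built from the remaining
#'   variants.
#' @inheritParams two_stage_least_squares
#' @return an `iv_estimate` with method `"composite"`.
#' @export
composite_iv <- function(main_genotypes, secondary_score, x, y) {
  score_values <- as_instrument_matrix(secondary_score)
  if (is.null(main_genotypes) || NCOL(main_genotypes) == 0L) {
    est <- score_iv(score_values, x, y)
    est$method <- "composite"
    return(est)
  }
  Z <- cbind(as.matrix(main_genotypes), score_values)
  est <- two_stage_least_squares(Z, x, y)
  est$method <- "composite"
  est
}

#' @export
print.iv_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("IV estimate (%s): non-estimable\n", x$method))
    return(invisible(x))
  }
  cat(sprintf("IV estimate (%s): beta = %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$method, x$beta_hat, x$se, x$ci_low, x$ci_high))
  if (is.finite(x$f_stat))
    cat(sprintf("  first-stage F = %.1f on %d instrument(s), n = %d\n",
                x$f_stat, x$n_instruments, x$n))
  invisible(x)
}
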