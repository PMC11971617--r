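#' Conditional cumulants of the latent trait given a score pattern
#'
#' The conditional cumulant of order `j` of the latent trait given pattern `y`
#' is the `j`-th derivative of the fitted CGF at `u = alpha' y_tilde`:
#' `kappa_j|y = sum_{r=j}^{v} lambda_r u^(r-j) / (r-j)!`.  In particular
#' `kappa_1|y` is the EAP person score and `kappa_2|y` the conditional latent
#' variance; both are exact functions of `u`, so the EAP is strictly
#' increasing in `u` and the variance is non-negative by the convexity
#' constraint.
#'
#' @param fit A [gpcm()] fit (or a bare [gpcm_model()]).
#' @param y One pattern (vector) or several (matrix rows).
#' @param j_max Highest cumulant order to return (default `v - 1`, the orders
#'   the truncated CGF can generate as cumulants).
#' @return Data frame with columns `pattern`, `u` and `kappa1` .. `kappa<j_max>`.
#' @export
conditional_cumulants <- function(fit, y, j_max = NULL) {
  model <- as_gpcm_model(fit)
  v <- model$spec$v
  if (is.null(j_max)) j_max <- v - 1L
  if (j_max < 1L || j_max > v) stop("'j_max' must be between 1 and v")
  Y <- check_patterns(if (is.matrix(y)) y else rbind(y), model$design)
  u <- model_u(model, Y)
  out <- data.frame(pattern = pattern_string(Y), u = u)
  for (j in seq_len(j_max))
    out[[paste0("kappa", j)]] <- cgf_derivative(u, model$lambda, j)
  out
}

#' EAP person scores and conditional latent variances
#'
#' Expected a posteriori scoring: for each score pattern, the conditional mean
#' (`eap`) and variance (`var`) of the latent trait given that pattern, under
#' the fitted model.  By identification the reference pattern scores exactly
#' `(0, 1)`.
#'
#' @param fit A [gpcm()] fit.
#' @param data A [pattern_counts()] to score; defaults to the fitted data.
#' @return Data frame with columns `pattern`, `n`, `u`, `eap`, `var`.
#' @export
eap <- function(fit, data = NULL) {
  if (is.null(data)) data <- fit$data
  cc <- conditional_cumulants(fit, data$y, j_max = 2L)
  data.frame(pattern = cc$pattern, n = data$counts, u = cc$u,
             eap = cc$kappa1, var = cc$kappa2)
}

#' Conditional moment-generating function of the latent trait
#'
#' `M(z | y) = exp(sum_r lambda_r ((z + u)^r - u^r) / r!)` with
#' `u = alpha' y_tilde`: the MGF of the latent trait given pattern `y`, whose
#' log-derivatives at `z = 0` are the conditional cumulants.
#'
#' @param fit A [gpcm()] fit (or [gpcm_model()]).
#' @param y A score pattern.
#' @param z Numeric vector of MGF arguments.
#' @return Numeric vector `M(z | y)`.
#' @export
conditional_mgf <- function(fit, y, z) {
  model <- as_gpcm_model(fit)
  u <- model_u(model, check_patterns(rbind(y), model$design))
  vapply(z, function(zz) {
    exp(cgf_derivative(u + zz, model$lambda) - cgf_derivative(u, model$lambda))
  }, numeric(1))
}

#' Convert cumulants to non-central moments (orders 1-4)
#'
#' Standard conversion: `mu'1 = k1`, `mu'2 = k2 + k1^2`,
#' `mu'3 = k3 + 3 k1 k2 + k1^3`,
#' `mu'4 = k4 + 4 k1 k3 + 3 k2^2 + 6 k1^2 k2 + k1^4`.
#'
#' @param kappa Numeric vector of length 4 (or a 4-column matrix, rows
#'   converted independently).
#' @return Vector (or matrix) of the first four non-central moments.
#' @export
moments_from_cumulants <- function(kappa) {
  K <- if (is.matrix(kappa)) kappa else rbind(kappa)
  if (ncol(K) != 4L) stop("'kappa' must supply cumulant orders 1..4")
  m <- cbind(
    K[, 1L],
    K[, 2L] + K[, 1L]^2,
    K[, 3L] + 3 * K[, 1L] * K[, 2L] + K[, 1L]^3,
    K[, 4L] + 4 * K[, 1L] * K[, 3L] + 3 * K[, 2L]^2 +
      6 * K[, 1L]^2 * K[, 2L] + K[, 1L]^4)
  colnames(m) <- paste0("mu", 1:4)
  if (is.matrix(kappa)) m else drop(m)
}

#' Latent population moments and cumulants over the support
#'
#' By the law of total expectation, the `j`-th non-central moment of the
#' latent trait in the subpopulation defined by `B` averages the per-pattern
#' conditional non-central moments over patterns, weighted by the fitted
#' pattern probabilities `P(Y = y | B)` (optionally by observed relative
#' frequencies, for sensitivity analysis).  The first four population
#' cumulants then follow by the inverse conversion; for the fourth,
#' `kappa4 = mu'4 - 4 mu'3 mu'1 - 3 (mu'2)^2 + 12 mu'2 (mu'1)^2 - 6 (mu'1)^4`
#' (the `"cubed"` variant replaces `(mu'2)^2` by `(mu'2)^3`, reproducing a
#' variant of the conversion found in some published tabulations).
#'
#' @param fit A [gpcm()] fit.
#' @param weights `"model"` (fitted probabilities; default) or `"observed"`
#'   (sample relative frequencies).
#' @param kappa4 `"standard"` (default) or `"cubed"` (see above).
#' @return List with `moments` (`mu1` .. `mu4`, non-central) and `cumulants`
#'   (`kappa1` .. `kappa4`).
#' @export
population_cumulants <- function(fit, weights = c("model", "observed"),
                                 kappa4 = c("standard", "cubed")) {
  weights <- match.arg(weights)
  kappa4 <- match.arg(kappa4)
  model <- as_gpcm_model(fit)
  # Conditional cumulants of orders 1..4 for every support pattern (orders
  # above v are zero under the truncated CGF).
  u <- model_u(model, model$B)
  K <- vapply(1:4, function(j)
    if (j <= model$spec$v) cgf_derivative(u, model$lambda, j)
    else rep(0, length(u)), numeric(length(u)))
  m_y <- moments_from_cumulants(matrix(K, nrow = length(u)))
  wts <- if (weights == "model") {
    pattern_probabilities(model)
  } else {
    if (!inherits(fit, "gpcm_fit"))
      stop("observed weighting requires a fitted object with data")
    idx <- match_support(model, fit$data)
    p <- numeric(nrow(model$B)); p[idx] <- fit$data$counts / fit$data$n
    p
  }
  mu <- drop(crossprod(m_y, wts))
  names(mu) <- paste0("mu", 1:4)
  k2term <- if (kappa4 == "standard") mu[2L]^2 else mu[2L]^3
  kap <- c(
    kappa1 = unname(mu[1L]),
    kappa2 = unname(mu[2L] - mu[1L]^2),
    kappa3 = unname(mu[3L] - 3 * mu[2L] * mu[1L] + 2 * mu[1L]^3),
    kappa4 = unname(mu[4L] - 4 * mu[3L] * mu[1L] - 3 * k2term +
                      12 * mu[2L] * mu[1L]^2 - 6 * mu[1L]^4))
  list(moments = mu, cumulants = kap)
}

as_gpcm_model <- function(x) {
  if (inherits(x, "gpcm_fit")) x$model
  else if (inherits(x, "gpcm_model")) x
  else stop("expected a 'gpcm_fit' or 'gpcm_model' object")
}
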