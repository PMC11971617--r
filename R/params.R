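#' Item threshold and location parameters with delta-method standard errors
#'
#' Back-transforms the fitted category-location parameters `beta[i,s]` to the
#' interpretable GPCM parameters: thresholds
#' `delta[i,s] = (beta[i,s-1] - beta[i,s]) / alpha[i]` (with `beta[i,0] = 0`),
#' the latent value where categories `s - 1` and `s` are equiprobable, and
#' mean thresholds `omega[i,s] = -beta[i,s] / (s * alpha[i])`.  Standard
#' errors come from the delta method applied to the full free-parameter
#' covariance.
#'
#' @param fit A [gpcm()] fit.
#' @return Data frame with one row per item category: `item`, `category`,
#'   `beta`, `se_beta`, `delta`, `se_delta`, `omega`, `se_omega`.
#' @export
item_parameters <- function(fit) {
  stopifnot(inherits(fit, "gpcm_fit"))
  model <- fit$model
  if (model$type != "gpcm")
    stop("thresholds are defined for the GPCM scaling structure only")
  design <- model$design
  if (any(abs(model$alpha) < 1e-8))
    stop("alpha estimate is (numerically) zero; thresholds undefined")
  V <- vcov(fit)
  p <- fit$np
  off <- c(0L, cumsum(design$m))
  rows <- lapply(seq_len(design$k), function(i) {
    ai <- model$alpha[i]
    ia <- sum(design$m) + i                      # index of alpha[i] in theta
    do.call(rbind, lapply(seq_len(design$m[i]), function(s) {
      ib <- off[i] + s                           # index of beta[i,s]
      b <- model$beta[ib]
      b_prev <- if (s > 1L) model$beta[ib - 1L] else 0
      delta <- (b_prev - b) / ai
      omega <- -b / (s * ai)
      gd <- numeric(p); go <- numeric(p)
      gd[ib] <- -1 / ai
      if (s > 1L) gd[ib - 1L] <- 1 / ai
      gd[ia] <- -delta / ai
      go[ib] <- -1 / (s * ai)
      go[ia] <- -omega / ai
      data.frame(item = i, category = s, beta = b,
                 se_beta = sqrt(V[ib, ib]),
                 delta = delta, se_delta = sqrt(drop(gd %*% V %*% gd)),
                 omega = omega, se_omega = sqrt(drop(go %*% V %*% go)))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimated cumulant coefficients of the latent trait at the reference pattern
#'
#' Returns `lambda_r = (r - 2)! * h_{r-2}(eps1, eps2)` for `r = 2, ..., v`
#' with delta-method standard errors.  For `r <= v - 1` these are the
#' conditional cumulants `kappa_r` of the latent trait given the reference
#' pattern (`kappa_2 = 1` by identification); the top coefficient `lambda_v`
#' is a Taylor remainder coefficient, not a cumulant.
#'
#' @param fit A [gpcm()] or [nominal_gpcm()] fit.
#' @return Data frame with columns `order` (r), `label` (`"kappa3"`, ...,
#'   `"lambdav"`), `estimate`, `se`.
#' @export
latent_cumulants <- function(fit) {
  stopifnot(inherits(fit, "gpcm_fit"))
  model <- fit$model
  spec <- model$spec
  v <- spec$v; q <- spec$q
  lam <- model$lambda[2:v]
  # Jacobian of lambda_r (r = 2..v) wrt the free parameters (eps block only).
  J <- matrix(0, v - 1L, fit$np)
  ie <- fit$np - spec$n_free_eps
  for (r in 2:v) {
    cc <- r - 2L
    for (j in seq_len(q)) {
      if (cc - j >= 0L && cc - j <= q)
        J[r - 1L, ie + j] <- factorial(cc) * 2 * model$eps1[cc - j + 1L]
    }
    for (j in seq_len(spec$deg2)) {
      if (cc - j >= 0L && cc - j <= spec$deg2)
        J[r - 1L, ie + q + j] <- factorial(cc) * 2 * model$eps2[cc - j + 1L]
    }
  }
  V <- vcov(fit)
  se <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
  data.frame(
    order = 2:v,
    label = ifelse(2:v <= v - 1L, paste0("kappa", 2:v), paste0("lambda", v)),
    estimate = unname(lam), se = se)
}
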