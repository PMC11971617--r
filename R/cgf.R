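#' Specify the truncated convex cumulant-generating function
#'
#' The conditional cumulant-generating function (CGF) of the latent trait given
#' the reference pattern is truncated at an even order `v`, giving a degree-`v`
#' polynomial `K(u) = sum_{r=1}^{v} lambda_r u^r / r!`.  Convexity is enforced
#' by writing its second derivative, a polynomial of degree `v - 2 = 2q`, as a
#' sum of two squared polynomials `p1(u)^2 + p2(u)^2` with coefficient vectors
#' `eps1` (degree `q`) and `eps2` (degree `deg2`, either `q` or `q - 1`).
#' Identification fixes `lambda1 = 0` and, via `eps1[0]^2 + eps2[0]^2 = 1`,
#' `lambda2 = 1`, anchoring the latent scale's location and unit at the
#' reference pattern.
#'
#' @param v Even truncation order, `v >= 2`.
#' @param deg2 Degree of the second polynomial: `q` or `q - 1` (the default,
#'   parsimonious choice; clamped at 0 when `v = 2`).
#' @param eps_fixed Length-2 vector `(eps10, eps20)` with unit sum of squares;
#'   default `c(3/5, 4/5)`, with `c(1, 1)/sqrt(2)` the usual alternative.
#' @return Object of class `"cgf_spec"` with elements `v`, `q`, `deg2`,
#'   `eps10`, `eps20`, and `n_free_eps = q + deg2`.
#' @examples
#' cgf_spec(6)          # q = 2, deg2 = 1: three free shape parameters
#' cgf_spec(2)          # conditionally normal sub-model, no free shape
#' @export
cgf_spec <- function(v = 6L, deg2 = NULL, eps_fixed = c(3 / 5, 4 / 5)) {
  v <- as.integer(v)
  if (length(v) != 1L || v < 2L || v %% 2L != 0L)
    stop("'v' must be an even integer >= 2")
  q <- (v - 2L) %/% 2L
  if (is.null(deg2)) deg2 <- max(0L, q - 1L)
  deg2 <- as.integer(deg2)
  if (!(deg2 %in% unique(c(max(0L, q - 1L), q))))
    stop(sprintf("'deg2' must be %d or %d for v = %d", max(0L, q - 1L), q, v))
  eps_fixed <- as.numeric(eps_fixed)
  if (length(eps_fixed) != 2L ||
      abs(sum(eps_fixed^2) - 1) > 1e-12)
    stop("'eps_fixed' must satisfy eps10^2 + eps20^2 = 1")
  structure(
    list(v = v, q = q, deg2 = deg2,
         eps10 = eps_fixed[1L], eps20 = eps_fixed[2L],
         n_free_eps = q + deg2),
    class = "cgf_spec"
  )
}

#' @export
print.cgf_spec <- function(x, ...) {
  cat(sprintf(
    "Convex CGF: order v = %d (q = %d), deg p1 = %d, deg p2 = %d, %d free shape parameter(s)\n",
    x$v, x$q, x$q, x$deg2, x$n_free_eps))
  cat(sprintf("  fixed (eps10, eps20) = (%.6g, %.6g)\n", x$eps10, x$eps20))
  invisible(x)
}

# Assemble full epsilon coefficient vectors from a spec and the free entries
# (indices >= 1 of each polynomial).
full_epsilons <- function(spec, eps_free) {
  eps_free <- as.numeric(eps_free)
  if (length(eps_free) != spec$n_free_eps)
    stop(sprintf("expected %d free epsilon entries, got %d",
                 spec$n_free_eps, length(eps_free)))
  list(
    eps1 = c(spec$eps10, eps_free[seq_len(spec$q)]),
    eps2 = c(spec$eps20, eps_free[spec$q + seq_len(spec$deg2)])
  )
}

#' Convolution coefficients and cumulants of the convex CGF
#'
#' The second derivative of the CGF is `sum_c h_c u^c` with
#' `h_c = sum_{j + j' = c} (eps1_j eps1_j' + eps2_j eps2_j')`, the
#' self-convolution of the two polynomial coefficient vectors.  The cumulant
#' coefficients follow as `lambda_{c+2} = c! * h_c`; `lambda_1 = 0` under
#' identification.
#'
#' @param eps1 Numeric vector `(eps1_0, ..., eps1_q)`.
#' @param eps2 Numeric vector `(eps2_0, ..., eps2_deg2)`.
#' @return List with `h` (length `2q + 1`, coefficients of `K''`) and `lambda`
#'   (length `v = 2q + 2`; entry `r` is `lambda_r`, with `lambda[1] = 0`).
#' @examples
#' h_coefficients(c(0.6, -0.110, 0.005), c(0.8, -0.074))
#' @export
h_coefficients <- function(eps1, eps2) {
  if (length(eps1) < 1L || length(eps2) < 1L || length(eps2) > length(eps1))
    stop("need length(eps1) >= length(eps2) >= 1")
  q <- length(eps1) - 1L
  e2 <- c(eps2, rep(0, length(eps1) - length(eps2)))
  h <- sapply(0:(2L * q), function(cc) {
    j <- max(0L, cc - q):min(q, cc)
    sum(eps1[j + 1L] * eps1[cc - j + 1L]) + sum(e2[j + 1L] * e2[cc - j + 1L])
  })
  lambda <- c(0, factorial(0:(2L * q)) * h)
  names(lambda) <- paste0("lambda", seq_along(lambda))
  list(h = h, lambda = lambda)
}

#' Evaluate the truncated CGF and its derivatives
#'
#' `K^(j)(u) = sum_{r = max(j, 1)}^{v} lambda_r u^(r - j) / (r - j)!`, so
#' `j = 0` gives the CGF itself, `j = 1` its first derivative (the conditional
#' latent mean at shift `u`), `j = 2` the conditional variance, and so on.
#'
#' @param u Numeric vector of evaluation points (`u = alpha' y_tilde`).
#' @param lambda Cumulant coefficient vector as returned by
#'   [h_coefficients()] (entry `r` is `lambda_r`, `lambda[1]` included).
#' @param j Derivative order, `0 <= j <= v`.
#' @return Numeric vector of the same length as `u`.
#' @examples
#' lam <- h_coefficients(c(0.6, 0, 0), c(0.8, 0))$lambda
#' cgf_derivative(2, lam)       # u^2 / 2 = 2: normal shape
#' cgf_derivative(2, lam, 2)    # 1
#' @export
cgf_derivative <- function(u, lambda, j = 0L) {
  v <- length(lambda)
  j <- as.integer(j)
  if (j < 0L || j > v) stop("'j' must be between 0 and v")
  r <- max(j, 1L):v
  coef <- numeric(v - j + 1L)                    # coef[t + 1] multiplies u^t
  coef[r - j + 1L] <- lambda[r] / factorial(r - j)
  horner(u, coef)
}

#' Sum-of-squares form of the CGF second derivative
#'
#' Evaluates `p1(u)^2 + p2(u)^2`, which equals `cgf_derivative(u, lambda, 2)`
#' identically and makes the non-negativity of `K''` explicit.
#'
#' @inheritParams h_coefficients
#' @param u Numeric vector of evaluation points.
#' @return Non-negative numeric vector.
#' @export
sos_second_derivative <- function(u, eps1, eps2) {
  horner(u, eps1)^2 + horner(u, eps2)^2
}

# Horner evaluation of sum_t coef[t + 1] * u^t; vectorized in u.
horner <- function(u, coef) {
  out <- rep(0, length(u))
  for (ct in rev(coef)) out <- out * u + ct
  out
}
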