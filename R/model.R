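#' Construct a random effects GPCM on a finite pattern support
#'
#' Collects everything the closed-form marginal likelihood needs: transformed
#' item-category locations `beta` (length `sum(m)`), item scaling parameters
#' `alpha` (length `k`), the free shape coefficients of the convex CGF, a
#' reference pattern `y0`, and a finite support `B` of score patterns (a subset
#' of the distribution's support containing `y0`; typically the observed
#' pattern set).  The marginal probability of pattern `y` in the subpopulation
#' defined by `B` is `tau_B * exp(beta' x_tilde + K(alpha' y_tilde))`.
#'
#' @param design A [test_design()].
#' @param beta Numeric vector of length `sum(design$m)`.
#' @param alpha Numeric vector of length `design$k`.
#' @param eps_free Free CGF shape coefficients (length `spec$n_free_eps`).
#' @param spec A [cgf_spec()].
#' @param y0 Reference score pattern; must lie in `B`.
#' @param B Integer matrix of support patterns (rows), or `"full"` for the
#'   complete product space (small designs only).
#' @return Object of class `"gpcm_model"`.
#' @examples
#' d <- test_design(c(1))
#' m <- gpcm_model(d, beta = 0, alpha = 1, spec = cgf_spec(2),
#'                 y0 = 0, B = rbind(0, 1))
#' pattern_probabilities(m)
#' @export
gpcm_model <- function(design, beta, alpha, eps_free = numeric(spec$n_free_eps),
                       spec = cgf_spec(), y0, B) {
  new_model(design, beta, scal = alpha, eps_free, spec, y0, B, type = "gpcm")
}

#' Construct a convexity-constrained nominal response model
#'
#' Generalizes [gpcm_model()] by replacing the CGF argument `alpha' y_tilde`
#' with `eta' x_tilde`, where `eta` holds one unrestricted scaling parameter
#' per item category.  The GPCM is the special case `eta[i,s] = alpha[i] * s`,
#' which makes the pair usable in nested likelihood-ratio tests
#' (see [lr_test()]).
#'
#' @inheritParams gpcm_model
#' @param eta Numeric vector of item-category scaling parameters, length
#'   `sum(design$m)`.
#' @return Object of class `"gpcm_model"` with `type = "nominal"`.
#' @export
nominal_model <- function(design, beta, eta, eps_free = numeric(spec$n_free_eps),
                          spec = cgf_spec(), y0, B) {
  new_model(design, beta, scal = eta, eps_free, spec, y0, B, type = "nominal")
}

new_model <- function(design, beta, scal, eps_free, spec, y0, B, type) {
  stopifnot(inherits(design, "test_design"), inherits(spec, "cgf_spec"))
  if (identical(B, "full")) B <- full_support(design)
  B <- check_patterns(B, design, what = "support B")
  if (nrow(B) < 1L) stop("support B is empty")
  y0 <- drop(check_patterns(rbind(y0), design, what = "reference pattern"))
  if (!pattern_string(y0) %in% pattern_string(B))
    stop("reference pattern y0 is not in the support B: model is degenerate")
  beta <- as.numeric(beta)
  if (length(beta) != sum(design$m))
    stop(sprintf("'beta' must have length sum(m) = %d", sum(design$m)))
  scal <- as.numeric(scal)
  len <- if (type == "gpcm") design$k else sum(design$m)
  if (length(scal) != len)
    stop(sprintf("scaling vector must have length %d", len))
  eps <- full_epsilons(spec, eps_free)
  hh <- h_coefficients(eps$eps1, eps$eps2)
  structure(
    list(design = design, beta = beta,
         alpha = if (type == "gpcm") scal, eta = if (type == "nominal") scal,
         eps_free = as.numeric(eps_free), eps1 = eps$eps1, eps2 = eps$eps2,
         lambda = hh$lambda, spec = spec, y0 = y0, B = B, type = type),
    class = "gpcm_model"
  )
}

#' @export
print.gpcm_model <- function(x, ...) {
  cat(sprintf("%s on %d items, support of %d patterns, y0 = %s, v = %d\n",
              if (x$type == "gpcm") "Random effects GPCM"
              else "Convexity-constrained nominal response model",
              x$design$k, nrow(x$B), pattern_string(x$y0), x$spec$v))
  invisible(x)
}

#' Enumerate the full score-pattern space
#'
#' @param design A [test_design()]; the product space has `prod(m + 1)` rows,
#'   so this is meant for small designs.
#' @return Integer matrix of all patterns, one per row, in lexicographic order.
#' @export
full_support <- function(design) {
  if (design$n_patterns > 2e6)
    stop("full pattern space too large to enumerate; use an explicit support")
  g <- do.call(expand.grid, rev(lapply(design$m, function(mi) 0:mi)))
  B <- as.matrix(g[, rev(seq_len(design$k)), drop = FALSE])
  dimnames(B) <- NULL
  B[do.call(order, as.data.frame(B)), , drop = FALSE]
}

#' Linear predictor of the CGF argument
#'
#' The scalar shift `u = alpha' y_tilde` that positions a score pattern on the
#' latent scale relative to the reference pattern.
#'
#' @param alpha Item scaling vector.
#' @param y_tilde Shifted score vector `y - y0`.
#' @return `sum(alpha * y_tilde)`.
#' @export
linear_predictor <- function(alpha, y_tilde) {
  if (length(alpha) != length(y_tilde))
    stop("'alpha' and 'y_tilde' must have equal length")
  sum(alpha * y_tilde)
}

# CGF argument u for each row of Y under the model.
model_u <- function(model, Y) {
  if (model$type == "gpcm") {
    drop(sweep(Y, 2L, model$y0) %*% model$alpha)
  } else {
    drop(dummy_matrix(Y, model$y0, model$design) %*% model$eta)
  }
}

#' Unnormalized log-weight of score patterns
#'
#' `log w(y) = beta' x_tilde + K(u)` with `u = alpha' y_tilde` (GPCM) or
#' `u = eta' x_tilde` (nominal model); the pattern probability is
#' `tau_B * exp(log w(y))`.  The reference pattern always has weight 0.
#'
#' @param model A [gpcm_model()] or [nominal_model()].
#' @param y One pattern (vector) or several (matrix rows); defaults to the
#'   model's support.
#' @return Numeric vector of log-weights.
#' @export
pattern_log_weight <- function(model, y = model$B) {
  Y <- check_patterns(if (is.matrix(y)) y else rbind(y), model$design)
  Xt <- dummy_matrix(Y, model$y0, model$design)
  drop(Xt %*% model$beta) + cgf_derivative(model_u(model, Y), model$lambda)
}

#' Log normalizing constant over the support
#'
#' `log tau_B = -log sum_{y in B} exp(beta' x_tilde + K(u))`, evaluated with a
#' log-sum-exp guard (weights in realistic fits span hundreds of log units).
#'
#' @param model A [gpcm_model()].
#' @return Scalar `log tau_B`.
#' @export
log_normalizer <- function(model) {
  -logsumexp(pattern_log_weight(model))
}

#' Marginal pattern probabilities over the support
#'
#' @param model A [gpcm_model()].
#' @return Named numeric vector (names are pattern strings, in the support's
#'   row order) of probabilities summing to 1 over `B`.
#' @export
pattern_probabilities <- function(model) {
  w <- pattern_log_weight(model)
  p <- exp(w - logsumexp(w))
  names(p) <- pattern_string(model$B)
  p
}

#' Marginal log-likelihood of a pattern-frequency table
#'
#' `l = n log tau_B + sum_y n_y (beta' x_tilde_y + K(u_y))`, the multinomial
#' log-likelihood of the observed pattern counts under the closed-form
#' marginal model.  Every observed pattern must lie in the model's support.
#'
#' @param model A [gpcm_model()] or [nominal_model()].
#' @param data A [pattern_counts()] object.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(model, data) {
  idx <- match_support(model, data)
  w <- pattern_log_weight(model)
  sum(data$counts * w[idx]) - data$n * logsumexp(w)
}

#' Score vector (gradient of the log-likelihood)
#'
#' Analytic gradient in the free coordinates, ordered `(beta, alpha, eps)` for
#' the GPCM and `(beta, eta, eps)` for the nominal model.  The model is an
#' exponential family at fixed scaling, so the `beta` block is the observed
#' minus model-expected dummy-score total; the scaling and shape blocks follow
#' by the chain rule through `K'` and the convolution coefficients `h_c`.
#'
#' @inheritParams log_likelihood
#' @return Named numeric gradient vector.
#' @export
score_vector <- function(model, data) {
  idx <- match_support(model, data)
  cB <- numeric(nrow(model$B))
  cB[idx] <- data$counts
  Xt <- dummy_matrix(model$B, model$y0, model$design)
  Z <- if (model$type == "gpcm") sweep(model$B, 2L, model$y0) else Xt
  u <- drop(Z %*% if (model$type == "gpcm") model$alpha else model$eta)
  w <- drop(Xt %*% model$beta) + cgf_derivative(u, model$lambda)
  resid <- cB - data$n * exp(w - logsumexp(w))
  g <- c(drop(crossprod(Xt, resid)),
         drop(crossprod(Z, resid * cgf_derivative(u, model$lambda, 1L))),
         drop(crossprod(eps_weight_jacobian(u, model), resid)))
  names(g) <- free_parameter_names(model$design, model$spec, model$type)
  g
}

# d w(y) / d eps_free: length(u) x n_free_eps matrix.  K(u) depends on the
# free epsilons through h_c; dh_c/deps1_j = 2 * eps1_{c-j}.
eps_weight_jacobian <- function(u, model) {
  spec <- model$spec
  q <- spec$q
  if (spec$n_free_eps == 0L) return(matrix(0, length(u), 0L))
  cc <- 0:(2L * q)
  G <- outer(u, cc, function(uu, c) uu^(c + 2) / ((c + 1) * (c + 2)))
  J <- matrix(0, length(u), spec$n_free_eps)
  for (j in seq_len(q)) {
    c_rng <- j:min(2L * q, j + q)
    J[, j] <- G[, c_rng + 1L, drop = FALSE] %*% (2 * model$eps1[c_rng - j + 1L])
  }
  for (j in seq_len(spec$deg2)) {
    c_rng <- j:min(2L * q, j + spec$deg2)
    J[, q + j] <- G[, c_rng + 1L, drop = FALSE] %*% (2 * model$eps2[c_rng - j + 1L])
  }
  J
}

free_parameter_names <- function(design, spec, type = "gpcm") {
  c(slot_names(design, "beta"),
    if (type == "gpcm") sprintf("alpha[%d]", seq_len(design$k))
    else slot_names(design, "eta"),
    if (spec$q > 0L) sprintf("eps1[%d]", seq_len(spec$q)),
    if (spec$deg2 > 0L) sprintf("eps2[%d]", seq_len(spec$deg2)))
}

# Row indices of each observed pattern inside the model support; errors if an
# observed pattern lies outside B.
match_support <- function(model, data) {
  idx <- match(pattern_string(data$y), pattern_string(model$B))
  if (anyNA(idx))
    stop("observed pattern(s) outside the model support B: ",
         paste(pattern_string(data$y)[is.na(idx)][1:min(3, sum(is.na(idx)))],
               collapse = ", "))
  idx
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
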