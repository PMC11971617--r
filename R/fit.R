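#' Number of free parameters of a model configuration
#'
#' The GPCM has `sum(m)` category-location parameters, `k` scaling parameters
#' and `q + deg2` free CGF shape coefficients, i.e. `sum(m) + k + v - 2` when
#' both sum-of-squares polynomials have degree `q`, one fewer under the
#' parsimonious `deg2 = q - 1` choice.  The nominal generalization replaces
#' the `k` scalings with `sum(m)` of them.
#'
#' @param design A [test_design()].
#' @param spec A [cgf_spec()].
#' @param type `"gpcm"` or `"nominal"`.
#' @return Integer parameter count.
#' @examples
#' n_free_parameters(test_design(rep(4, 5)), cgf_spec(6))  # 28
#' @export
n_free_parameters <- function(design, spec, type = c("gpcm", "nominal")) {
  type <- match.arg(type)
  sum(design$m) + (if (type == "gpcm") design$k else sum(design$m)) +
    spec$n_free_eps
}

#' Fit the random effects GPCM by marginal maximum likelihood
#'
#' Maximizes the closed-form marginal likelihood of the observed pattern
#' frequencies over `(beta, alpha, eps)` under the identification constraints
#' `lambda1 = 0`, `lambda2 = 1` (fixed `eps10, eps20`), using BFGS with the
#' analytic gradient.  The convexity constraints make the log-likelihood
#' log-concave, so the optimum found is the global maximum, unique up to the
#' latent direction; the remaining sign indeterminacy is resolved by flipping
#' the solution so that `sum(alpha) >= 0`.
#'
#' @param data A [pattern_counts()] object.
#' @param v Even CGF truncation order (see [cgf_spec()]).
#' @param deg2,eps_fixed Passed to [cgf_spec()].
#' @param y0 Reference score pattern; default: the most frequent observed
#'   pattern (ties broken lexicographically).
#' @param support `"observed"` (`B = O`, the default) or `"full"` (the whole
#'   product space; small designs only).
#' @param start Optional full start vector over the free parameters (defaults
#'   to the always-feasible normal start `beta = 0`, `alpha = 1`, `eps = 0`).
#' @param control List of optimizer settings: `maxit` (2000), `reltol`
#'   (1e-12), `grad_tol` (1e-6, infinity norm), `max_restarts` (40).
#' @param vcov If `TRUE` (default), compute the observed-information
#'   covariance via [observed_information()] after fitting.
#' @return Object of class `"gpcm_fit"`: list with `model` (a [gpcm_model()]
#'   at the optimum), `data`, `loglik`, `coef`, `cov`, `se`, `converged`,
#'   `iterations`, `grad_norm` and `np` (free-parameter count).  Methods:
#'   `print`, `coef`, `logLik`, `vcov`, `summary`.
#' @examples
#' \donttest{
#' fit <- gpcm(antisocial_patterns())
#' logLik(fit)
#' }
#' @export
gpcm <- function(data, v = 6L, deg2 = NULL, eps_fixed = c(3 / 5, 4 / 5),
                 y0 = NULL, support = c("observed", "full"), start = NULL,
                 control = list(), vcov = TRUE) {
  spec <- cgf_spec(v, deg2, eps_fixed)
  fit_engine(data, spec, y0, match.arg(support), type = "gpcm",
             start = start, control = control, vcov = vcov)
}

#' Fit the convexity-constrained nominal response model
#'
#' As [gpcm()], but with one unrestricted scaling parameter per item category
#' (`eta[i,s]` in place of `alpha[i] * s`).  The GPCM is nested inside this
#' model, which makes the pair suitable for [lr_test()].
#'
#' @inheritParams gpcm
#' @return Object of class `"gpcm_fit"` whose model has `type = "nominal"`.
#' @export
nominal_gpcm <- function(data, v = 6L, deg2 = NULL, eps_fixed = c(3 / 5, 4 / 5),
                         y0 = NULL, support = c("observed", "full"),
                         start = NULL, control = list(), vcov = TRUE) {
  spec <- cgf_spec(v, deg2, eps_fixed)
  fit_engine(data, spec, y0, match.arg(support), type = "nominal",
             start = start, control = control, vcov = vcov)
}

fit_engine <- function(data, spec, y0, support, type, start, control, vcov) {
  stopifnot(inherits(data, "pattern_counts"))
  if (nrow(data$y) < 2L)
    stop("data contain a single score pattern; the model is saturated/degenerate")
  design <- data$design
  ctrl <- utils::modifyList(
    list(maxit = 2000L, reltol = 1e-12, grad_tol = 1e-6, max_restarts = 40L),
    control)
  if (is.null(y0)) y0 <- data$y[which.max(data$counts), ]
  y0 <- drop(check_patterns(rbind(y0), design, what = "reference pattern"))
  B <- if (support == "observed") data$y else full_support(design)

  # Precomputed sufficient pieces; theta = (beta, scaling, free eps).
  Xt <- dummy_matrix(B, y0, design)
  Z <- if (type == "gpcm") sweep(B, 2L, y0) else Xt
  idx <- match(pattern_string(data$y), pattern_string(B))
  if (anyNA(idx)) stop("observed pattern(s) outside the chosen support")
  cB <- numeric(nrow(B)); cB[idx] <- data$counts
  n <- data$n
  nb <- sum(design$m); ns <- ncol(Z); ne <- spec$n_free_eps
  np <- nb + ns + ne

  unpack <- function(theta)
    list(beta = theta[seq_len(nb)], scal = theta[nb + seq_len(ns)],
         eps = theta[nb + ns + seq_len(ne)])

  weights_of <- function(p) {
    eps <- full_epsilons(spec, p$eps)
    lambda <- h_coefficients(eps$eps1, eps$eps2)$lambda
    u <- drop(Z %*% p$scal)
    list(w = drop(Xt %*% p$beta) + cgf_derivative(u, lambda),
         u = u, lambda = lambda, eps1 = eps$eps1, eps2 = eps$eps2)
  }
  nll <- function(theta) {
    p <- unpack(theta); ww <- weights_of(p)
    -(sum(cB * ww$w) - n * logsumexp(ww$w))
  }
  ngr <- function(theta) {
    p <- unpack(theta); ww <- weights_of(p)
    resid <- cB - n * exp(ww$w - logsumexp(ww$w))
    fake <- list(spec = spec, eps1 = ww$eps1, eps2 = ww$eps2)
    -c(drop(crossprod(Xt, resid)),
       drop(crossprod(Z, resid * cgf_derivative(ww$u, ww$lambda, 1L))),
       drop(crossprod(eps_weight_jacobian(ww$u, fake), resid)))
  }

  theta <- if (is.null(start)) c(numeric(nb), rep(1, ns), numeric(ne))
           else as.numeric(start)
  if (length(theta) != np)
    stop(sprintf("'start' must have length %d", np))
  iterations <- 0L

  # Stage 1: optimize (beta, scaling) with the CGF shape frozen.  With the
  # shape fixed the problem is well-behaved from any start; releasing the
  # shape afterwards avoids stalls in the non-concave eps geometry.
  if (ne > 0L) {
    e0 <- theta[nb + ns + seq_len(ne)]
    s1 <- stats::optim(theta[seq_len(nb + ns)],
                       function(bs) nll(c(bs, e0)),
                       function(bs) ngr(c(bs, e0))[seq_len(nb + ns)],
                       method = "BFGS",
                       control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
    theta[seq_len(nb + ns)] <- s1$par
    iterations <- iterations + s1$counts[["gradient"]]
  }
  for (r in seq_len(ctrl$max_restarts)) {
    opt <- stats::optim(theta, nll, ngr, method = "BFGS",
                        control = list(maxit = ctrl$maxit,
                                       reltol = ctrl$reltol))
    iterations <- iterations + opt$counts[["gradient"]]
    moved <- max(abs(opt$par - theta))
    theta <- opt$par
    grad_norm <- max(abs(ngr(theta)))
    if (grad_norm < ctrl$grad_tol) break
    if (moved == 0 && r > 1L) break   # BFGS stalled at numeric precision
  }

  # Newton polish: BFGS tends to stall short of a tight gradient tolerance;
  # the log-likelihood is concave, so damped Newton steps on a
  # finite-difference Hessian of the analytic gradient finish the job.
  fd_hess <- function(th) {
    H <- matrix(0, np, np)
    for (i in seq_len(np)) {
      h <- 1e-5 * max(1, abs(th[i]))
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      H[, i] <- (ngr(tp) - ngr(tm)) / (2 * h)
    }
    (H + t(H)) / 2
  }
  for (it in seq_len(50L)) {
    if (grad_norm < ctrl$grad_tol) break
    g <- ngr(theta)
    H <- fd_hess(theta)
    scale <- mean(abs(diag(H)))
    f0 <- nll(theta)
    cand <- NULL
    ridge <- 0
    repeat {   # Levenberg damping for (near-)singular or indefinite curvature
      dir <- tryCatch(-solve(H + diag(ridge, np), g), error = function(e) NULL)
      if (!is.null(dir)) {
        stepsize <- 1
        while (stepsize >= 1e-10) {
          trial <- theta + stepsize * dir
          # accept on objective decrease or clear gradient-norm decrease
          # (the latter matters on near-flat ridges of the eps geometry)
          if (nll(trial) < f0 - 1e-12 * abs(f0) ||
              max(abs(ngr(trial))) < 0.7 * grad_norm) { cand <- trial; break }
          stepsize <- stepsize / 2
        }
        if (!is.null(cand)) break
      }
      ridge <- if (ridge == 0) 1e-8 * max(scale, 1) else ridge * 100
      if (ridge > 1e6 * max(scale, 1)) break
    }
    if (is.null(cand)) break
    theta <- cand
    iterations <- iterations + 1L
    grad_norm <- max(abs(ngr(theta)))
  }
  converged <- grad_norm < ctrl$grad_tol

  # Sign convention: flip the latent direction so the scalings sum >= 0.
  p <- unpack(theta)
  if (sum(p$scal) < 0) {
    p$scal <- -p$scal
    sgn <- c(if (spec$q > 0L) (-1)^seq_len(spec$q),
             if (spec$deg2 > 0L) (-1)^seq_len(spec$deg2))
    p$eps <- p$eps * sgn
    theta <- c(p$beta, p$scal, p$eps)
  }

  model <- new_model(design, p$beta, p$scal, p$eps, spec, y0, B, type)
  names(theta) <- free_parameter_names(design, spec, type)
  fit <- structure(
    list(model = model, data = data, loglik = -nll(theta), coef = theta,
         cov = NULL, se = NULL, converged = converged,
         iterations = iterations, grad_norm = grad_norm, np = np),
    class = "gpcm_fit")
  if (vcov) {
    fit$cov <- observed_information(model, data)
    fit$se <- sqrt(pmax(diag(fit$cov), 0))
  }
  fit
}

#' Observed-information covariance matrix
#'
#' Inverse of the negative Hessian of the marginal log-likelihood over the
#' free parameters, the Hessian being obtained by central finite differences
#' of the analytic gradient (relative step 1e-5).  Computed afresh at the
#' reported optimum rather than taken from the optimizer's internal BFGS
#' approximation, which accumulates numerical error.
#'
#' @param model A [gpcm_model()] at (or near) the optimum.
#' @param data The [pattern_counts()] that were fitted.
#' @param step Relative finite-difference step.
#' @return Symmetric covariance matrix over the free parameters.
#' @export
observed_information <- function(model, data, step = 1e-5) {
  theta <- c(model$beta, if (model$type == "gpcm") model$alpha else model$eta,
             model$eps_free)
  p <- length(theta)
  grad_at <- function(th) {
    m2 <- new_model(model$design, th[seq_along(model$beta)],
                    th[length(model$beta) + seq_len(p - length(model$beta) -
                                                      model$spec$n_free_eps)],
                    th[p - model$spec$n_free_eps + seq_len(model$spec$n_free_eps)],
                    model$spec, model$y0, model$B, model$type)
    score_vector(m2, data)
  }
  H <- matrix(0, p, p)
  for (i in seq_len(p)) {
    h <- step * max(1, abs(theta[i]))
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    H[, i] <- (grad_at(tp) - grad_at(tm)) / (2 * h)
  }
  H <- (H + t(H)) / 2
  cov <- tryCatch(solve(-H), error = function(e) {
    ev <- eigen(-H, symmetric = TRUE)
    worst <- ev$vectors[, which.min(abs(ev$values))]
    nm <- free_parameter_names(model$design, model$spec, model$type)
    stop("observed information is singular; null direction loads mainly on ",
         nm[which.max(abs(worst))])
  })
  dimnames(cov) <- rep(list(free_parameter_names(model$design, model$spec,
                                                 model$type)), 2L)
  cov
}

#' @export
print.gpcm_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("log-likelihood %.3f on %d free parameters (n = %d)\n",
              x$loglik, x$np, x$data$n))
  cat(sprintf("converged: %s (|grad|_inf = %.2e, %d gradient evaluations)\n",
              x$converged, x$grad_norm, x$iterations))
  invisible(x)
}

#' @export
coef.gpcm_fit <- function(object, ...) object$coef

#' @export
logLik.gpcm_fit <- function(object, ...) {
  structure(object$loglik, df = object$np, nobs = object$data$n,
            class = "logLik")
}

#' @export
vcov.gpcm_fit <- function(object, ...) {
  if (is.null(object$cov))
    object$cov <- observed_information(object$model, object$data)
  object$cov
}

#' @export
summary.gpcm_fit <- function(object, ...) {
  out <- data.frame(estimate = object$coef,
                    se = if (is.null(object$se)) NA_real_ else object$se)
  rownames(out) <- names(object$coef)
  out
}
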