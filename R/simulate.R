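#' Latent trait densities for data generation
#'
#' The marginal model is latent-distribution-free, so the generator supports
#' several latent shapes for misspecification experiments: normal, a
#' two-component normal mixture, and a shifted gamma (skewed).  Each object
#' carries a sampler `r(n)` and a density `d(x)` (the latter used by
#' numerical-integration cross-checks).
#'
#' @param mean,sd Mean and standard deviation (normal).
#' @return Object of class `"latent_dist"`.
#' @export
latent_normal <- function(mean = 0, sd = 1) {
  structure(list(name = "normal",
                 r = function(n) stats::rnorm(n, mean, sd),
                 d = function(x) stats::dnorm(x, mean, sd)),
            class = "latent_dist")
}

#' @rdname latent_normal
#' @param means,sds,weights Component parameters (mixture); `weights` sum to 1.
#' @export
latent_mixture <- function(means, sds, weights) {
  stopifnot(length(means) == length(sds), length(means) == length(weights),
            abs(sum(weights) - 1) < 1e-10)
  structure(list(
    name = "mixture",
    r = function(n) {
      g <- sample.int(length(weights), n, replace = TRUE, prob = weights)
      stats::rnorm(n, means[g], sds[g])
    },
    d = function(x) {
      rowSums(sapply(seq_along(weights), function(g)
        weights[g] * stats::dnorm(x, means[g], sds[g])))
    }), class = "latent_dist")
}

#' @rdname latent_normal
#' @param shape,rate,shift Gamma shape and rate, plus a location shift
#'   (shifted gamma, for positively skewed latent traits).
#' @export
latent_sgamma <- function(shape = 4, rate = 2, shift = -2) {
  structure(list(name = "sgamma",
                 r = function(n) shift + stats::rgamma(n, shape, rate),
                 d = function(x) stats::dgamma(x - shift, shape, rate)),
            class = "latent_dist")
}

#' Generative GPCM for response simulation
#'
#' The conditional (fixed-effects) GPCM specified directly through its item
#' scalings `alpha` and per-category thresholds `delta[[i]]` (length `m[i]`),
#' coupled with a latent density for the person parameters.
#'
#' @param design A [test_design()].
#' @param alpha Item scaling vector, length `k`.
#' @param delta List of `k` numeric threshold vectors, `delta[[i]]` of length
#'   `m[i]`; `delta[i,a]` is the latent value where categories `a - 1` and `a`
#'   of item `i` are equiprobable.
#' @param theta_dist A latent density ([latent_normal()] and friends).
#' @return Object of class `"generative_gpcm"`.
#' @export
generative_gpcm <- function(design, alpha, delta, theta_dist = latent_normal()) {
  stopifnot(inherits(design, "test_design"),
            length(alpha) == design$k, length(delta) == design$k,
            all(lengths(delta) == design$m),
            inherits(theta_dist, "latent_dist"))
  structure(list(design = design, alpha = as.numeric(alpha),
                 delta = lapply(delta, as.numeric), theta_dist = theta_dist),
            class = "generative_gpcm")
}

#' Conditional category probabilities of one item
#'
#' `P(Y_i = s | theta)` is proportional to
#' `exp(alpha_i * (s * theta - sum_{a <= s} delta[i,a]))` (empty sum for
#' `s = 0`), the adjacent-category logit form: at `theta = delta[i,a]`
#' categories `a - 1` and `a` are equiprobable, and `alpha_i = 0` gives a
#' uniform distribution over categories.
#'
#' @param model A [generative_gpcm()], or a fitted [gpcm()] object (whose
#'   `alpha` and back-transformed `delta` are then used).
#' @param theta Numeric vector of latent values.
#' @param item Item index.
#' @return Matrix of probabilities, `length(theta)` rows and `m[i] + 1`
#'   columns; rows sum to 1.
#' @export
category_probs <- function(model, theta, item) {
  gm <- as_generative(model)
  mi <- gm$design$m[item]
  cumdelta <- c(0, cumsum(gm$delta[[item]]))   # sum_{a<=s} delta_ia, s = 0..mi
  lw <- outer(theta, 0:mi) * gm$alpha[item] -
    rep(gm$alpha[item] * cumdelta, each = length(theta))
  lw <- lw - apply(lw, 1L, max)
  p <- exp(lw)
  p / rowSums(p)
}

#' Simulate person-by-item responses under a latent density
#'
#' Draws a latent value per person from the generative model's latent density,
#' then item scores independently from the conditional category probabilities,
#' in fixed person-major order from a single seeded stream.
#'
#' @param model A [generative_gpcm()].
#' @param n Number of persons, `n >= 1`.
#' @param seed Optional integer seed.
#' @return Integer matrix of scores, `n` rows and `k` columns.
#' @export
simulate_responses <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "generative_gpcm"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  theta <- model$theta_dist$r(n)
  Y <- matrix(0L, n, model$design$k)
  for (i in seq_len(model$design$k)) {
    P <- category_probs(model, theta, i)
    cum <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
    Y[, i] <- as.integer(rowSums(stats::runif(n) > cum))
  }
  Y
}

#' Sample pattern counts from a fitted discrete model
#'
#' Multinomial draw of `n` score patterns with the fitted pattern
#' probabilities over the model's finite support.
#'
#' @param model A [gpcm_model()] or [gpcm()] fit.
#' @param n Sample size.
#' @param seed Optional integer seed.
#' @return A [pattern_counts()] holding the sampled patterns (only patterns
#'   with positive sampled counts appear).
#' @export
simulate_patterns <- function(model, n, seed = NULL) {
  model <- as_gpcm_model(model)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  p <- pattern_probabilities(model)
  cnt <- drop(stats::rmultinom(1L, n, p))
  keep <- cnt > 0L
  pattern_counts(model$B[keep, , drop = FALSE], cnt[keep],
                 design = model$design)
}

#' Conditional category-probability curves
#'
#' Evaluates every item's conditional category probabilities over a grid of
#' latent values, for plots of the fitted item response functions (adjacent
#' curves cross at the thresholds `delta[i,a]`).
#'
#' @param model A [generative_gpcm()] or fitted [gpcm()] object.
#' @param theta Numeric grid of latent values.
#' @return Long data frame with columns `item`, `category`, `theta`, `prob`.
#' @export
category_curves <- function(model, theta = seq(-1, 7, length.out = 201)) {
  gm <- as_generative(model)
  do.call(rbind, lapply(seq_len(gm$design$k), function(i) {
    P <- category_probs(gm, theta, i)
    data.frame(item = i,
               category = rep(0:gm$design$m[i], each = length(theta)),
               theta = theta, prob = as.vector(P))
  }))
}

# Coerce a fitted model to the (alpha, delta) generative form; the latent
# density slot is a placeholder (conditional probabilities do not use it).
as_generative <- function(x) {
  if (inherits(x, "generative_gpcm")) return(x)
  model <- as_gpcm_model(x)
  if (model$type != "gpcm")
    stop("category curves need the GPCM scaling structure")
  off <- c(0L, cumsum(model$design$m))
  delta <- lapply(seq_len(model$design$k), function(i) {
    b <- c(0, model$beta[off[i] + seq_len(model$design$m[i])])
    -diff(b) / model$alpha[i]
  })
  generative_gpcm(model$design, model$alpha, delta)
}
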