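# Shared fixtures built in code, plus a per-run cache for the expensive
# worked-example fit so every file can reuse it.

the_cache <- new.env(parent = emptyenv())

example_fit <- function() {
  if (is.null(the_cache$fit))
    the_cache$fit <- gpcm(antisocial_patterns(), y0 = rep(0L, 5L))
  the_cache$fit
}

# Small three-item trichotomous test: full pattern coverage at moderate n,
# sub-fits comfortably overdetermined.
trich_design <- function() test_design(c(2L, 2L, 2L))

trich_generator <- function(theta_dist = latent_normal()) {
  generative_gpcm(trich_design(), alpha = c(1, 1.2, 0.9),
                  delta = list(c(-0.5, 0.7), c(0, 1), c(-0.8, 0.5)),
                  theta_dist = theta_dist)
}

trich_data <- function(n = 3000, seed = 5) {
  as_pattern_counts(simulate_responses(trich_generator(), n, seed = seed),
                    trich_design())
}

# One dichotomous item, support {0, 1}: the hand-computable two-pattern model.
toy_model <- function(beta = 0, alpha = 1) {
  gpcm_model(test_design(1L), beta = beta, alpha = alpha, spec = cgf_spec(2L),
             y0 = 0L, B = rbind(0L, 1L))
}

fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# Epsilon coefficients printed for the worked example (used as a realistic
# fixed shape in unit tests).
example_eps1 <- c(0.6, -0.110, 0.005)
example_eps2 <- c(0.8, -0.074)
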