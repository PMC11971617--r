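test_that("free-parameter counting follows the identification rules", {
  des5 <- test_design(rep(4, 5))
  expect_equal(n_free_parameters(des5, cgf_spec(6)), 28L)          # 20 + 5 + 3
  expect_equal(n_free_parameters(des5, cgf_spec(6, deg2 = 2)), 29L) # sum(m)+k+v-2
  expect_equal(n_free_parameters(des5, cgf_spec(2)), 25L)           # sum(m)+k
  des3 <- trich_design()
  expect_equal(n_free_parameters(des3, cgf_spec(4)), 10L)
  expect_equal(n_free_parameters(des3, cgf_spec(4), type = "nominal"), 13L)
})

test_that("fitting recovers generating parameters on simulated data", {
  # truth: a converged fit on skewed-latent data (so the CGF shape is
  # interior and identified), then resample from the fitted discrete model
  # and refit with the same reference and spec
  dat <- as_pattern_counts(
    simulate_responses(trich_generator(latent_sgamma(4, 2, -2)), 3000,
                       seed = 5), trich_design())
  truth <- gpcm(dat, v = 4, deg2 = 1, y0 = c(0L, 0L, 0L), vcov = FALSE)
  expect_true(truth$converged)
  sim <- simulate_patterns(truth$model, 20000, seed = 61)
  refit <- gpcm(sim, v = 4, deg2 = 1, y0 = c(0L, 0L, 0L))
  expect_true(refit$converged)
  # judge recovery on the identified quantities: item parameters and the
  # latent cumulant coefficients (the raw eps are auxiliary and can swap
  # between the two roots of the lambda -> eps map)
  z_item <- abs(coef(refit)[1:9] - coef(truth)[1:9]) / refit$se[1:9]
  expect_true(all(z_item < 3))
  lc_t <- latent_cumulants(truth)
  lc_r <- latent_cumulants(refit)
  z_cum <- abs(lc_r$estimate[2:3] - lc_t$estimate[2:3]) / lc_r$se[2:3]
  expect_true(all(z_cum < 3))
})

test_that("random restarts reach the same global maximum", {
  d <- antisocial_patterns()
  base <- example_fit()
  set.seed(407)
  lls <- replicate(20, {
    st <- c(rnorm(20, 0, 2), runif(5, 0.2, 2), rnorm(3, 0, 0.1))
    gpcm(d, y0 = rep(0L, 5L), start = st, vcov = FALSE)$loglik
  })
  expect_lt(max(abs(lls - base$loglik)), 1e-4)
})

test_that("refitting from the optimum does not improve the likelihood", {
  fit <- example_fit()
  again <- gpcm(fit$data, y0 = rep(0L, 5L), start = coef(fit), vcov = FALSE)
  expect_lt(again$loglik - fit$loglik, 1e-6)
  expect_lt(fit$grad_norm, 1e-6)
})

test_that("observed information matches independent curvature oracles", {
  # (a) value-based FD Hessian of the log-likelihood (no analytic gradient)
  dat <- trich_data(1500, seed = 13)
  fit <- gpcm(dat, v = 2, y0 = c(0L, 0L, 0L))
  th0 <- coef(fit)
  p <- length(th0)
  build <- function(x) gpcm_model(trich_design(), x[1:6], x[7:9], numeric(0),
                                  cgf_spec(2), c(0L, 0L, 0L), fit$model$B)
  H <- matrix(0, p, p)
  hs <- 1e-4 * pmax(1, abs(th0))
  for (i in 1:p) for (j in i:p) {
    ei <- replace(rep(0, p), i, hs[i]); ej <- replace(rep(0, p), j, hs[j])
    H[i, j] <- H[j, i] <-
      (log_likelihood(build(th0 + ei + ej), dat) -
         log_likelihood(build(th0 + ei - ej), dat) -
         log_likelihood(build(th0 - ei + ej), dat) +
         log_likelihood(build(th0 - ei - ej), dat)) / (4 * hs[i] * hs[j])
  }
  V <- vcov(fit)
  expect_equal(sqrt(diag(V)), sqrt(diag(solve(-H))),
               tolerance = 0.02, ignore_attr = TRUE)
  expect_equal(V, t(V), tolerance = 1e-8)
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > 0))

  # (b) closed-form binomial curvature on the two-pattern toy: the beta-beta
  # Hessian entry is -n p (1 - p) at any parameter point
  toy_dat <- pattern_counts(rbind(0L, 1L), c(3L, 7L), test_design(1L))
  m <- toy_model(0.3, 1)
  p1 <- unname(pattern_probabilities(m)[2])
  fd_bb <- (score_vector(toy_model(0.3 + 1e-6, 1), toy_dat)[1] -
              score_vector(toy_model(0.3 - 1e-6, 1), toy_dat)[1]) / 2e-6
  expect_equal(unname(fd_bb), -10 * p1 * (1 - p1), tolerance = 1e-6)
})

test_that("threshold back-transform inverts the beta map exactly", {
  fit <- gpcm(trich_data(1200, seed = 17), v = 2, y0 = c(0L, 0L, 0L))
  ip <- item_parameters(fit)
  for (i in 1:3) {
    rows <- ip[ip$item == i, ]
    # beta_is = -alpha_i * sum_{a<=s} delta_ia reproduces beta exactly
    expect_equal(rows$beta, -fit$model$alpha[i] * cumsum(rows$delta),
                 tolerance = 1e-12)
    # omega_i1 = delta_i1 always
    expect_equal(rows$omega[1], rows$delta[1])
    expect_equal(rows$se_omega[1], rows$se_delta[1], tolerance = 1e-12)
  }
  expect_true(all(ip$se_delta > 0) && all(ip$se_omega > 0))

  broken <- fit
  broken$model$alpha[2] <- 0
  expect_error(item_parameters(broken), "alpha")
})

test_that("cumulant estimates follow the h-coefficient map", {
  fit2 <- gpcm(trich_data(1200, seed = 17), v = 2, y0 = c(0L, 0L, 0L))
  lc2 <- latent_cumulants(fit2)
  expect_equal(lc2$estimate, 1)                 # lambda2 only, fixed at 1
  expect_equal(lc2$se, 0)

  fit4 <- gpcm(trich_data(2500, seed = 19), v = 4, deg2 = 1,
               y0 = c(0L, 0L, 0L))
  lc4 <- latent_cumulants(fit4)
  expect_equal(lc4$order, 2:4)
  expect_equal(lc4$label, c("kappa2", "kappa3", "lambda4"))
  expect_equal(lc4$estimate[1], 1)
  expect_equal(lc4$se[1], 0)
  e1 <- fit4$model$eps1; e2 <- fit4$model$eps2
  expect_equal(lc4$estimate[2], 2 * (e1[1] * e1[2] + e2[1] * e2[2]))
  expect_true(all(lc4$se[2:3] > 0))
})

test_that("sign convention and degenerate-data guards hold", {
  dat <- trich_data(1000, seed = 23)
  # start from a flipped configuration; the fit must come back normalized
  st <- c(rnorm(6), rep(-1, 3), numeric(1))
  fit <- gpcm(dat, v = 4, deg2 = 0, y0 = c(0L, 0L, 0L), start = st,
              vcov = FALSE)
  expect_gte(sum(fit$model$alpha), 0)
  ref <- gpcm(dat, v = 4, deg2 = 0, y0 = c(0L, 0L, 0L), vcov = FALSE)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)

  single <- pattern_counts(rbind(c(0L, 0L, 0L)), 10L, trich_design())
  expect_error(gpcm(single), "single")
})
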