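test_that("linear predictor and pattern log-weights match hand expansion", {
  expect_equal(linear_predictor(c(1.397, 1.302, 1.105, 1.267, 1.037),
                                c(1, 0, 0, 0, 0)), 1.397)
  expect_equal(linear_predictor(c(1, 1), c(-2, 3)), 1)
  expect_equal(linear_predictor(rep(1.2, 3), rep(0, 3)), 0)
  expect_error(linear_predictor(c(1, 2), c(1, 2, 3)), "length")

  m <- toy_model()
  expect_equal(pattern_log_weight(m, 0L), 0)       # reference pattern
  expect_equal(pattern_log_weight(m, 1L), 0.5)     # 0 + K(1) = 1/2
})

test_that("normalizer and probabilities agree with hand-computed toy values", {
  single <- gpcm_model(test_design(1L), beta = 0.7, alpha = 1.2,
                       spec = cgf_spec(2), y0 = 1L, B = rbind(1L))
  expect_equal(log_normalizer(single), 0)
  expect_equal(unname(pattern_probabilities(single)), 1)

  m <- toy_model()
  expect_equal(log_normalizer(m), -log(1 + exp(0.5)))
  p <- pattern_probabilities(m)
  expect_equal(unname(p), c(1, exp(0.5)) / (1 + exp(0.5)))
  expect_equal(unname(p), c(0.37754067, 0.62245933), tolerance = 1e-7)

  expect_error(gpcm_model(test_design(1L), 0, 1, spec = cgf_spec(2),
                          y0 = 0L, B = rbind(1L)), "degenerate")
})

test_that("probabilities sum to one across random designs and parameters", {
  set.seed(403)
  designs <- list(c(1, 1), c(2, 1), c(3, 2, 2))
  for (mm in designs) {
    des <- test_design(mm)
    for (rep in 1:5) {
      spec <- cgf_spec(sample(c(2, 4), 1))
      mod <- gpcm_model(des, beta = rnorm(sum(mm)), alpha = runif(length(mm), 0.3, 1.5),
                        eps_free = rnorm(spec$n_free_eps, 0, 0.2), spec = spec,
                        y0 = rep(0L, length(mm)), B = "full")
      expect_equal(sum(pattern_probabilities(mod)), 1, tolerance = 1e-12)
    }
  }
})

test_that("log-likelihood matches the multinomial form on hand-checkable cases", {
  m <- toy_model()
  dat <- pattern_counts(rbind(0L, 1L), c(1L, 1L), test_design(1L))
  expect_equal(log_likelihood(m, dat),
               log(1 / (1 + exp(0.5))) + log(exp(0.5) / (1 + exp(0.5))))

  # single-cell support: probability one regardless of parameters
  single <- gpcm_model(test_design(1L), beta = -2, alpha = 3,
                       spec = cgf_spec(2), y0 = 0L, B = rbind(0L))
  dat1 <- pattern_counts(rbind(0L), 5L, test_design(1L))
  expect_equal(log_likelihood(single, dat1), 0)

  expect_error(log_likelihood(m, pattern_counts(rbind(2L), 1L, test_design(2))))
})

test_that("analytic score matches central finite differences", {
  # toy two-pattern model over (beta, alpha)
  dat <- pattern_counts(rbind(0L, 1L), c(3L, 7L), test_design(1L))
  set.seed(404)
  for (rep in 1:5) {
    th <- rnorm(2)
    g <- score_vector(toy_model(th[1], th[2]), dat)
    fd <- fd_gradient(function(x)
      log_likelihood(toy_model(x[1], x[2]), dat), th)
    expect_equal(unname(g), fd, tolerance = 1e-7)
  }

  # richer design, both deg2 choices, random interior points
  des <- trich_design()
  dat3 <- trich_data(800, seed = 9)
  for (dg in c(0L, 1L)) {
    spec <- cgf_spec(4, dg)
    npar <- n_free_parameters(des, spec)
    for (rep in 1:3) {
      th <- c(rnorm(6, 0, 0.7), runif(3, 0.5, 1.5), rnorm(spec$n_free_eps, 0, 0.2))
      build <- function(x) gpcm_model(des, x[1:6], x[7:9],
                                      x[9 + seq_len(spec$n_free_eps)],
                                      spec, c(0L, 0L, 0L), dat3$y)
      g <- score_vector(build(th), dat3)
      fd <- fd_gradient(function(x) log_likelihood(build(x), dat3), th)
      expect_lt(max(abs(g - fd)) / max(1, max(abs(fd))), 1e-7)
      expect_equal(length(g), npar)
    }
  }
})

test_that("beta score equals observed minus expected dummy totals", {
  des <- trich_design()
  dat <- trich_data(500, seed = 21)
  spec <- cgf_spec(4)
  mod <- gpcm_model(des, rnorm(6), c(1, 1, 1), rnorm(spec$n_free_eps, 0, 0.1),
                    spec, c(0L, 0L, 0L), dat$y)
  g <- score_vector(mod, dat)
  p <- pattern_probabilities(mod)
  Xt <- t(vapply(seq_len(nrow(dat$y)), function(r)
    dummy_code(dat$y[r, ], c(0L, 0L, 0L), des)$x_tilde, numeric(6)))
  n_tilde <- colSums(dat$counts * Xt)
  XB <- t(vapply(seq_len(nrow(mod$B)), function(r)
    dummy_code(mod$B[r, ], c(0L, 0L, 0L), des)$x_tilde, numeric(6)))
  expected <- dat$n * colSums(unname(p) * XB)
  expect_equal(unname(g[1:6]), n_tilde - expected, tolerance = 1e-10)
})

test_that("nominal model nests the GPCM and has a correct gradient", {
  des <- test_design(c(2, 1))
  dat <- as_pattern_counts(rbind(c(0, 0), c(1, 0), c(2, 1), c(1, 1), c(0, 1),
                                 c(2, 0), c(0, 0), c(1, 1)), des)
  spec <- cgf_spec(4)
  alpha <- c(0.8, 1.3)
  eta <- c(0.8 * 1, 0.8 * 2, 1.3 * 1)          # eta[i,s] = alpha_i * s
  beta <- c(-0.5, -1.2, -0.7)
  mg <- gpcm_model(des, beta, alpha, c(-0.1), spec, c(0L, 0L), dat$y)
  mn <- nominal_model(des, beta, eta, c(-0.1), spec, c(0L, 0L), dat$y)
  expect_equal(log_likelihood(mn, dat), log_likelihood(mg, dat))

  # nominal toy: weight of y = 1 is K(eta) = eta^2/2 under the normal shape
  nt <- nominal_model(test_design(1L), beta = 0, eta = 0.5,
                      spec = cgf_spec(2), y0 = 0L, B = rbind(0L, 1L))
  expect_equal(pattern_log_weight(nt, 1L), 0.125)

  set.seed(405)
  th <- c(rnorm(3), runif(3, 0.3, 1.5), -0.05)
  build <- function(x) nominal_model(des, x[1:3], x[4:6], x[7], spec,
                                     c(0L, 0L), dat$y)
  g <- score_vector(build(th), dat)
  fd <- fd_gradient(function(x) log_likelihood(build(x), dat), th)
  expect_lt(max(abs(g - fd)) / max(1, max(abs(fd))), 1e-7)
})

test_that("log-likelihood is concave in the canonical (beta, lambda) block", {
  # at fixed alpha the model is exponential-family in (beta, lambda); check
  # concavity along random line segments with an independent mini-evaluator
  des <- trich_design()
  dat <- trich_data(600, seed = 33)
  alpha <- c(1, 1.2, 0.9)
  y0 <- c(0L, 0L, 0L)
  Xt <- t(vapply(seq_len(nrow(dat$y)), function(r)
    dummy_code(dat$y[r, ], y0, des)$x_tilde, numeric(6)))
  u <- drop(sweep(dat$y, 2, y0) %*% alpha)
  ll <- function(beta, lam) {
    w <- drop(Xt %*% beta) + cgf_derivative(u, lam)
    sum(dat$counts * w) - dat$n * (max(w) + log(sum(exp(w - max(w)))))
  }
  set.seed(406)
  for (rep in 1:20) {
    b0 <- rnorm(6); l0 <- c(0, 1, rnorm(2, 0, 0.3))
    db <- rnorm(6); dl <- c(0, 0, rnorm(2, 0, 0.3))
    v <- sapply(seq(-1, 1, length.out = 9), function(t)
      ll(b0 + t * db, l0 + t * dl))
    expect_true(all(diff(diff(v)) <= 1e-7 * max(1, abs(v[5]))))
  }
})
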