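test_that("log marginal likelihood matches the dense oracle", {
  # single observation at 0 with unit total variance: standard normal density
  o1 <- obs_set(0.5, 0)
  expect_equal(log_marginal_likelihood(o1, kernel_hyp(1, sqrt(0.5),
                                                      sqrt(0.5))),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  set.seed(4)
  t <- runif(5, 0, 3)
  y <- rnorm(5)
  obs <- obs_set(t, y)
  expect_equal(log_marginal_likelihood(obs, kernel_hyp(0.7, 1.1, 0.3)),
               oracle_lml(t, y, 0.7, 1.1, 0.3), tolerance = 1e-8)

  # invariance under joint permutation of rows
  perm <- sample(5)
  expect_equal(log_marginal_likelihood(obs_set(t[perm], y[perm]),
                                       kernel_hyp(0.7, 1.1, 0.3)),
               log_marginal_likelihood(obs, kernel_hyp(0.7, 1.1, 0.3)),
               tolerance = 1e-10)
})

test_that("analytic objective gradient matches finite differences", {
  set.seed(5)
  t <- sort(runif(25, 0, 4))
  y <- draw_gp_data(t, 0.6, 1, 0.2, seed = 6)
  spec <- compose_effect_kernel(rbf_effect("time", "time"))
  X <- matrix(t, ncol = 1, dimnames = list(NULL, "time"))
  d2 <- gptrace:::spec_sq_dists(spec, X)
  yc <- y - median(y)
  p <- log(c(0.4, 0.8, 0.3))
  an <- gptrace:::dense_nll(p, spec, d2, yc)
  num <- vapply(1:3, function(i) {
    h <- 1e-6; pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    (gptrace:::dense_nll(pp, spec, d2, yc)$value -
       gptrace:::dense_nll(pm, spec, d2, yc)$value) / (2 * h)
  }, numeric(1))
  expect_equal(an$grad, num, tolerance = 1e-5)
})

test_that("exact fit posterior matches the closed-form dense oracle", {
  set.seed(7)
  t <- sort(runif(30, 0, 6))
  y <- draw_gp_data(t, 0.8, 1, 0.2, seed = 8)
  obs <- obs_set(t, y)
  m <- fit_gp(obs, config = quick_config(n_inducing = 30), seed = 1)
  expect_false(m$sparse)   # M = N fits the exact GP
  g <- seq(0.2, 5.8, length.out = 40)
  p <- predict(m, g)
  h <- m$hyp$effects$time
  orc <- oracle_posterior(t, y - m$center, g, h$lengthscale, h$signal_sd,
                          m$hyp$noise_sd)
  expect_equal(p$mean, orc$mean + m$center, tolerance = 1e-3)
  expect_equal(p$latent_var, orc$var, tolerance = 1e-3)
})

test_that("sparse fit with M = N - 1 reproduces the dense posterior", {
  set.seed(9)
  t <- sort(runif(40, 0, 8))
  y <- draw_gp_data(t, 1, 1, 0.2, seed = 10)
  obs <- obs_set(t, y)
  md <- fit_gp(obs, config = quick_config(n_inducing = 40, n_iter = 40),
               seed = 2)
  ms <- fit_gp(obs, config = quick_config(n_inducing = 39, n_iter = 40),
               seed = 2)
  expect_true(ms$sparse)
  g <- seq(0.5, 7.5, length.out = 30)
  pd <- predict(md, g)
  ps <- predict(ms, g)
  expect_equal(ps$mean, pd$mean, tolerance = 1e-3)
  expect_equal(ps$latent_var, pd$latent_var, tolerance = 1e-3)
})

test_that("restart policy returns the best objective and fit errors are clear", {
  set.seed(11)
  t <- sort(runif(25, 0, 4))
  obs <- obs_set(t, draw_gp_data(t, 0.5, 1, 0.3, seed = 12))
  cfgs <- lapply(1:4, function(r) fit_config(n_inducing = 50, n_iter = 15,
                                             n_restarts = 1))
  single <- vapply(1:4, function(r) {
    set.seed(100 + r)
    fit_gp(obs, config = cfgs[[r]], seed = 100 + r)$objective
  }, numeric(1))
  multi <- fit_gp(obs, config = fit_config(n_inducing = 50, n_iter = 15,
                                           n_restarts = 4), seed = 100)
  # the multi-restart objective is at least as good as any comparable start
  expect_gte(multi$objective, max(single) - 1e-6)

  expect_error(fit_gp(obs_set(1, 2)), "at least 2")
})

test_that("posterior invariants hold: variance ordering and conditioning", {
  set.seed(13)
  t <- sort(runif(35, 0, 6))
  obs <- obs_set(t, draw_gp_data(t, 0.7, 1, 0.25, seed = 14))
  m <- fit_gp(obs, config = quick_config(), seed = 3)
  g <- seq(-1, 7, length.out = 60)
  p <- predict(m, g)
  expect_true(all(p$latent_var >= 0))
  expect_true(all(p$noisy_var >= p$latent_var))
  expect_equal(p$noisy_var - p$latent_var,
               rep(m$hyp$noise_sd^2, length(g)), tolerance = 1e-12)

  # far from all data the prior is recovered
  pf <- predict(m, 1e4)
  expect_equal(pf$latent_var, m$hyp$effects$time$signal_sd^2,
               tolerance = 1e-6)
  expect_equal(pf$mean, m$center, tolerance = 1e-6)

  # near-interpolation when the noise is tiny
  tt <- seq(0, 2, length.out = 9)
  yy <- sin(tt)
  K <- outer(tt, tt, function(a, b) exp(-(a - b)^2 / 2))
  # fixed-hyperparameter posterior via the package kernel path
  mi <- structure(list(
    kernel = compose_effect_kernel(rbf_effect("time", "time")),
    hyp = list(effects = list(time = list(lengthscale = 1, signal_sd = 1)),
               noise_sd = 1e-6),
    X = matrix(tt, ncol = 1, dimnames = list(NULL, "time")),
    y = yy, center = 0, Z = NULL, sparse = FALSE, objective = NA,
    n_obs = 9, warp = NULL, encoding = NULL, restart = 1L,
    config = fit_config()), class = "fitted_gp")
  mi$cache <- gptrace:::build_gp_cache(mi)
  expect_equal(predict(mi, tt)$mean, yy, tolerance = 1e-4)

  # under fixed hyperparameters, adding an observation never increases
  # the latent posterior variance anywhere (GP conditioning)
  mi2 <- mi
  mi2$X <- rbind(mi$X, matrix(2.5, dimnames = list(NULL, "time")))
  mi2$y <- c(yy, sin(2.5))
  mi2$n_obs <- 10
  mi2$cache <- gptrace:::build_gp_cache(mi2)
  gg <- seq(-0.5, 3, length.out = 50)
  expect_true(all(predict(mi2, gg)$latent_var <=
                    predict(mi, gg)$latent_var + 1e-10))
})

test_that("lengthscale is recovered from simulated data (small scale)", {
  ok <- vapply(1:3, function(s) {
    set.seed(s)
    t <- sort(runif(220, 0, 12))
    y <- draw_gp_data(t, 0.5, 1, 0.2, seed = 50 + s)
    m <- fit_gp(obs_set(t, y), config = quick_config(n_inducing = 300,
                                                     n_iter = 30),
                seed = s)
    abs(log(m$hyp$effects$time$lengthscale / 0.5)) < log(1.3)
  }, logical(1))
  expect_gte(sum(ok), 2L)
})

test_that("posterior samples are reproducible and consistent with the mean", {
  set.seed(15)
  t <- sort(runif(30, 0, 5))
  obs <- obs_set(t, draw_gp_data(t, 0.8, 1, 0.2, seed = 16))
  m <- fit_gp(obs, config = quick_config(), seed = 4)
  g <- seq(0, 5, length.out = 100)

  s1 <- draw_posterior_samples(m, g, n_samples = 5, seed = 99)
  s2 <- draw_posterior_samples(m, g, n_samples = 5, seed = 99)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(5L, 100L))

  big <- draw_posterior_samples(m, g, n_samples = 4000, seed = 7)
  p <- predict(m, g)
  mc_tol <- 4 * sqrt(max(p$latent_var) / 4000)
  expect_lt(max(abs(colMeans(big) - p$mean)), mc_tol * 2)
})
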