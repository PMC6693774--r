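# a gp_difference built directly from vectors, bypassing any fitting
make_diff <- function(time, mean, var) {
  structure(data.frame(time = time, mean = mean, var = var),
            class = c("gp_difference", "data.frame"))
}

test_that("EC equals the brute-force run counter on random masks", {
  set.seed(41)
  grid <- seq(0, 1, length.out = 64)
  for (i in 1:100) {
    mask <- runif(64) < runif(1, 0.05, 0.6)
    # encode the mask as a difference function exceeding z = 1 where TRUE
    d <- make_diff(grid, ifelse(mask, 5, 0), rep(1, 64))
    expect_identical(euler_characteristic(d, 1)$ec, oracle_run_count(mask))
  }
})

test_that("EC handles hand-constructed patterns and zero differences", {
  grid <- seq_len(7) / 10
  mask <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  d <- make_diff(grid, ifelse(mask, 3, 0), rep(1, 7))
  res <- euler_characteristic(d, 2)
  expect_identical(res$ec, 3L)
  expect_equal(nrow(res$regions), 3L)

  dz <- make_diff(grid, rep(0, 7), rep(1, 7))
  for (z in c(0.5, 1, 3, 6))
    expect_identical(euler_characteristic(dz, z)$ec, 0L)
})

test_that("EC curve endpoints behave as the threshold grows", {
  # one isolated bump at 5 sd: EC is 1 below 5 and 0 beyond
  grid <- seq(0, 10, length.out = 512)
  bump <- 5 * exp(-(grid - 5)^2 / (2 * 0.3^2))
  d <- make_diff(grid, bump, rep(1, 512))
  zg <- c(1, 2, 3, 4, 4.9, 5.1, 6)
  ec <- ec_curve(d, zg)
  expect_equal(ec, c(1L, 1L, 1L, 1L, 1L, 0L, 0L))
  # beyond max |mean| / sd the EC is always 0
  expect_true(all(ec[zg > max(abs(bump))] == 0L))
})

test_that("difference of identical models is zero with doubled variance", {
  set.seed(42)
  t <- sort(runif(40, 0, 5))
  obs <- obs_set(t, draw_gp_data(t, 0.8, 1, 0.2, seed = 43))
  m <- fit_gp(obs, config = quick_config(), seed = 6)
  g <- seq(0, 5, length.out = 64)
  d <- difference_function(m, m, g)
  expect_equal(d$mean, rep(0, 64), tolerance = 1e-12)
  expect_equal(d$var, 2 * predict(m, g)$latent_var, tolerance = 1e-12)
})

test_that("difference matches the dense oracle on two tiny exact GPs", {
  set.seed(44)
  t1 <- sort(runif(5, 0, 2)); y1 <- rnorm(5)
  t2 <- sort(runif(5, 0, 2)); y2 <- rnorm(5)
  m1 <- fit_gp(obs_set(t1, y1), config = quick_config(n_iter = 10,
                                                      n_restarts = 1),
               seed = 7)
  m2 <- fit_gp(obs_set(t2, y2), config = quick_config(n_iter = 10,
                                                      n_restarts = 1),
               seed = 8)
  g <- seq(0.2, 1.8, length.out = 20)
  d <- difference_function(m1, m2, g)
  h1 <- m1$hyp$effects$time; h2 <- m2$hyp$effects$time
  o1 <- oracle_posterior(t1, y1 - m1$center, g, h1$lengthscale,
                         h1$signal_sd, m1$hyp$noise_sd)
  o2 <- oracle_posterior(t2, y2 - m2$center, g, h2$lengthscale,
                         h2$signal_sd, m2$hyp$noise_sd)
  expect_equal(d$mean, (o1$mean + m1$center) - (o2$mean + m2$center),
               tolerance = 1e-6)
  expect_equal(d$var, o1$var + o2$var, tolerance = 1e-6)
})

test_that("bootstrap null is seeded, shaped, and errors on small pools", {
  obs <- sim_chirp_obs(n = 140, seed = 45)
  grid <- seq(0, 32, length.out = 256)
  zg <- c(1, 2, 3)
  cfg <- fit_config(n_inducing = 300, n_iter = 8, n_restarts = 1)
  n1 <- bootstrap_ec_null(obs, n_reps = 4, sample_size = 60, grid = grid,
                          z_grid = zg, config = cfg, seed = 9)
  n2 <- bootstrap_ec_null(obs, n_reps = 4, sample_size = 60, grid = grid,
                          z_grid = zg, config = cfg, seed = 9)
  expect_identical(n1, n2)
  expect_equal(dim(n1), c(4L, 3L))
  expect_error(bootstrap_ec_null(obs, n_reps = 2, sample_size = 100,
                                 grid = grid, z_grid = zg, config = cfg),
               "sample_size")
})

test_that("equality test is order-invariant in p up to shared pooling", {
  obs <- sim_chirp_obs(n = 240, seed = 46)
  set.seed(47)
  idx <- sample(240, 120)
  o1 <- obs_subset(obs, idx)
  o2 <- obs_subset(obs, setdiff(seq_len(240), idx))
  cfg <- fit_config(n_inducing = 300, n_iter = 10, n_restarts = 1)
  t12 <- equality_test(o1, o2, n_reps = 12, sample_size = 100, config = cfg,
                       seed = 10)
  t21 <- equality_test(o2, o1, n_reps = 12, sample_size = 100, config = cfg,
                       seed = 10)
  # the pooled set and seed coincide, so the null and p agree exactly
  expect_identical(t12$p, t21$p)
  expect_identical(t12$ec, t21$ec)
  # p is a proportion with ties counted as >=; add-one p never reaches 0
  expect_true(all(t12$p >= 0 & t12$p <= 1))
  expect_true(all(t12$p_add_one > 0))
  path <- withr::local_tempfile(fileext = ".csv")
  export_ec_csv(t12, path)
  expect_equal(nrow(read.csv(path)), length(t12$z_grid))
})

test_that("significant regions export as half-open millisecond intervals", {
  regions <- data.frame(start = c(1.25, 10), end = c(2.5, 12.125))
  path <- withr::local_tempfile(fileext = ".bed")
  export_regions_bed(regions, path, name = "cmp")
  lines <- readLines(path)
  expect_match(lines[1], "track name=cmp")
  expect_equal(lines[2], "cmp\t1250\t2500")
  expect_equal(lines[3], "cmp\t10000\t12125")
})
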