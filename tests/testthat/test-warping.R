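test_that("window count follows the spacing: 512 windows for 32 s", {
  st <- generate_stimulus(chirp_protocol(), sample_rate = 64)
  fits <- estimate_local_lengthscales(st)
  expect_equal(nrow(fits), 512L)
})

test_that("stationary sine gives constant lengthscales, chirp a falling trend", {
  # constant-frequency sine: lengthscale cv under 5%
  p <- sine_protocol(data.frame(frequency = rep(4, 20),
                                contrast = rep(100, 20)))
  f_sine <- estimate_local_lengthscales(generate_stimulus(p, 128))
  expect_false(any(f_sine$flagged))
  expect_lt(sd(f_sine$lengthscale) / mean(f_sine$lengthscale), 0.05)

  # 1 -> 8 Hz linear chirp: lengthscale monotonically decreasing
  tt <- seq(0, 16 - 1 / 128, by = 1 / 128)
  sweep_tr <- data.frame(time = tt,
                         value = 0.5 + 0.5 * sin(2 * pi * (tt + 7 * tt^2 /
                                                             32)))
  f_chirp <- estimate_local_lengthscales(sweep_tr)
  rho <- cor(f_chirp$window_center, f_chirp$lengthscale, method = "spearman")
  expect_lt(rho, -0.9)
})

test_that("flat windows are flagged and filled with the maximum lengthscale", {
  tt <- seq(0, 8 - 1 / 64, by = 1 / 64)
  v <- ifelse(tt < 4, 0.5 + 0.4 * sin(2 * pi * 3 * tt), 0.2)
  fits <- estimate_local_lengthscales(data.frame(time = tt, value = v))
  expect_true(any(fits$flagged))
  expect_equal(max(fits$lengthscale[fits$flagged]),
               max(fits$lengthscale[!fits$flagged]))
})

test_that("warp construction: linearity, monotonicity, inverse, slope ratio", {
  centers <- seq(0, 8 - 1 / 16, by = 1 / 16)
  base <- data.frame(window_center = centers,
                     lengthscale = rep(0.2, length(centers)),
                     amplitude = 1, offset = 0, flagged = FALSE)
  attr(base, "spacing") <- 1 / 16
  attr(base, "t0") <- 0
  class(base) <- c("autocorr_fits", "data.frame")

  # constant lengthscale: the warp is a straight line
  w <- build_time_warp(base)
  line <- seq(w$warped_values[1], w$warped_values[length(w$warped_values)],
              length.out = length(w$warped_values))
  expect_lt(max(abs(w$warped_values - line)), 1e-9)

  # halved lengthscale on the second half doubles the local warp slope
  two <- base
  two$lengthscale[two$window_center >= 4] <- 0.1
  w2 <- build_time_warp(two, normalize = FALSE)
  s1 <- (warp_forward(w2, 3) - warp_forward(w2, 1)) / 2
  s2 <- (warp_forward(w2, 7) - warp_forward(w2, 5)) / 2
  expect_equal(s2 / s1, 2, tolerance = 0.01)

  # strictly increasing; forward-then-inverse is the identity
  jitter_l <- base
  set.seed(21)
  jitter_l$lengthscale <- runif(nrow(base), 0.05, 0.5)
  w3 <- build_time_warp(jitter_l)
  expect_true(all(diff(w3$warped_values) > 0))
  tt <- seq(0, 8, length.out = 400)
  expect_lt(max(abs(warp_inverse(w3, warp_forward(w3, tt)) - tt)), 1e-9)

  # the inv_sq variant accumulates 1/(2 l^2)
  w4 <- build_time_warp(two, normalize = FALSE, variant = "inv_sq")
  r1 <- (warp_forward(w4, 3) - warp_forward(w4, 1)) / 2
  expect_equal(r1, 1 / (2 * 0.2^2), tolerance = 0.01)

  expect_error(build_time_warp(transform(base, lengthscale = NaN)),
               "finite")
})

test_that("warped GP reports higher latent sd in fast chirp segments", {
  st <- generate_stimulus(chirp_protocol(), 128)
  warp <- stimulus_time_warp(st)
  obs <- sim_chirp_obs(n = 500, noise_sd = 0.1, seed = 31)
  m <- fit_gp(obs, config = quick_config(n_inducing = 200, n_iter = 20),
              warp = warp, seed = 5)
  # late (fast, ~6-8 Hz) sweep segment vs the ON step plateau
  sd_fast <- mean(sqrt(predict(m, seq(14, 15.5, by = 1 / 64))$latent_var))
  sd_step <- mean(sqrt(predict(m, seq(3, 4.5, by = 1 / 64))$latent_var))
  expect_gt(sd_fast, sd_step)
})

test_that("warp round-trips through CSV export", {
  tt <- seq(0, 4 - 1 / 64, by = 1 / 64)
  tr <- data.frame(time = tt, value = 0.5 + 0.5 * sin(2 * pi * 2 * tt))
  fits <- estimate_local_lengthscales(tr)
  w <- build_time_warp(fits)
  path <- withr::local_tempfile(fileext = ".csv")
  export_warp_csv(fits, w, path)
  back <- read.csv(path)
  expect_equal(back$lengthscale, fits$lengthscale, tolerance = 1e-6)
  expect_true(all(diff(back$warped_time) > 0))
})
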