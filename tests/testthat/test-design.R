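test_that("blue-noise sampling honours thresholds and minimum distance", {
  sp <- parameter_space()
  pts <- blue_noise_parameters(sp, n = 150, seed = 71)
  expect_equal(nrow(pts), 150L)
  expect_true(all(pts$frequency >= 1))
  expect_true(all(pts$contrast >= 10))
  R <- gptrace:::space_rescale(sp, pts$frequency, pts$contrast)
  d <- as.matrix(dist(R))
  diag(d) <- Inf
  expect_gte(min(d), 0.7 * sqrt(1 / 150))

  expect_error(blue_noise_parameters(sp, n = 50, min_dist = 0.5,
                                     max_attempts = 2000),
               "smaller min_dist")
})

test_that("batch selection finds constructed peaks with deterministic ties", {
  sp <- parameter_space(resolution = 32)
  fr <- seq(1, 8, length.out = 32)
  co <- seq(10, 100, length.out = 32)
  bump <- function(i0, j0, amp) {
    outer(seq_len(32), seq_len(32), function(i, j)
      amp * exp(-((i - i0)^2 + (j - j0)^2) / 18))
  }
  V <- bump(8, 8, 3) + bump(16, 25, 2.2) + bump(27, 10, 1.5)
  map <- structure(list(value = V, frequency = fr, contrast = co,
                        space = sp, time_grid = 0),
                   class = "uncertainty_map")
  top3 <- select_next_batch(map, batch_size = 3, min_peak_dist = 3)
  got <- cbind(match(top3$frequency, fr), match(top3$contrast, co))
  expect_setequal(paste(got[, 1], got[, 2]),
                  c("8 8", "16 25", "27 10"))
  # ranked by map value: the global maximum comes first
  expect_equal(got[1, ], c(8L, 8L))

  # fill rule: more points than peaks still respects the separation
  top10 <- select_next_batch(map, batch_size = 10, min_peak_dist = 3)
  expect_equal(nrow(top10), 10L)
  cells <- cbind(match(top10$frequency, fr), match(top10$contrast, co))
  cheb <- outer(seq_len(10), seq_len(10), Vectorize(function(a, b)
    max(abs(cells[a, ] - cells[b, ]))))
  diag(cheb) <- Inf
  expect_gte(min(cheb), 3)

  expect_error(select_next_batch(map, batch_size = 0), "positive")
})

test_that("boundary handling: edge peaks excluded unless requested", {
  sp <- parameter_space(resolution = 16)
  V <- outer(seq_len(16), seq_len(16), function(i, j) i + j)  # max at corner
  map <- structure(list(value = V, frequency = seq(1, 8, length.out = 16),
                        contrast = seq(10, 100, length.out = 16),
                        space = sp, time_grid = 0),
                   class = "uncertainty_map")
  off <- select_next_batch(map, batch_size = 1, min_peak_dist = 3,
                           include_boundary = FALSE)
  on <- select_next_batch(map, batch_size = 1, min_peak_dist = 3,
                          include_boundary = TRUE)
  # with the boundary excluded, the corner cell cannot be chosen as a peak
  expect_false(off$is_peak[1] && off$frequency[1] == 8 &&
                 off$contrast[1] == 100)
  # with reflect padding the global maximum at the corner is selected
  expect_true(on$is_peak[1])
  expect_equal(on$frequency[1], 8)
  expect_equal(on$contrast[1], 100)
})

test_that("uncertainty map: prior limit and reduction at observed cells", {
  # model with (almost) no information: map is constant at the prior level
  set.seed(72)
  pars <- blue_noise_parameters(parameter_space(), n = 20, seed = 73)
  prot <- sine_protocol(pars)
  st <- generate_stimulus(prot, 64)
  neu <- gt_neuron(noise_sd = 0.1,
                   freq_tuning = function(f) 1 / (1 + 0.3 * f))
  tt <- sort(runif(400, 0, prot$duration))
  obs <- simulate_roi_observations(neu, st, tt, seed = 74)
  effects <- candidate_effects("sine")[c("phase", "frequency:contrast")]
  enc <- encode_predictors(obs, effects)
  m <- fit_gp(obs, kernel = compose_effect_kernel(effects),
              config = fit_config(150, 15, 2), encoding = enc, seed = 75)
  tg <- seq(0, 1, length.out = 8)
  map <- latent_uncertainty_map(m, parameter_space(resolution = 16),
                                time_grid = tg)
  expect_equal(dim(map$value), c(16L, 16L))
  expect_true(all(is.finite(map$value)))

  # cells at observed parameters are less uncertain than the most
  # uncertain cells of the map
  obs_cells <- unique(cbind(
    findInterval(pars$frequency, map$frequency),
    findInterval(pars$contrast, map$contrast)))
  obs_cells[obs_cells == 0] <- 1L
  v_obs <- mean(map$value[obs_cells])
  expect_lt(v_obs, max(map$value))
})

test_that("closed-loop step appends data, refits and reduces uncertainty", {
  set.seed(76)
  sp <- parameter_space(resolution = 16)
  effects <- candidate_effects("sine")[c("phase", "frequency:contrast")]
  state <- design_state(sp, effects, batch_size = 5)
  neu <- gt_neuron(noise_sd = 0.1,
                   freq_tuning = function(f) 1 / (1 + 0.3 * f))
  run_round <- function(state, pars, seed) {
    prot <- sine_protocol(pars)
    st <- generate_stimulus(prot, 64)
    tt <- sort(runif(12 * nrow(pars), 0, prot$duration))
    obs <- simulate_roi_observations(neu, st, tt, seed = seed)
    closed_loop_step(state, obs, pars, config = fit_config(120, 12, 2),
                     time_grid = seq(0, 1, length.out = 8),
                     resolution = 16, seed = seed)
  }
  s1 <- run_round(state, blue_noise_parameters(sp, 10, seed = 77), 78)
  expect_equal(s1$round, 1L)
  expect_equal(nrow(s1$next_batch), 5L)
  expect_true(all(s1$next_batch$frequency >= 1 &
                    s1$next_batch$contrast >= 10))
  s2 <- run_round(s1, s1$next_batch[c("frequency", "contrast")], 79)
  expect_equal(nrow(s2$params), 15L)
  # under the round-1 kernel, conditioning on more observations can only
  # reduce the summed latent variance
  m2 <- latent_uncertainty_map(set_gp_hyperparams(s2$model, s1$model$hyp),
                               sp, time_grid = seq(0, 1, length.out = 8),
                               resolution = 16)
  expect_lt(sum(m2$value), sum(s1$map$value) + 1e-9)
})
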