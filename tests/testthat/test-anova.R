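# a sine-stimulus observation set whose response is modulated only by the
# requested tuning functions
sim_sine_obs <- function(n_trials = 30, n = 600, noise_sd = 0.12, seed = 1,
                         freq_tuning = NULL, contrast_tuning = NULL) {
  set.seed(seed)
  pars <- blue_noise_parameters(parameter_space(), n = n_trials, seed = seed)
  prot <- sine_protocol(pars)
  st <- generate_stimulus(prot, 128)
  neu <- gt_neuron(noise_sd = noise_sd, freq_tuning = freq_tuning,
                   contrast_tuning = contrast_tuning)
  tt <- sort(runif(n, 0, prot$duration))
  simulate_roi_observations(neu, st, tt, seed = seed + 7)
}

test_that("predictor encoding: circularity, phase origin, z-scoring", {
  obs <- sim_sine_obs(n_trials = 12, n = 300, seed = 61)
  cands <- candidate_effects("sine")
  enc <- encode_predictors(obs, cands)
  X <- gptrace:::encoding_matrix(enc, obs)
  expect_true(all(c("phase_cos", "phase_sin", "frequency", "contrast",
                    "trial_time") %in% colnames(X)))
  # z-scored training columns have mean 0, sd 1 (constant columns excepted)
  for (cc in colnames(X)) {
    if (sd(X[, cc]) > 1e-9) {
      expect_equal(mean(X[, cc]), 0, tolerance = 1e-10)
      expect_equal(sd(X[, cc]), 1, tolerance = 1e-10)
    }
  }

  # direction circularity: 0 and 360 degrees encode identically
  dir_obs <- obs_set(c(1, 2), c(0, 0), stim = data.frame(
    direction = c(0, 360), trial_time = c(0, 0)))
  enc_d <- encode_predictors(dir_obs, candidate_effects("moving_bar"))
  Xd <- gptrace:::encoding_matrix(enc_d, dir_obs)
  expect_equal(Xd[1, c("dir_cos", "dir_sin")],
               Xd[2, c("dir_cos", "dir_sin")], tolerance = 1e-12)

  # phase at t = 0 is (cos, sin) = (1, 0) before z-scoring
  raw <- gptrace:::raw_predictor_frame(
    obs_set(0, 0, stim = data.frame(trial_time = 0, frequency = 3)),
    c("phase_cos", "phase_sin"))
  expect_equal(unlist(raw), c(phase_cos = 1, phase_sin = 0))

  # a requested effect with a missing parameter errors by name
  expect_error(encode_predictors(obs_set(1, 1),
                                 candidate_effects("sine")["frequency"]),
               "frequency")
})

test_that("likelihood ratio test matches the chi-squared oracle", {
  # identical fits: Lambda 0, p 1
  r0 <- likelihood_ratio_test(-100, -100, added_df = 2)
  expect_equal(r0$lambda, 0)
  expect_equal(r0$p, 1)

  # the survival function equals the incomplete-gamma form
  set.seed(62)
  for (i in 1:20) {
    l0 <- runif(1, -200, -100)
    l1 <- l0 + runif(1, 0, 10)
    df <- sample(1:5, 1)
    r <- likelihood_ratio_test(l0, l1, added_df = df)
    lam <- 2 * (l1 - l0)
    # upper incomplete gamma ratio, independently via pgamma
    expect_equal(r$p, pgamma(lam / 2, df / 2, lower.tail = FALSE),
                 tolerance = 1e-10)
  }

  expect_warning(r2 <- likelihood_ratio_test(-10, -11), "clamped")
  expect_equal(r2$lambda, 0)
})

test_that("LRT null calibration: rejection rate near alpha", {
  # under H0 the deviance of one extra unconstrained parameter pair is
  # chi-squared; simulate the test decision directly on its inputs
  set.seed(63)
  alpha <- 0.05
  rej <- mean(vapply(1:400, function(i) {
    lam <- rchisq(1, df = 2)
    likelihood_ratio_test(0, lam / 2, added_df = 2, alpha = alpha)$reject
  }, logical(1)))
  expect_lt(abs(rej - alpha), 0.03)
})

test_that("forward selection recovers a frequency-only modulation", {
  obs <- sim_sine_obs(n_trials = 30, n = 500, seed = 64,
                      freq_tuning = function(f) 1 / (1 + 0.4 * f))
  cands <- candidate_effects("sine")[c("phase", "frequency", "contrast")]
  sel <- forward_select_effects(obs, cands,
                                config = fit_config(500, 20, 2),
                                alpha = 0.01, seed = 65)
  expect_gte(length(sel$effects), 1L)
  # pass 1 adopts exactly one candidate unconditionally
  p1 <- subset(sel$audit, pass == 1)
  expect_equal(sum(p1$decision == "adopted"), 1L)
  # the audit lists one row per candidate per pass
  expect_false(any(duplicated(sel$audit[c("pass", "candidate")])))
  # nested objectives never decrease across passes for adopted models
  adopted <- subset(sel$audit, decision == "adopted")
  if (nrow(adopted) > 1)
    expect_true(all(diff(adopted$objective) > -1e-6))
})
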