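# Independent oracles and small fixtures used across the test suite. These
# deliberately avoid the package's fitting/prediction code paths: they use
# plain dense linear algebra (solve / determinant) so that agreement with
# the package is a genuine cross-check.

# scalar RBF kernel, evaluated elementwise
oracle_rbf <- function(x, x2, l, s_sig) {
  s_sig^2 * exp(-sum((x - x2)^2) / (2 * l^2))
}

# dense log marginal likelihood via solve() and determinant()
oracle_lml <- function(t, y, l, s_sig, s_noise) {
  n <- length(t)
  K <- outer(t, t, function(a, b) s_sig^2 * exp(-(a - b)^2 / (2 * l^2)))
  K <- K + diag(s_noise^2, n)
  drop(-0.5 * t(y) %*% solve(K, y) -
         0.5 * as.numeric(determinant(K)$modulus) - n / 2 * log(2 * pi))
}

# dense GP posterior (mean and latent variance diagonal) via solve()
oracle_posterior <- function(t, y, tstar, l, s_sig, s_noise) {
  k <- function(a, b) s_sig^2 * exp(-outer(a, b, "-")^2 / (2 * l^2))
  Ky <- k(t, t) + diag(s_noise^2, length(t))
  Ks <- k(tstar, t)
  mean <- drop(Ks %*% solve(Ky, y))
  var <- s_sig^2 - diag(Ks %*% solve(Ky, t(Ks)))
  list(mean = mean, var = pmax(var, 0))
}

# brute-force connected-run counter for logical masks
oracle_run_count <- function(mask) {
  count <- 0L
  prev <- FALSE
  for (m in mask) {
    if (m && !prev) count <- count + 1L
    prev <- m
  }
  count
}

# draw a noisy sample path from a known RBF GP at given times
draw_gp_data <- function(t, l, s_sig, s_noise, seed) {
  set.seed(seed)
  K <- outer(t, t, function(a, b) s_sig^2 * exp(-(a - b)^2 / (2 * l^2)))
  f <- drop(crossprod(chol(K + diag(1e-9, length(t))),
                      stats::rnorm(length(t))))
  f + stats::rnorm(length(t), 0, s_noise)
}

# small fast fitting configuration for unit tests
quick_config <- function(n_inducing = 500, n_iter = 20, n_restarts = 2) {
  fit_config(n_inducing = n_inducing, n_iter = n_iter,
             n_restarts = n_restarts)
}

# a compact smooth-response observation set driven by the chirp generator
sim_chirp_obs <- function(n = 200, noise_sd = 0.15, seed = 1,
                          duration = 32, offset_fun = NULL) {
  st <- generate_stimulus(chirp_protocol(), 128)
  neu <- gt_neuron(noise_sd = noise_sd, offset_fun = offset_fun)
  set.seed(seed)
  times <- sort(stats::runif(n, 0, duration))
  simulate_roi_observations(neu, st, times, seed = seed + 1000)
}
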