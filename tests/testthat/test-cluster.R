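# light-weight fitted models built directly at fixed hyperparameters so the
# clustering structure is fully controlled
fixed_gp <- function(t, y, l = 0.5, s_sig = 1, s_noise = 0.1) {
  m <- structure(list(
    kernel = compose_effect_kernel(rbf_effect("time", "time")),
    hyp = list(effects = list(time = list(lengthscale = l,
                                          signal_sd = s_sig)),
               noise_sd = s_noise),
    X = matrix(t, ncol = 1, dimnames = list(NULL, "time")),
    y = y - median(y), center = median(y), Z = NULL, sparse = FALSE,
    objective = NA_real_, n_obs = length(t), warp = NULL, encoding = NULL,
    restart = 1L, config = fit_config()), class = "fitted_gp")
  m$cache <- gptrace:::build_gp_cache(m)
  m
}

test_that("Ward clustering of mean functions separates response families", {
  set.seed(91)
  t <- seq(0, 6, length.out = 80)
  on_step <- function() as.numeric(t > 2 & t < 4) + rnorm(80, 0, 0.05)
  off_step <- function() -as.numeric(t > 2 & t < 4) + rnorm(80, 0, 0.05)
  models <- c(lapply(1:4, function(i) fixed_gp(t, on_step())),
              lapply(1:4, function(i) fixed_gp(t, off_step())))
  names(models) <- paste0("roi", 1:8)
  dend <- cluster_mean_functions(models, t)

  hc <- dend$hclust
  expect_true(all(diff(hc$height) > -1e-9))  # Ward heights non-decreasing
  root_split <- cutree(hc, k = 2)
  expect_equal(length(unique(root_split[1:4])), 1L)
  expect_equal(length(unique(root_split[5:8])), 1L)
  expect_false(root_split[1] == root_split[5])

  # identical mean vectors merge at height zero
  y0 <- on_step()
  m_same <- list(a = fixed_gp(t, y0), b = fixed_gp(t, y0))
  d0 <- cluster_mean_functions(m_same, t)
  expect_equal(min(d0$hclust$height), 0, tolerance = 1e-9)
})

test_that("prune_dendrogram returns a valid frontier partition with audit", {
  set.seed(92)
  pop <- simulate_population(2, 4, effect_size = 6, max_obs = 250,
                             noise_sd = 0.1, seed = 93)
  cfg <- fit_config(n_inducing = 300, n_iter = 12, n_restarts = 2)
  models <- lapply(pop$observations, fit_gp, config = cfg, seed = 94)
  grid <- seq(0, 32, by = 1 / 16)
  dend <- cluster_mean_functions(models, grid)
  res <- prune_dendrogram(dend, pop$observations, grid = grid,
                          n_reps = 30, sample_size = 200,
                          config = cfg,
                          boot_config = fit_config(300, 8, 1),
                          seed = 95)
  # every ROI in exactly one accepted cluster
  expect_setequal(res$assignment$roi_id, names(pop$observations))
  expect_false(anyNA(res$assignment$cluster))
  expect_equal(res$n_clusters, length(unique(res$assignment$cluster)))
  # audit holds the tested nodes in traversal order, root first
  expect_equal(res$audit$node[1], nrow(dend$hclust$merge))
  expect_true(all(res$audit$decision %in% c(TRUE, FALSE)))
})

test_that("singleton sides and small pools are handled with a warning", {
  set.seed(96)
  t <- sort(runif(120, 0, 6))
  mk <- function(seed, shift = 0) {
    set.seed(seed)
    obs_set(t, sin(t) + shift + rnorm(120, 0, 0.2))
  }
  expect_warning(
    res <- test_split_node(mk(1), mk(2), grid = seq(0, 6, by = 1 / 16),
                           n_reps = 10, sample_size = 300,
                           config = fit_config(300, 8, 1)),
    "reduced")
  expect_true(is.finite(res$p))
})

test_that("responsiveness filter separates flat from step-responsive ROIs", {
  set.seed(97)
  t <- seq(0, 6, length.out = 150)
  resp <- fixed_gp(t, 0.02 * rnorm(150) + as.numeric(t > 2) * 1.5,
                   s_noise = 0.05)
  flat <- fixed_gp(t, 0.02 * rnorm(150), s_noise = 0.05)
  keep <- filter_responsive_rois(list(r = resp, f = flat), step_time = 2)
  expect_true(keep[["r"]])
  expect_false(keep[["f"]])
})
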