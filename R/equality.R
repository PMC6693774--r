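# GP equality testing via the difference process and the Euler
# characteristic of its exceedance set, with bootstrap null distributions,
# plus the classical frame-average/spline baseline and its shuffle test.

#' Difference of two GP posteriors
#'
#' Computes the pointwise difference process of two independently fitted
#' GPs on a shared regular grid: mean `mu1 - mu2` and variance
#' `var1 + var2`, using the latent (noise-free) posteriors; the
#' observation-noise components are excluded.
#'
#' @param gp1,gp2 `fitted_gp` models over the same predictor space.
#' @param grid Regular numeric grid of times.
#' @return Data.frame of class `gp_difference` with columns `time`, `mean`,
#'   `var`.
#' @export
difference_function <- function(gp1, gp2, grid) {
  stopifnot(inherits(gp1, "fitted_gp"), inherits(gp2, "fitted_gp"))
  if (ncol(gp1$X) != ncol(gp2$X))
    stop("models have mismatched predictor dimensionality")
  p1 <- predict(gp1, grid)
  p2 <- predict(gp2, grid)
  out <- data.frame(time = grid, mean = p1$mean - p2$mean,
                    var = p1$latent_var + p2$latent_var)
  class(out) <- c("gp_difference", "data.frame")
  out
}

# run counting on a logical mask: number of maximal contiguous TRUE runs
count_runs <- function(mask) {
  if (!any(mask)) return(0L)
  r <- rle(mask)
  sum(r$values)
}

#' Euler characteristic of a difference function at one threshold
#'
#' The EC is the number of discrete, non-intersecting grid regions where
#' `|mean| > z * sqrt(var)`, i.e. where the `z`-sd credible band of the
#' difference excludes zero.
#'
#' @param diff A `gp_difference` from [difference_function()].
#' @param z Threshold in posterior standard deviations (default 3).
#' @return List with `ec` (count) and `regions` (data.frame of half-open
#'   `[start, end)` time intervals).
#' @export
euler_characteristic <- function(diff, z = 3) {
  stopifnot(inherits(diff, "gp_difference"), z > 0)
  mask <- abs(diff$mean) > z * sqrt(diff$var)
  ec <- count_runs(mask)
  regions <- data.frame(start = numeric(0), end = numeric(0))
  if (ec > 0) {
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    dt <- if (nrow(diff) > 1) stats::median(diff(diff$time)) else 0
    regions <- data.frame(start = diff$time[starts[keep]],
                          end = diff$time[ends[keep]] + dt)
  }
  list(ec = as.integer(ec), regions = regions)
}

#' EC as a function of the threshold
#'
#' @param diff A `gp_difference`.
#' @param z_grid Increasing vector of thresholds (sd multipliers).
#' @return Integer vector of EC values, one per threshold.
#' @export
ec_curve <- function(diff, z_grid) {
  stopifnot(all(diff(z_grid) > 0))
  vapply(z_grid, function(z) euler_characteristic(diff, z)$ec, integer(1))
}

#' Bootstrap null distribution of the EC curve
#'
#' Approximates the null distribution of the EC under "no difference" by
#' repeatedly drawing two disjoint samples (without replacement, within each
#' replicate) from the pooled observations, fitting a GP to each, and
#' computing the EC of their difference over the threshold grid. Replicates
#' whose fits fail are redrawn, up to 10% of the replicate count.
#'
#' @param pooled Pooled [obs_set()] (both conditions concatenated).
#' @param n_reps Number of bootstrap replicates (default 500).
#' @param sample_size Observations per sample (default 300).
#' @param grid Prediction grid for the difference.
#' @param z_grid Threshold grid.
#' @param config [fit_config()] for the replicate fits; defaults to a
#'   single restart (a deliberate speed/accuracy trade-off for the
#'   bootstrap).
#' @param warp Optional warp shared with the main fits.
#' @param init Optional warm-start hyperparameters for the replicate fits
#'   (normally the main fits' point estimates), stabilising the
#'   single-restart replicates.
#' @param seed Optional integer seed; the null matrix is reproducible.
#' @return Matrix of dimension `n_reps` by `length(z_grid)`.
#' @export
bootstrap_ec_null <- function(pooled, n_reps = 500, sample_size = 300,
                              grid, z_grid = default_z_grid(),
                              config = fit_config(n_restarts = 1),
                              warp = NULL, init = NULL, seed = NULL) {
  stopifnot(inherits(pooled, "obs_set"))
  n <- length(pooled$times)
  if (n < 2 * sample_size)
    stop("pooled set (", n, ") smaller than 2 * sample_size (",
         2 * sample_size, ")")
  if (!is.null(seed)) set.seed(seed)
  # canonical pool order, so the null is invariant to condition order
  ord <- order(pooled$times, pooled$values)
  pooled <- obs_subset(pooled, ord)
  null_mat <- matrix(NA_real_, n_reps, length(z_grid))
  redraws <- 0L
  max_redraws <- ceiling(0.1 * n_reps)
  rep_i <- 1L
  while (rep_i <= n_reps) {
    idx <- sample.int(n, 2 * sample_size)
    o1 <- obs_subset(pooled, idx[seq_len(sample_size)])
    o2 <- obs_subset(pooled, idx[sample_size + seq_len(sample_size)])
    ecs <- tryCatch({
      g1 <- fit_gp(o1, config = config, warp = warp, init = init)
      g2 <- fit_gp(o2, config = config, warp = warp, init = init)
      ec_curve(difference_function(g1, g2, grid), z_grid)
    }, error = function(e) NULL)
    if (is.null(ecs)) {
      redraws <- redraws + 1L
      if (redraws > max_redraws)
        stop("bootstrap replicate failure rate exceeded 10%")
      message("bootstrap replicate refit failed; redrawing")
      next
    }
    null_mat[rep_i, ] <- ecs
    rep_i <- rep_i + 1L
  }
  null_mat
}

#' Default threshold grid for EC curves
#'
#' @return Thresholds from 0.5 to 6 sd in steps of 0.25.
#' @export
default_z_grid <- function() seq(0.5, 6, by = 0.25)

#' GP equality test between two observation sets
#'
#' Fits one GP per condition, computes the EC curve of their latent
#' difference, builds the bootstrap null from the pooled observations and
#' reports per-threshold empirical p-values: the raw proportion of null
#' replicates whose EC is at least the observed EC (ties count, so an
#' observed EC of 0 gives p = 1 and a clear difference can give exactly
#' p = 0). The headline decision is taken at `z = 3` with `alpha = 0.01`.
#' An add-one-corrected p-value is also reported.
#'
#' @param obs1,obs2 [obs_set()] objects over the same predictor space.
#' @param grid Prediction grid; default spacing 1/64 s over the joint span.
#' @param z_grid Threshold grid (default [default_z_grid()]).
#' @param z Headline threshold (default 3).
#' @param alpha Significance level (default 0.01).
#' @param n_reps,sample_size Bootstrap settings (defaults 500 and 300).
#' @param config [fit_config()] for the two main fits.
#' @param boot_config [fit_config()] for bootstrap fits (default: single
#'   restart, same iteration cap).
#' @param warp Optional warp applied to all fits.
#' @param init Optional warm-start hyperparameters applied to the two main
#'   fits (e.g. from a fit of the pooled observations); the bootstrap
#'   replicates are always warm-started from the main fits.
#' @param seed Optional integer seed.
#' @return An object of class `ec_test`: `z_grid`, `ec` (observed curve),
#'   `null` (replicate-by-threshold matrix), `p`, `p_add_one`,
#'   `significant_regions` at `z`, and the headline `p_value`/`reject`.
#' @export
equality_test <- function(obs1, obs2, grid = NULL,
                          z_grid = default_z_grid(), z = 3, alpha = 0.01,
                          n_reps = 500, sample_size = 300,
                          config = fit_config(),
                          boot_config = NULL, warp = NULL, init = NULL,
                          seed = NULL) {
  stopifnot(inherits(obs1, "obs_set"), inherits(obs2, "obs_set"),
            length(obs1) > 0, length(obs2) > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(grid)) {
    span <- range(c(obs1$times, obs2$times))
    grid <- seq(span[1], span[2], by = 1 / 64)
  }
  if (is.null(boot_config))
    boot_config <- fit_config(n_inducing = config$n_inducing,
                              n_iter = config$n_iter, n_restarts = 1)
  g1 <- fit_gp(obs1, config = config, warp = warp, init = init,
               seed = if (!is.null(seed)) seed + 1L)
  g2 <- fit_gp(obs2, config = config, warp = warp, init = init,
               seed = if (!is.null(seed)) seed + 1L)
  dfun <- difference_function(g1, g2, grid)
  ec_obs <- ec_curve(dfun, z_grid)
  pooled <- pool_observations(obs1, obs2)
  sample_size <- min(sample_size, floor(length(pooled) / 2))
  # replicate fits are warm-started at the geometric mean of the two main
  # fits' hyperparameters (same kernel structure by construction)
  init <- list(effects = Map(function(a, b) list(
    lengthscale = sqrt(a$lengthscale * b$lengthscale),
    signal_sd = sqrt(a$signal_sd * b$signal_sd)),
    g1$hyp$effects, g2$hyp$effects),
    noise_sd = sqrt(g1$hyp$noise_sd * g2$hyp$noise_sd))
  null_mat <- bootstrap_ec_null(pooled, n_reps = n_reps,
                                sample_size = sample_size, grid = grid,
                                z_grid = z_grid, config = boot_config,
                                warp = warp, init = init,
                                seed = if (!is.null(seed)) seed + 3L)
  exceed <- sweep(null_mat, 2, ec_obs, ">=") * 1
  p <- colMeans(exceed)
  p1 <- (colSums(exceed) + 1) / (n_reps + 1)
  zi <- which.min(abs(z_grid - z))
  ecz <- euler_characteristic(dfun, z_grid[zi])
  structure(list(
    z_grid = z_grid, ec = ec_obs, null = null_mat, p = p, p_add_one = p1,
    z = z_grid[zi], alpha = alpha, p_value = p[zi],
    reject = p[zi] < alpha,
    significant_regions = ecz$regions,
    models = list(g1, g2), difference = dfun, grid = grid),
    class = "ec_test")
}

#' @export
print.ec_test <- function(x, ...) {
  cat("<ec_test> GP equality test\n")
  cat(sprintf("  EC at z = %.2f: %d; empirical p = %.4g (alpha = %g)\n",
              x$z, x$ec[which.min(abs(x$z_grid - x$z))], x$p_value, x$alpha))
  cat("  decision:", if (x$reject) "signals differ" else
    "no evidence of difference", "\n")
  if (nrow(x$significant_regions))
    cat("  significant regions (s):",
        paste(sprintf("[%.2f, %.2f)", x$significant_regions$start,
                      x$significant_regions$end), collapse = " "), "\n")
  invisible(x)
}

#' Export an EC test to CSV
#'
#' Writes one row per threshold with the observed EC, the null mean/sd and
#' the empirical p-value.
#'
#' @param test An `ec_test`.
#' @param path Output file path.
#' @export
export_ec_csv <- function(test, path) {
  utils::write.csv(data.frame(
    z = test$z_grid, ec_observed = test$ec,
    null_mean = colMeans(test$null),
    null_sd = apply(test$null, 2, stats::sd), p = test$p),
    path, row.names = FALSE)
  invisible(path)
}

#' Export significant regions as BED-like intervals
#'
#' Three-column half-open intervals with coordinates in integer
#' milliseconds, preceded by a track line naming the comparison.
#'
#' @param regions Data.frame with `start`/`end` columns in seconds.
#' @param path Output file path.
#' @param name Comparison identifier for the track line.
#' @export
export_regions_bed <- function(regions, path, name = "comparison") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track name=%s", name), con)
  if (nrow(regions))
    writeLines(sprintf("%s\t%d\t%d", name,
                       as.integer(round(regions$start * 1000)),
                       as.integer(round(regions$end * 1000))), con)
  invisible(path)
}

#' Classical frame-average / spline estimate
#'
#' The classical pipeline baseline: each trial's frame-averaged trace is
#' interpolated onto a common time base with a cubic spline, and the mean
#' and inter-trial standard deviation are taken across trials.
#'
#' @param per_trial_frames List of data.frames with `time`/`value` columns,
#'   one per trial (frame-averaged samples).
#' @param timebase Common regular grid for interpolation.
#' @return Object of class `classical_estimate` with `timebase`, `traces`
#'   (trial-by-grid matrix), `mean`, `sd`.
#' @export
classical_estimate <- function(per_trial_frames, timebase) {
  stopifnot(length(per_trial_frames) >= 1L)
  traces <- t(vapply(per_trial_frames, function(tr) {
    if (nrow(tr) < 4L)
      stop("a trial has fewer than 4 frames; cubic spline underdetermined")
    stats::splinefun(tr$time, tr$value, method = "fmm")(timebase)
  }, numeric(length(timebase))))
  m <- colMeans(traces)
  s <- if (nrow(traces) >= 2L) apply(traces, 2, stats::sd) else
    rep(NA_real_, length(timebase))
  structure(list(timebase = timebase, traces = traces, mean = m, sd = s),
            class = "classical_estimate")
}

#' Classical shuffle test
#'
#' EC-based equality test for the classical pipeline: the observed EC counts
#' regions where `|mean1 - mean2|` exceeds `z` times the combined
#' inter-trial standard deviation `sqrt(sd1^2 + sd2^2)`; the null is built
#' by reshuffling the interpolated trial traces between the two conditions.
#'
#' @param trials1,trials2 Lists of per-trial frame data.frames
#'   (`time`/`value`), at least 2 trials each.
#' @param timebase Common interpolation grid.
#' @param z_grid Threshold grid (default [default_z_grid()]).
#' @param z Headline threshold (default 3).
#' @param alpha Significance level (default 0.01).
#' @param n_shuffles Number of shuffled pairs (default 500).
#' @param seed Optional integer seed.
#' @return An object of class `ec_test` (without GP models).
#' @export
classical_shuffle_test <- function(trials1, trials2, timebase,
                                   z_grid = default_z_grid(), z = 3,
                                   alpha = 0.01, n_shuffles = 500,
                                   seed = NULL) {
  if (length(trials1) < 2L || length(trials2) < 2L)
    stop("need at least 2 trials per condition")
  if (!is.null(seed)) set.seed(seed)
  e1 <- classical_estimate(trials1, timebase)
  e2 <- classical_estimate(trials2, timebase)
  ec_of <- function(m1, s1, m2, s2) {
    sd_c <- sqrt(s1^2 + s2^2)
    vapply(z_grid, function(zz)
      count_runs(abs(m1 - m2) > zz * sd_c), integer(1))
  }
  ec_obs <- ec_of(e1$mean, e1$sd, e2$mean, e2$sd)
  all_tr <- rbind(e1$traces, e2$traces)
  n1 <- nrow(e1$traces); ntot <- nrow(all_tr)
  null_mat <- t(vapply(seq_len(n_shuffles), function(b) {
    idx <- sample.int(ntot)
    a <- all_tr[idx[seq_len(n1)], , drop = FALSE]
    b2 <- all_tr[idx[(n1 + 1):ntot], , drop = FALSE]
    ec_of(colMeans(a), apply(a, 2, stats::sd),
          colMeans(b2), apply(b2, 2, stats::sd))
  }, integer(length(z_grid))))
  exceed <- sweep(null_mat, 2, ec_obs, ">=") * 1
  p <- colMeans(exceed)
  zi <- which.min(abs(z_grid - z))
  structure(list(z_grid = z_grid, ec = ec_obs, null = null_mat, p = p,
                 p_add_one = (colSums(exceed) + 1) / (n_shuffles + 1),
                 z = z_grid[zi], alpha = alpha, p_value = p[zi],
                 reject = p[zi] < alpha,
                 significant_regions = data.frame(start = numeric(0),
                                                  end = numeric(0)),
                 estimates = list(e1, e2)),
            class = "ec_test")
}
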