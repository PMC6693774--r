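# Posterior queries for fitted (sparse) GP models.

# latent posterior mean and either the variance diagonal or the full
# covariance at encoded predictor rows Xs
posterior_raw <- function(model, Xs, full_cov = FALSE) {
  hyp <- model$hyp; spec <- model$kernel; cache <- model$cache
  prior_var <- spec_prior_var(spec, hyp)
  if (!model$sparse) {
    Kxs <- spec_kernel_matrix(spec, hyp, model$X, Xs)      # n x P
    mean <- drop(crossprod(Kxs, cache$alpha))
    v <- backsolve(cache$L, Kxs, transpose = TRUE)
    if (full_cov) {
      cov <- spec_kernel_matrix(spec, hyp, Xs) - crossprod(v)
      list(mean = mean, cov = cov)
    } else {
      list(mean = mean, var = pmax(prior_var - colSums(v^2), 0))
    }
  } else {
    Kms <- spec_kernel_matrix(spec, hyp, model$Z, Xs)      # M x P
    t1 <- backsolve(cache$L, Kms, transpose = TRUE)
    t2 <- backsolve(cache$LB, t1, transpose = TRUE)
    mean <- drop(crossprod(t2, cache$cvec))
    if (full_cov) {
      cov <- spec_kernel_matrix(spec, hyp, Xs) - crossprod(t1) + crossprod(t2)
      list(mean = mean, cov = cov)
    } else {
      list(mean = mean,
           var = pmax(prior_var - colSums(t1^2) + colSums(t2^2), 0))
    }
  }
}

#' Posterior prediction with credible bands
#'
#' Evaluates the posterior of the latent (noise-free) function on a grid and
#' returns its mean, the latent variance, the noisy variance (latent plus
#' observation-noise variance), and `mean +/- z * sd` credible bands for
#' both. The latent variance excludes the additive observation-noise term;
#' the two differ by exactly `noise_sd^2` at every grid point.
#'
#' @param object A `fitted_gp`.
#' @param newdata Prediction inputs: numeric vector of times (original,
#'   unwarped time; any warp or encoding stored in the model is applied
#'   internally), or a data.frame of raw predictors for encoded models.
#' @param z Credible-band half-width in posterior standard deviations
#'   (default 3).
#' @param ... Unused.
#' @return A data.frame of class `gp_posterior` with columns `mean`,
#'   `latent_var`, `noisy_var`, `latent_lower/upper`, `noisy_lower/upper`
#'   (and `time` for time-only models).
#' @export
predict.fitted_gp <- function(object, newdata, z = 3, ...) {
  stopifnot(z > 0)
  Xs <- new_predictors(object, newdata)
  post <- posterior_raw(object, Xs)
  mean <- post$mean + object$center
  latent_var <- post$var
  noisy_var <- latent_var + object$hyp$noise_sd^2
  out <- data.frame(
    mean = mean, latent_var = latent_var, noisy_var = noisy_var,
    latent_lower = mean - z * sqrt(latent_var),
    latent_upper = mean + z * sqrt(latent_var),
    noisy_lower = mean - z * sqrt(noisy_var),
    noisy_upper = mean + z * sqrt(noisy_var))
  if (is.null(object$encoding)) {
    tt <- if (is.data.frame(newdata)) newdata$time else as.numeric(newdata)
    out <- cbind(data.frame(time = tt), out)
  }
  attr(out, "z") <- z
  class(out) <- c("gp_posterior", "data.frame")
  out
}

#' Draw joint samples from the latent posterior
#'
#' Draws sample paths from the joint latent (noise-free) posterior on a
#' grid, via a Cholesky factor of the posterior covariance with escalating
#' numerical jitter (1e-8 up to 1e-4 of the mean diagonal) if needed.
#'
#' @param model A `fitted_gp`.
#' @param newdata Prediction inputs as in [predict.fitted_gp()].
#' @param n_samples Number of sample paths.
#' @param seed Optional integer seed; the same seed reproduces the draws.
#' @return Matrix of dimension `n_samples` by `length(grid)`.
#' @export
draw_posterior_samples <- function(model, newdata, n_samples = 5, seed = NULL) {
  stopifnot(inherits(model, "fitted_gp"), n_samples >= 1)
  if (!is.null(seed)) set.seed(seed)
  Xs <- new_predictors(model, newdata)
  post <- posterior_raw(model, Xs, full_cov = TRUE)
  R <- chol_safe(post$cov + diag(1e-12, nrow(post$cov)))
  Zn <- matrix(stats::rnorm(n_samples * nrow(Xs)), nrow(Xs), n_samples)
  sweep(t(crossprod(R, Zn)), 2, post$mean + model$center, "+")
}

#' Replace a fitted model's hyperparameters
#'
#' Returns the model with the given hyperparameters and a rebuilt posterior
#' cache, leaving the training inputs untouched. Useful for
#' fixed-hyperparameter analyses, e.g. comparing the latent-uncertainty
#' maps of two experimental designs under one shared kernel (given the
#' kernel, the latent variance depends only on the input locations).
#'
#' @param model A `fitted_gp`.
#' @param hyp Hyperparameters shaped like `model$hyp` (per-effect
#'   lengthscale/signal sd, plus `noise_sd`).
#' @return The modified `fitted_gp`.
#' @export
set_gp_hyperparams <- function(model, hyp) {
  stopifnot(inherits(model, "fitted_gp"))
  stopifnot(length(hyp$effects) == length(model$hyp$effects))
  model$hyp <- hyp
  model$objective <- NA_real_
  model$cache <- build_gp_cache(model)
  model
}

#' Export a posterior estimate to CSV
#'
#' Writes the prediction grid, posterior mean and the latent and noisy
#' standard deviations with columns `(x, mean, latent_sd, noisy_sd)`.
#'
#' @param post A `gp_posterior` from [predict.fitted_gp()].
#' @param path Output file path.
#' @export
export_posterior_csv <- function(post, path) {
  x <- if ("time" %in% names(post)) post$time else seq_len(nrow(post))
  utils::write.csv(data.frame(x = x, mean = post$mean,
                              latent_sd = sqrt(post$latent_var),
                              noisy_sd = sqrt(post$noisy_var)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Plot a posterior estimate
#'
#' @param x A `gp_posterior` with a `time` column.
#' @param obs Optional `obs_set` overlaid as points.
#' @param ... Passed to [plot()].
#' @export
plot.gp_posterior <- function(x, obs = NULL, ...) {
  if (!"time" %in% names(x)) stop("plotting requires a time-only posterior")
  ylim <- range(x$noisy_lower, x$noisy_upper, if (!is.null(obs)) obs$values)
  plot(x$time, x$mean, type = "n", xlab = "time (s)", ylab = "activity (a.u.)",
       ylim = ylim, ...)
  graphics::polygon(c(x$time, rev(x$time)), c(x$noisy_lower, rev(x$noisy_upper)),
                    col = "grey90", border = NA)
  graphics::polygon(c(x$time, rev(x$time)),
                    c(x$latent_lower, rev(x$latent_upper)),
                    col = "grey75", border = NA)
  if (!is.null(obs)) graphics::points(obs$times, obs$values, pch = 16,
                                      cex = 0.3, col = "steelblue")
  graphics::lines(x$time, x$mean, lwd = 1.5)
  invisible(x)
}
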