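# Monotone time warping from windowed stimulus autocorrelation.
#
# A stationary RBF kernel cannot track a chirp-driven response whose
# autocorrelation shortens as the stimulus accelerates. The warp stretches
# time where the stimulus decorrelates quickly (short local lengthscale) and
# compresses it where the stimulus is slow, so that in warped time the
# stimulus - and, by assumption, the response - is approximately stationary.

#' Estimate local stimulus lengthscales from windowed autocorrelation
#'
#' Slides a window over a regularly sampled stimulus trace, computes the
#' empirical autocorrelation of each (mean-removed) window and fits a
#' Gaussian curve `A * exp(-(x - mu)^2 / (2 l^2))` to it by least squares,
#' retaining the lengthscale `l` per window. Windows with (near-)zero
#' variance have no defined autocorrelation; their lengthscale is set to the
#' maximum over the other windows and flagged.
#'
#' @param stimulus Data.frame with columns `time` and `value`, regularly
#'   sampled at at least twice the highest stimulus frequency.
#' @param window Window width in seconds (default 0.5).
#' @param spacing Window spacing in seconds (default 1/16).
#' @return A data.frame of class `autocorr_fits` with columns
#'   `window_center`, `lengthscale`, `amplitude`, `offset`, `flagged`, and
#'   attributes `spacing`, `window`, `t0`.
#' @export
estimate_local_lengthscales <- function(stimulus, window = 0.5,
                                        spacing = 1 / 16) {
  stopifnot(is.data.frame(stimulus), all(c("time", "value") %in%
                                           names(stimulus)))
  if (window <= spacing) stop("window must exceed spacing")
  tt <- stimulus$time; vv <- stimulus$value
  dt <- stats::median(diff(tt))
  if (dt <= 0 || stats::sd(diff(tt)) > 1e-6 * dt + 1e-12)
    stop("stimulus must be regularly sampled")
  t0 <- tt[1]
  duration <- length(tt) * dt
  n_win <- floor(duration / spacing + 1e-9)
  centers <- t0 + (seq_len(n_win) - 1L) * spacing
  half <- max(2L, round(window / (2 * dt)))   # half-window in samples
  max_lag <- half

  fit_one <- function(ctr) {
    ci <- round((ctr - t0) / dt) + 1L
    idx <- max(1L, ci - half):min(length(tt), ci + half)
    x <- vv[idx]
    if (length(x) < 8L || stats::sd(x) < 1e-10)
      return(c(NA_real_, NA_real_, NA_real_))
    ac <- stats::acf(x, lag.max = min(max_lag, length(x) - 2L),
                     plot = FALSE, demean = TRUE)$acf[, 1, 1]
    lag_s <- (seq_along(ac) - 1L) * dt
    # A is bounded near 1 (the autocorrelation at lag 0) and several l
    # starts guard against local minima of the oscillatory residual
    best <- NULL
    for (l0 in window / c(32, 8, 4)) {
      fit <- tryCatch(minpack.lm::nls.lm(
        par = list(A = 1, mu = 0, l = l0),
        fn = function(p) ac - p$A * exp(-(lag_s - p$mu)^2 / (2 * p$l^2)),
        lower = c(A = 0.2, mu = -window / 8, l = dt / 2),
        upper = c(A = 2, mu = window / 8, l = 10 * window),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$info %in% 1:4) next
      rss <- sum(fit$fvec^2)
      if (is.null(best) || rss < best$rss)
        best <- list(rss = rss, par = fit$par)
    }
    if (is.null(best)) return(c(NA_real_, NA_real_, NA_real_))
    c(best$par$l, best$par$A, best$par$mu)
  }

  res <- t(vapply(centers, fit_one, numeric(3)))
  flagged <- !is.finite(res[, 1])
  if (all(flagged)) stop("no window produced a valid autocorrelation fit")
  res[flagged, 1] <- max(res[!flagged, 1])
  out <- data.frame(window_center = centers, lengthscale = res[, 1],
                    amplitude = res[, 2], offset = res[, 3],
                    flagged = flagged)
  attr(out, "spacing") <- spacing
  attr(out, "window") <- window
  attr(out, "t0") <- t0
  class(out) <- c("autocorr_fits", "data.frame")
  out
}

#' Build a monotone time warp from windowed lengthscales
#'
#' Accumulates the inverse local lengthscale over the window sequence: the
#' warped coordinate of knot `k` is `sum_{j <= k} spacing / l_j`, so time
#' intervals where the stimulus decorrelates quickly are stretched. The
#' alternative accumulation of `spacing / (2 l_j^2)` is available via
#' `variant = "inv_sq"`. Evaluation is piecewise linear with linear
#' extrapolation of the terminal segments; the inverse map uses inverse
#' interpolation.
#'
#' @param fits An `autocorr_fits` data.frame from
#'   [estimate_local_lengthscales()].
#' @param normalize If `TRUE` (default), rescale so the total warped
#'   duration equals the original duration.
#' @param variant `"inverse"` (default, cumulative `1/l`) or `"inv_sq"`
#'   (cumulative `1/(2 l^2)`).
#' @return An object of class `warp_fun` with fields `knot_times` and
#'   `warped_values` (strictly increasing).
#' @export
build_time_warp <- function(fits, normalize = TRUE,
                            variant = c("inverse", "inv_sq")) {
  variant <- match.arg(variant)
  stopifnot(nrow(fits) >= 2L)
  l <- fits$lengthscale
  if (any(!is.finite(l))) stop("non-finite lengthscale in window fits")
  if (any(l <= 0)) stop("lengthscales must be strictly positive")
  spacing <- attr(fits, "spacing")
  t0 <- attr(fits, "t0")
  if (is.null(spacing)) spacing <- stats::median(diff(fits$window_center))
  if (is.null(t0)) t0 <- fits$window_center[1]
  rate <- switch(variant, inverse = 1 / l, inv_sq = 1 / (2 * l^2))
  knots <- c(t0, fits$window_center + spacing)
  w <- c(0, cumsum(rate * spacing))
  duration <- knots[length(knots)] - knots[1]
  if (normalize) w <- w * duration / w[length(w)]
  structure(list(knot_times = knots, warped_values = w,
                 variant = variant, normalized = normalize),
            class = "warp_fun")
}

# piecewise-linear evaluation with linear extrapolation of terminal segments
pl_interp <- function(x, y, xout) {
  n <- length(x)
  out <- stats::approx(x, y, xout, rule = 2)$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    s <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + s * (xout[lo] - x[1])
  }
  if (any(hi)) {
    s <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + s * (xout[hi] - x[n])
  }
  out
}

#' Apply a time warp
#'
#' @param warp A `warp_fun`.
#' @param t Times in the original base (seconds).
#' @return Warped times.
#' @export
warp_forward <- function(warp, t) {
  stopifnot(inherits(warp, "warp_fun"))
  pl_interp(warp$knot_times, warp$warped_values, as.numeric(t))
}

#' Invert a time warp
#'
#' @param warp A `warp_fun`.
#' @param w Warped times.
#' @return Times in the original base.
#' @export
warp_inverse <- function(warp, w) {
  stopifnot(inherits(warp, "warp_fun"))
  pl_interp(warp$warped_values, warp$knot_times, as.numeric(w))
}

#' Build a warp directly from a stimulus trace
#'
#' Convenience wrapper chaining [estimate_local_lengthscales()] and
#' [build_time_warp()]. The warp is computed once per stimulus (the response
#' autocorrelation is assumed approximately equal to the stimulus
#' autocorrelation), not per ROI.
#'
#' @inheritParams estimate_local_lengthscales
#' @inheritParams build_time_warp
#' @return A `warp_fun`.
#' @export
stimulus_time_warp <- function(stimulus, window = 0.5, spacing = 1 / 16,
                               normalize = TRUE,
                               variant = c("inverse", "inv_sq")) {
  fits <- estimate_local_lengthscales(stimulus, window, spacing)
  build_time_warp(fits, normalize = normalize, variant = variant)
}

#' @export
print.warp_fun <- function(x, ...) {
  n <- length(x$knot_times)
  cat("<warp_fun>", n - 1L, "segments over [",
      sprintf("%.3f", x$knot_times[1]), ",",
      sprintf("%.3f", x$knot_times[n]), ") s, variant:", x$variant, "\n")
  invisible(x)
}

#' Export a warp (with its window lengthscales) to CSV
#'
#' @param fits An `autocorr_fits` data.frame.
#' @param warp The `warp_fun` built from `fits`.
#' @param path Output file path; columns `(time, lengthscale, warped_time)`.
#' @export
export_warp_csv <- function(fits, warp, path) {
  utils::write.csv(data.frame(time = fits$window_center,
                              lengthscale = fits$lengthscale,
                              warped_time = warp_forward(warp,
                                                         fits$window_center)),
                   path, row.names = FALSE)
  invisible(path)
}
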