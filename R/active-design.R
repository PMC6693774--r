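# Blue-noise stimulus-parameter sampling, latent-uncertainty maps over
# (frequency, contrast), and peak-based batch selection for closed-loop
# experiments.

#' Stimulus parameter space
#'
#' Bounds and exclusion thresholds of the (frequency, contrast) space, plus
#' the default map grid resolution. Distances are always computed on axes
#' rescaled to `[0, 1]` since the units are incommensurate.
#'
#' @param frequency Frequency bounds in Hz (default `c(1, 8)`).
#' @param contrast Contrast bounds in percent (default `c(10, 100)`).
#' @param min_frequency,min_contrast Exclusion thresholds (defaults 1 Hz
#'   and 10%).
#' @param resolution Map grid resolution per axis (default 64).
#' @return A `parameter_space` object.
#' @export
parameter_space <- function(frequency = c(1, 8), contrast = c(10, 100),
                            min_frequency = 1, min_contrast = 10,
                            resolution = 64) {
  stopifnot(all(is.finite(c(frequency, contrast))),
            frequency[1] < frequency[2], contrast[1] < contrast[2],
            resolution >= 4)
  structure(list(frequency = frequency, contrast = contrast,
                 min_frequency = min_frequency, min_contrast = min_contrast,
                 resolution = resolution), class = "parameter_space")
}

# rescale parameters to [0,1]^2
space_rescale <- function(space, freq, contrast) {
  cbind((freq - space$frequency[1]) / diff(space$frequency),
        (contrast - space$contrast[1]) / diff(space$contrast))
}

#' Blue-noise (Poisson-disk) sampling of stimulus parameters
#'
#' Dart-throwing rejection sampling on the rescaled unit square: uniform
#' proposals are rejected if they fall below the exclusion thresholds or
#' within `min_dist` (rescaled units) of an already accepted point, until
#' exactly `n` points are accepted.
#'
#' @param space A [parameter_space()].
#' @param n Number of parameters (default 150).
#' @param min_dist Minimum pairwise rescaled distance; default
#'   `0.7 * sqrt(1/n)` (Poisson-disk heuristic).
#' @param seed Optional integer seed.
#' @param max_attempts Proposal cap (default `5000 * n`); exceeding it
#'   raises an error advising a smaller `min_dist`.
#' @return Data.frame with columns `frequency` (Hz), `contrast` (percent).
#' @export
blue_noise_parameters <- function(space = parameter_space(), n = 150,
                                  min_dist = NULL, seed = NULL,
                                  max_attempts = 5000 * n) {
  stopifnot(n >= 1)
  if (is.null(min_dist)) min_dist <- 0.7 * sqrt(1 / n)
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(NA_real_, n, 2)
  accepted <- 0L
  attempts <- 0L
  while (accepted < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("could not place ", n, " points at min_dist = ",
           signif(min_dist, 3), "; use a smaller min_dist")
    f <- stats::runif(1, space$frequency[1], space$frequency[2])
    cc <- stats::runif(1, space$contrast[1], space$contrast[2])
    if (f < space$min_frequency || cc < space$min_contrast) next
    p <- space_rescale(space, f, cc)
    if (accepted > 0L) {
      d2 <- (pts[seq_len(accepted), 1] - p[1])^2 +
        (pts[seq_len(accepted), 2] - p[2])^2
      if (min(d2) < min_dist^2) next
    }
    accepted <- accepted + 1L
    pts[accepted, ] <- p
  }
  data.frame(frequency = space$frequency[1] + pts[, 1] * diff(space$frequency),
             contrast = space$contrast[1] + pts[, 2] * diff(space$contrast))
}

#' Latent-uncertainty map over the parameter space
#'
#' For every (frequency, contrast) cell of the map grid, builds the encoded
#' predictor rows of one trial's time grid under those parameters and sums
#' the latent posterior variance of the model, giving a 2-D map of how
#' uncertain the model still is about the response at each parameter
#' combination.
#'
#' @param model A `fitted_gp` fitted with a phase/frequency/contrast
#'   encoding (see [encode_predictors()]).
#' @param space A [parameter_space()].
#' @param time_grid Within-trial time points (default 16 points over 1 s).
#' @param resolution Map grid resolution (default from `space`).
#' @return Object of class `uncertainty_map`: `value` (resolution x
#'   resolution matrix, rows indexing frequency, columns contrast),
#'   `frequency`, `contrast` (axis vectors), `space`.
#' @export
latent_uncertainty_map <- function(model, space = parameter_space(),
                                   time_grid = seq(0, 1, length.out = 16),
                                   resolution = space$resolution) {
  stopifnot(inherits(model, "fitted_gp"))
  if (is.null(model$encoding))
    stop("model has no predictor encoding; fit with encode_predictors()")
  fr <- seq(space$frequency[1], space$frequency[2], length.out = resolution)
  co <- seq(space$contrast[1], space$contrast[2], length.out = resolution)
  nt <- length(time_grid)
  val <- matrix(NA_real_, resolution, resolution)
  # evaluate one frequency-row of cells at a time (resolution * nt rows)
  for (i in seq_len(resolution)) {
    newdata <- data.frame(
      trial_time = rep(time_grid, times = resolution),
      time = rep(time_grid, times = resolution),
      frequency = fr[i],
      contrast = rep(co, each = nt))
    Xs <- encoding_matrix(model$encoding, newdata, model$warp)
    v <- posterior_raw(model, Xs)$var
    val[i, ] <- colSums(matrix(v, nrow = nt))
  }
  structure(list(value = val, frequency = fr, contrast = co, space = space,
                 time_grid = time_grid), class = "uncertainty_map")
}

#' @export
print.uncertainty_map <- function(x, ...) {
  cat("<uncertainty_map>", nrow(x$value), "x", ncol(x$value),
      "cells; total latent variance", sprintf("%.4g", sum(x$value)), "\n")
  invisible(x)
}

#' Select the next stimulus batch from an uncertainty map
#'
#' Finds local maxima of the map with a maximum-filter neighbourhood of
#' Chebyshev radius `min_peak_dist` cells, ranks them by map value (ties
#' broken by row-major grid order) and returns the top `batch_size`. If
#' fewer peaks exist, the batch is filled with the highest-value cells that
#' keep `min_peak_dist` from all already chosen points. With
#' `include_boundary = FALSE` (default) cells within `min_peak_dist` of the
#' map edge are not eligible as peaks, reproducing the edge bias of plain
#' peak finding; `TRUE` uses a reflect-padded filter so boundary cells can
#' be selected.
#'
#' @param map An `uncertainty_map`.
#' @param batch_size Number of parameters to select (default 30).
#' @param min_peak_dist Minimum peak separation in cells (default 3).
#' @param include_boundary Allow peaks on the map boundary (default FALSE).
#' @return Data.frame with columns `frequency`, `contrast`, `value`,
#'   `is_peak`.
#' @export
select_next_batch <- function(map, batch_size = 30, min_peak_dist = 3,
                              include_boundary = FALSE) {
  stopifnot(inherits(map, "uncertainty_map"))
  if (batch_size <= 0) stop("batch_size must be positive")
  V <- map$value
  if (any(!is.finite(V))) stop("uncertainty map contains non-finite values")
  nr <- nrow(V); nc <- ncol(V); r <- min_peak_dist
  nbhd_max <- matrix(-Inf, nr, nc)
  for (di in -r:r) for (dj in -r:r) {
    if (di == 0 && dj == 0) next
    ri <- pmin(pmax(seq_len(nr) + di, 1L), nr)
    cj <- pmin(pmax(seq_len(nc) + dj, 1L), nc)
    nbhd_max <- pmax(nbhd_max, V[ri, cj])
  }
  # >= admits plateau cells; the separation filter below keeps only the
  # first of any tied neighbours (row-major order)
  is_peak <- V >= nbhd_max
  if (!include_boundary) {
    is_peak[c(seq_len(r), nr - seq_len(r) + 1L), ] <- FALSE
    is_peak[, c(seq_len(r), nc - seq_len(r) + 1L)] <- FALSE
  }
  cells <- data.frame(i = rep(seq_len(nr), nc), j = rep(seq_len(nc), each = nr),
                      value = as.vector(V), peak = as.vector(is_peak))
  # rank: peaks first by value, then non-peak cells by value; row-major ties
  cells <- cells[order(-cells$peak, -cells$value, cells$i, cells$j), ]
  chosen <- matrix(NA_real_, 0, 2)
  out <- cells[0, ]
  for (k in seq_len(nrow(cells))) {
    if (nrow(out) == batch_size) break
    ck <- cells[k, ]
    if (nrow(chosen)) {
      dd <- pmax(abs(chosen[, 1] - ck$i), abs(chosen[, 2] - ck$j))
      if (min(dd) < min_peak_dist) next
    }
    chosen <- rbind(chosen, c(ck$i, ck$j))
    out <- rbind(out, ck)
  }
  data.frame(frequency = map$frequency[out$i], contrast = map$contrast[out$j],
             value = out$value, is_peak = out$peak)
}

#' Initialise a closed-loop design state
#'
#' @param space A [parameter_space()].
#' @param effects Accepted effect set (kernel structure retained across
#'   rounds), e.g. from [forward_select_effects()].
#' @param batch_size Batch size per round (default 30).
#' @return A `design_state` object with no observations yet.
#' @export
design_state <- function(space = parameter_space(),
                         effects = candidate_effects("sine")[
                           c("phase", "frequency:contrast")],
                         batch_size = 30) {
  structure(list(space = space, effects = effects, batch_size = batch_size,
                 params = data.frame(round = integer(0),
                                     frequency = numeric(0),
                                     contrast = numeric(0)),
                 observations = NULL, model = NULL, map = NULL,
                 next_batch = NULL, round = 0L), class = "design_state")
}

#' One round of closed-loop active design
#'
#' Appends the new observations (tagged with their stimulus parameters),
#' refits the model retaining the kernel structure selected previously,
#' recomputes the latent-uncertainty map and selects the next parameter
#' batch at the map's uncertainty peaks.
#'
#' @param state A [design_state()].
#' @param new_obs An [obs_set()] whose `stim` includes `frequency`,
#'   `contrast` and `trial_time` per observation.
#' @param params Data.frame of the parameter sets presented this round.
#' @param config [fit_config()] for the refit.
#' @param time_grid,resolution Map settings (see
#'   [latent_uncertainty_map()]).
#' @param min_peak_dist,include_boundary Batch-selection settings.
#' @param seed Optional integer seed for the refit.
#' @return The updated `design_state` (fields `model`, `map`, `next_batch`,
#'   `round` advanced).
#' @export
closed_loop_step <- function(state, new_obs, params, config = fit_config(),
                             time_grid = seq(0, 1, length.out = 16),
                             resolution = state$space$resolution,
                             min_peak_dist = 3, include_boundary = FALSE,
                             seed = NULL) {
  stopifnot(inherits(state, "design_state"), inherits(new_obs, "obs_set"))
  if (is.null(new_obs$stim) ||
      !all(c("frequency", "contrast") %in% names(new_obs$stim)))
    stop("new observations must be tagged with frequency and contrast")
  state$round <- state$round + 1L
  state$params <- rbind(state$params,
                        cbind(round = state$round, as.data.frame(params)))
  state$observations <- if (is.null(state$observations)) new_obs else
    pool_observations(state$observations, new_obs)
  encoding <- encode_predictors(state$observations, state$effects)
  state$model <- fit_gp(state$observations,
                        kernel = compose_effect_kernel(state$effects),
                        config = config, encoding = encoding, seed = seed)
  state$map <- latent_uncertainty_map(state$model, state$space,
                                      time_grid = time_grid,
                                      resolution = resolution)
  state$next_batch <- select_next_batch(state$map, state$batch_size,
                                        min_peak_dist = min_peak_dist,
                                        include_boundary = include_boundary)
  state
}

#' @export
print.design_state <- function(x, ...) {
  cat("<design_state> round", x$round, "-", nrow(x$params),
      "parameters observed\n")
  if (!is.null(x$map))
    cat("  total map uncertainty:", sprintf("%.4g", sum(x$map$value)), "\n")
  invisible(x)
}

#' Export an uncertainty map with its axis coordinates
#'
#' Writes the map matrix and the frequency/contrast axis vectors as a
#' single JSON document (full-precision doubles).
#'
#' @param map An `uncertainty_map`.
#' @param path Output file path.
#' @export
export_map_json <- function(map, path) {
  stopifnot(inherits(map, "uncertainty_map"))
  jsonlite::write_json(list(frequency = map$frequency,
                            contrast = map$contrast,
                            value = map$value), path, digits = NA,
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Export a parameter batch to CSV
#'
#' @param state A `design_state` (its accumulated parameters and next
#'   batch) or a plain batch data.frame.
#' @param path Output file path; columns
#'   `(round, frequency_hz, contrast_percent)`.
#' @export
export_batch_csv <- function(state, path) {
  df <- if (inherits(state, "design_state")) {
    nb <- state$next_batch
    rbind(data.frame(round = state$params$round,
                     frequency_hz = state$params$frequency,
                     contrast_percent = state$params$contrast),
          if (!is.null(nb)) data.frame(round = state$round + 1L,
                                       frequency_hz = nb$frequency,
                                       contrast_percent = nb$contrast))
  } else data.frame(round = 1L, frequency_hz = state$frequency,
                    contrast_percent = state$contrast)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
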