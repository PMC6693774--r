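# Synthetic stimuli, scan-geometry sampling times and simulated ROI
# responses. These generators define the study conditions the rest of the
# package is exercised under: a 32 s chirp, 1 s sine trials with frequency
# and contrast parameters, a moving bar over 8 directions, spiral and linear
# scan sampling, and neurons with ~100 ms indicator decay and additive
# Gaussian observation noise.

#' Stimulus protocol definitions
#'
#' `chirp_protocol()` describes a full-field chirp: 2 s baseline, 3 s ON
#' step, 3 s OFF, an 8 s frequency sweep (0.5 to 8 Hz at full contrast), a
#' 2 s pause, an 8 s contrast sweep (0 to 100% at 2 Hz) and 6 s baseline,
#' totalling 32 s per repeat. `sine_protocol()` is a sequence of 1 s trials
#' with fixed (frequency, contrast) per trial. `bar_protocol()` is a moving
#' bar along evenly spaced directions.
#'
#' @param repeats Number of stimulus repeats (chirp default 4; bar default 3
#'   per direction).
#' @param params Data.frame with columns `frequency` (Hz, in `[1, 8]`) and
#'   `contrast` (percent, in `[10, 100]`), one row per sine trial.
#' @param trial_duration Trial length in seconds (sine default 1, bar
#'   default 4).
#' @param directions Bar directions in degrees (default 8 evenly spaced).
#' @return A `stimulus_protocol` object.
#' @name stimulus_protocols
NULL

#' @rdname stimulus_protocols
#' @export
chirp_protocol <- function(repeats = 4) {
  segments <- data.frame(
    kind = c("baseline", "on", "off", "freq_sweep", "pause", "contrast_sweep",
             "baseline2"),
    duration = c(2, 3, 3, 8, 2, 8, 6))
  structure(list(kind = "chirp", repeats = repeats, segments = segments,
                 duration = sum(segments$duration),
                 f_lo = 0.5, f_hi = 8, sweep_freq = 2),
            class = "stimulus_protocol")
}

#' @rdname stimulus_protocols
#' @export
sine_protocol <- function(params, trial_duration = 1) {
  params <- as.data.frame(params)
  stopifnot(all(c("frequency", "contrast") %in% names(params)))
  if (any(params$frequency < 1 | params$frequency > 8))
    stop("sine frequencies must lie in [1, 8] Hz")
  if (any(params$contrast < 10 | params$contrast > 100))
    stop("sine contrasts must lie in [10, 100] %")
  structure(list(kind = "sine", params = params,
                 trial_duration = trial_duration,
                 duration = nrow(params) * trial_duration),
            class = "stimulus_protocol")
}

#' @rdname stimulus_protocols
#' @export
bar_protocol <- function(directions = seq(0, 315, by = 45), repeats = 3,
                         trial_duration = 4) {
  stopifnot(length(directions) >= 1L, trial_duration > 0)
  structure(list(kind = "moving_bar", directions = directions,
                 repeats = repeats, trial_duration = trial_duration,
                 duration = length(directions) * repeats * trial_duration),
            class = "stimulus_protocol")
}

#' Generate a regularly sampled stimulus trace
#'
#' Renders a protocol as an intensity trace in `[0, 1]` with a per-sample
#' parameter timeline (instantaneous frequency, contrast and direction where
#' applicable), one repeat.
#'
#' @param protocol A `stimulus_protocol`.
#' @param sample_rate Samples per second (default 128; must be at least
#'   twice the highest stimulus frequency).
#' @return Data.frame with columns `time`, `value`, `frequency`, `contrast`,
#'   `direction`, `trial_id`, `trial_time`; attribute `protocol`.
#' @export
generate_stimulus <- function(protocol, sample_rate = 128) {
  stopifnot(inherits(protocol, "stimulus_protocol"), sample_rate >= 16)
  dt <- 1 / sample_rate
  tt <- seq(0, protocol$duration - dt, by = dt)
  n <- length(tt)
  val <- numeric(n); freq <- rep(NA_real_, n); con <- rep(NA_real_, n)
  dir <- rep(NA_real_, n); trial <- rep(1L, n); ttrial <- tt

  if (protocol$kind == "chirp") {
    seg <- protocol$segments
    edges <- cumsum(c(0, seg$duration))
    for (i in seq_len(nrow(seg))) {
      idx <- which(tt >= edges[i] & tt < edges[i + 1])
      ts <- tt[idx] - edges[i]
      val[idx] <- switch(seg$kind[i],
        baseline = , baseline2 = 0.5,
        on = 1, off = 0,
        freq_sweep = {
          # linear sweep f_lo -> f_hi; phase is the integral of f(t)
          f0 <- protocol$f_lo; f1 <- protocol$f_hi; Td <- seg$duration[i]
          finst <- f0 + (f1 - f0) * ts / Td
          freq[idx] <- finst
          con[idx] <- 100
          phase <- 2 * pi * (f0 * ts + (f1 - f0) * ts^2 / (2 * Td))
          0.5 + 0.5 * sin(phase)
        },
        pause = 0.5,
        contrast_sweep = {
          Td <- seg$duration[i]
          freq[idx] <- protocol$sweep_freq
          con[idx] <- 100 * ts / Td
          0.5 + 0.5 * (ts / Td) * sin(2 * pi * protocol$sweep_freq * ts)
        })
    }
  } else if (protocol$kind == "sine") {
    Td <- protocol$trial_duration
    trial <- pmin(floor(tt / Td) + 1L, nrow(protocol$params))
    ttrial <- tt - (trial - 1L) * Td
    freq <- protocol$params$frequency[trial]
    con <- protocol$params$contrast[trial]
    val <- 0.5 + 0.5 * (con / 100) * sin(2 * pi * freq * ttrial)
  } else if (protocol$kind == "moving_bar") {
    Td <- protocol$trial_duration
    dirs <- rep(protocol$directions, times = protocol$repeats)
    trial <- pmin(floor(tt / Td) + 1L, length(dirs))
    ttrial <- tt - (trial - 1L) * Td
    dir <- dirs[trial]
    # full-field intensity proxy: bar sweeps through the field mid-trial
    val <- exp(-(ttrial - Td / 2)^2 / (2 * 0.5^2))
  } else stop("unknown protocol kind: ", protocol$kind)

  out <- data.frame(time = tt, value = val, frequency = freq, contrast = con,
                    direction = dir, trial_id = as.integer(trial),
                    trial_time = ttrial)
  attr(out, "protocol") <- protocol
  attr(out, "sample_rate") <- sample_rate
  out
}

#' Scan configuration and ROI masks
#'
#' `scan_config()` describes a two-photon scan trajectory: a linear raster
#' (default 32 lines at 15.625 Hz) or a spiral grid of rotated Archimedean
#' arcs `r = theta^(1/a)` (default 16 arcs at 31.25 Hz, tightness `a = 2`),
#' each arc traversed at constant speed. `roi_mask_disc()` builds a disc-
#' shaped ROI mask on the scan grid.
#'
#' @param mode `"linear"` or `"spiral"`.
#' @param lines Raster line count (linear mode).
#' @param arcs Spiral arc count per frame (spiral mode).
#' @param frame_rate Frames per second.
#' @param tightness Spiral tightness `a`.
#' @param grid Scan grid resolution (cells per side).
#' @return A `scan_config` object.
#' @export
scan_config <- function(mode = c("spiral", "linear"), lines = 32, arcs = 16,
                        frame_rate = NULL, tightness = 2, grid = 32) {
  mode <- match.arg(mode)
  if (is.null(frame_rate)) frame_rate <- if (mode == "spiral") 31.25 else 15.625
  stopifnot(frame_rate > 0, lines >= 1, arcs >= 1)
  structure(list(mode = mode, lines = lines, arcs = arcs,
                 frame_rate = frame_rate, tightness = tightness, grid = grid),
            class = "scan_config")
}

#' @rdname scan_config
#' @param center Disc centre in `[0, 1]^2` field coordinates.
#' @param radius Disc radius in field units.
#' @export
roi_mask_disc <- function(grid = 32, center = c(0.5, 0.5), radius = 0.08) {
  cx <- (seq_len(grid) - 0.5) / grid
  outer(cx, cx, function(x, y) (x - center[1])^2 + (y - center[2])^2 <=
          radius^2)
}

# base spiral arc positions in [0,1]^2 field coords, constant arc length;
# returns a function of rotation angle giving n_pts positions
spiral_arc_points <- function(tightness, n_pts = 400) {
  th_max <- pi * 6
  th <- seq(1e-3, th_max, length.out = 4000)
  r <- th^(1 / tightness)
  r <- r / max(r) * 0.5
  x <- r * cos(th); y <- r * sin(th)
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  su <- seq(0, s[length(s)], length.out = n_pts)
  list(x = stats::approx(s, x, su)$y, y = stats::approx(s, y, su)$y)
}

#' Sampling times of an ROI under a scan trajectory
#'
#' Computes, per frame, the times at which the scan trajectory intersects
#' the ROI mask, concatenated over frames. For a linear raster, one sample
#' is produced per mask-covering line per frame (at the time the line
#' crosses the mask centroid). For a spiral, each of the rotated arcs is
#' traversed at constant speed within its share of the frame period and
#' every contiguous run of trajectory points inside the mask yields one
#' sample at the run's mean time.
#'
#' @param scan A [scan_config()].
#' @param roi_mask Logical matrix of size `grid` by `grid` (rows are y
#'   cells, columns x cells) marking the ROI.
#' @param n_frames Number of frames to simulate.
#' @return Strictly increasing numeric vector of sample times (seconds).
#' @export
scan_sampling_times <- function(scan, roi_mask, n_frames) {
  stopifnot(inherits(scan, "scan_config"), n_frames >= 1)
  g <- scan$grid
  if (!is.matrix(roi_mask) || nrow(roi_mask) != g || ncol(roi_mask) != g)
    stop("roi_mask must be a ", g, "x", g, " logical matrix on the scan field")
  if (!any(roi_mask)) stop("roi_mask is empty")
  Tf <- 1 / scan$frame_rate
  if (scan$mode == "linear") {
    rows <- which(apply(roi_mask, 1, any))
    line_dt <- Tf / scan$lines
    # map mask rows onto scan lines (grid rows == lines when sizes match)
    lines_hit <- unique(ceiling(rows / g * scan$lines))
    col_frac <- vapply(lines_hit, function(li) {
      r <- rows[ceiling(rows / g * scan$lines) == li]
      mean(which(apply(roi_mask[r, , drop = FALSE], 2, any))) / g
    }, numeric(1))
    per_frame <- sort((lines_hit - 1) * line_dt + col_frac * line_dt)
    times <- as.vector(outer(per_frame, (seq_len(n_frames) - 1) * Tf, "+"))
  } else {
    arc <- spiral_arc_points(scan$tightness)
    arc_dt <- Tf / scan$arcs
    per_frame <- numeric(0)
    for (k in seq_len(scan$arcs)) {
      ang <- 2 * pi * (k - 1) / scan$arcs
      x <- 0.5 + cos(ang) * arc$x - sin(ang) * arc$y
      y <- 0.5 + sin(ang) * arc$x + cos(ang) * arc$y
      ci <- pmin(pmax(ceiling(x * g), 1L), g)
      ri <- pmin(pmax(ceiling(y * g), 1L), g)
      inside <- roi_mask[cbind(ri, ci)]
      rl <- rle(inside)
      ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
      frac <- (starts[rl$values] + ends[rl$values]) / 2 / length(inside)
      per_frame <- c(per_frame, (k - 1) * arc_dt + frac * arc_dt)
    }
    per_frame <- sort(per_frame)
    times <- as.vector(outer(per_frame, (seq_len(n_frames) - 1) * Tf, "+"))
  }
  times <- sort(times)
  times[c(TRUE, diff(times) > 0)]
}

#' Ground-truth simulated neuron
#'
#' A linear-nonlinear response model with indicator kinetics: the stimulus
#' drive (intensity minus baseline, scaled by frequency/contrast/direction
#' tuning) is filtered with an exponential indicator-decay kernel (time
#' constant ~100 ms for typical calcium/glutamate indicators), passed
#' through a rectifying gain, and observed under additive Gaussian noise.
#'
#' @param tau Indicator decay time constant in seconds (default 0.1).
#' @param gain Output gain.
#' @param threshold Rectification threshold on the filtered drive.
#' @param noise_sd Observation noise standard deviation.
#' @param freq_tuning,contrast_tuning,dir_tuning Optional functions mapping
#'   the respective stimulus parameter to a multiplicative gain (default 1).
#' @param offset_fun Optional function of time added to the latent response
#'   (used by [simulate_population()] to impose cluster structure).
#' @return A `gt_neuron` object.
#' @export
gt_neuron <- function(tau = 0.1, gain = 1, threshold = 0, noise_sd = 0.1,
                      freq_tuning = NULL, contrast_tuning = NULL,
                      dir_tuning = NULL, offset_fun = NULL) {
  stopifnot(tau > 0, noise_sd >= 0)
  structure(list(tau = tau, gain = gain, threshold = threshold,
                 noise_sd = noise_sd, freq_tuning = freq_tuning,
                 contrast_tuning = contrast_tuning, dir_tuning = dir_tuning,
                 offset_fun = offset_fun), class = "gt_neuron")
}

# latent response of a neuron on the stimulus grid
neuron_latent <- function(neuron, stimulus) {
  dt <- stats::median(diff(stimulus$time))
  drive <- stimulus$value - 0.5
  tune <- rep(1, length(drive))
  if (!is.null(neuron$freq_tuning)) {
    f <- stimulus$frequency; f[is.na(f)] <- 0
    tune <- tune * neuron$freq_tuning(f)
  }
  if (!is.null(neuron$contrast_tuning)) {
    cc <- stimulus$contrast; cc[is.na(cc)] <- 0
    tune <- tune * neuron$contrast_tuning(cc)
  }
  if (!is.null(neuron$dir_tuning)) {
    d <- stimulus$direction; d[is.na(d)] <- 0
    tune <- tune * neuron$dir_tuning(d)
  }
  x <- drive * tune
  a <- exp(-dt / neuron$tau)
  filt <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  lat <- neuron$gain * pmax(filt - neuron$threshold, 0)
  if (!is.null(neuron$offset_fun)) lat <- lat + neuron$offset_fun(stimulus$time)
  lat
}

#' Simulate ROI observations from a ground-truth neuron
#'
#' Evaluates the neuron's latent response at the given sample times (by
#' linear interpolation of the response computed on the stimulus grid) and
#' adds Gaussian observation noise. Sample times are interpreted per trial:
#' times beyond one stimulus repeat wrap onto the trial-relative time base,
#' so pooled multi-trial sampling is obtained by passing times spanning
#' several repeats.
#'
#' @param neuron A [gt_neuron()].
#' @param stimulus A stimulus trace from [generate_stimulus()] (one repeat).
#' @param times Sample times in seconds (may span multiple repeats).
#' @param seed Optional integer seed.
#' @param roi_id ROI identifier for the returned set.
#' @return An [obs_set()] with trial-relative times, per-observation
#'   stimulus parameters and trial ids; the noise-free latent values are
#'   attached as attribute `latent`.
#' @export
simulate_roi_observations <- function(neuron, stimulus, times, seed = NULL,
                                      roi_id = "sim") {
  stopifnot(inherits(neuron, "gt_neuron"))
  if (!is.null(seed)) set.seed(seed)
  dur <- attr(stimulus, "protocol")$duration
  if (is.null(dur)) dur <- max(stimulus$time)
  trial <- floor(times / dur) + 1L
  ttimes <- times - (trial - 1L) * dur
  lat_grid <- neuron_latent(neuron, stimulus)
  lat <- stats::approx(stimulus$time, lat_grid, ttimes, rule = 2)$y
  vals <- lat + stats::rnorm(length(lat), 0, neuron$noise_sd)
  interp_par <- function(v) {
    if (all(is.na(v))) return(rep(NA_real_, length(ttimes)))
    stats::approx(stimulus$time, v, ttimes, method = "constant", rule = 2)$y
  }
  stim <- data.frame(
    frequency = interp_par(stimulus$frequency),
    contrast = interp_par(stimulus$contrast),
    direction = interp_par(stimulus$direction),
    trial_time = interp_par(stimulus$trial_time),
    stim_trial = interp_par(stimulus$trial_id))
  out <- obs_set(ttimes, vals, roi_id = roi_id, stim = stim, trial_id = trial)
  attr(out, "latent") <- lat
  out
}

#' Reference two-condition simulation for equality testing
#'
#' Generates the paired observation sets used to calibrate and power-check
#' the EC equality test: both conditions share a smooth 1 Hz sine-driven
#' response over 16 s; the second condition additionally receives a
#' windowed oscillatory offset (amplitude `effect_size * noise_sd`, 1 Hz
#' modulation under a smooth flat-top envelope) inside `window`. With
#' `effect_size = 0` the two conditions are draws from one homogeneous
#' process.
#'
#' @param n_per_condition Observations per condition (irregular uniform
#'   sampling times).
#' @param effect_size Offset amplitude in units of `noise_sd` (default 3;
#'   0 gives the null).
#' @param window Offset window in seconds (default `c(10, 12)`).
#' @param noise_sd Observation noise sd (default 0.15).
#' @param seed Optional integer seed.
#' @return List with `obs1`, `obs2`, `window`, `stimulus`.
#' @export
simulate_equality_conditions <- function(n_per_condition, effect_size = 3,
                                         window = c(10, 12),
                                         noise_sd = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prot <- sine_protocol(data.frame(frequency = rep(1, 16),
                                   contrast = rep(80, 16)))
  st <- generate_stimulus(prot, 128)
  mid <- mean(window); hw <- diff(window) / 2
  off <- if (effect_size > 0) {
    amp <- effect_size * noise_sd
    function(t) amp * exp(-((t - mid) / (0.75 * hw))^4) *
      sin(2 * pi * (t - window[1]))
  } else NULL
  n1 <- gt_neuron(noise_sd = noise_sd)
  n2 <- gt_neuron(noise_sd = noise_sd, offset_fun = off)
  t1 <- sort(stats::runif(n_per_condition, 0, prot$duration))
  t2 <- sort(stats::runif(n_per_condition, 0, prot$duration))
  s2 <- if (!is.null(seed)) seed + 1L else NULL
  list(obs1 = simulate_roi_observations(n1, st, t1, seed = s2,
                                        roi_id = "cond1"),
       obs2 = simulate_roi_observations(n2, st, t2,
                                        seed = if (!is.null(seed)) seed + 2L,
                                        roi_id = "cond2"),
       window = window, stimulus = st)
}

#' Simulate a population with known cluster structure
#'
#' Draws `k_clusters * rois_per_cluster` neurons; all share a common base
#' response to the protocol, and neurons of cluster `c > 1` additionally
#' receive a windowed oscillatory offset (a ~1.5 Hz modulation under a
#' smooth envelope, emulating an amplitude difference during an oscillatory
#' response segment) of amplitude `(c - 1) * effect_size * noise_sd` over a
#' cluster-specific window, so the separation between cluster templates is
#' `effect_size` in units of the observation noise.
#'
#' @param k_clusters Number of clusters (>= 1).
#' @param rois_per_cluster ROIs per cluster.
#' @param effect_size Template separation in noise-sd units (0 = identical).
#' @param protocol Stimulus protocol (default [chirp_protocol()]).
#' @param scan A [scan_config()] used for sampling times (default spiral).
#' @param n_repeats Stimulus repeats pooled per ROI (default from protocol).
#' @param noise_sd Observation noise sd (default 0.1).
#' @param max_obs Per-ROI observation budget: scan sampling times are
#'   subsampled uniformly at random down to this count (default 2000;
#'   spiral scans otherwise yield tens of thousands of samples per ROI).
#' @param seed Optional integer seed.
#' @return List with `observations` (named list of [obs_set()]), `labels`
#'   (integer vector of true cluster per ROI), `stimulus`, and `neurons`.
#' @export
simulate_population <- function(k_clusters, rois_per_cluster, effect_size,
                                protocol = chirp_protocol(),
                                scan = scan_config("spiral"),
                                n_repeats = NULL, noise_sd = 0.1,
                                max_obs = 2000, seed = NULL) {
  stopifnot(k_clusters >= 1, rois_per_cluster >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_repeats)) n_repeats <- if (!is.null(protocol$repeats))
    protocol$repeats else 1L
  stimulus <- generate_stimulus(protocol)
  dur <- protocol$duration
  n_frames <- ceiling(dur * n_repeats * scan$frame_rate)
  bump <- function(t0, t1) {
    # windowed oscillation: flat-top envelope times a 1.5 Hz modulation
    force(t0); force(t1)
    mid <- (t0 + t1) / 2; hw <- (t1 - t0) / 2
    function(t) exp(-((t - mid) / (0.75 * hw))^4) *
      sin(2 * pi * 1.5 * (t - t0))
  }
  # cluster-specific windows staggered over the stimulus
  windows <- lapply(seq_len(max(k_clusters - 1, 1)), function(i)
    c(2 + (i - 1) * 4, 5 + (i - 1) * 4))
  obs <- list(); labels <- integer(0); neurons <- list()
  idx <- 0L
  for (cl in seq_len(k_clusters)) {
    off <- if (cl == 1L) NULL else local({
      w <- windows[[cl - 1]]
      amp <- effect_size * noise_sd
      b <- bump(w[1], w[2])
      function(t) amp * b(t)
    })
    for (r in seq_len(rois_per_cluster)) {
      idx <- idx + 1L
      id <- sprintf("roi%02d", idx)
      neuron <- gt_neuron(noise_sd = noise_sd, offset_fun = off)
      mask <- roi_mask_disc(scan$grid,
                            center = stats::runif(2, 0.25, 0.75),
                            radius = 0.07)
      times <- scan_sampling_times(scan, mask, n_frames)
      times <- times[times < dur * n_repeats]
      if (!is.null(max_obs) && length(times) > max_obs)
        times <- sort(sample(times, max_obs))
      obs[[id]] <- simulate_roi_observations(neuron, stimulus, times,
                                             roi_id = id)
      labels <- c(labels, cl)
      neurons[[id]] <- neuron
    }
  }
  names(labels) <- names(obs)
  list(observations = obs, labels = labels, stimulus = stimulus,
       neurons = neurons)
}
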