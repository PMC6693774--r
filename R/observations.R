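#' Irregular fluorescence observations for one ROI
#'
#' Container for the (time, value) samples of a single region of interest,
#' pooled across stimulus trials. Times are seconds relative to trial start.
#' Optional per-observation stimulus parameters (frequency in Hz, contrast in
#' percent, direction in degrees) and a trial index may be attached; the trial
#' index is metadata only and is never used as a model predictor.
#'
#' @param times Numeric vector of sample times (seconds, trial-relative).
#' @param values Numeric vector of fluorescence values (arbitrary units).
#' @param roi_id Identifier for the ROI.
#' @param stim Optional list or data.frame of per-observation stimulus
#'   parameters; recognised names are `frequency`, `contrast`, `direction`.
#' @param trial_id Optional integer vector of trial indices per observation.
#' @return An object of class `obs_set`.
#' @export
obs_set <- function(times, values, roi_id = "roi", stim = NULL,
                    trial_id = NULL) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (any(!is.finite(times))) stop("times must be finite")
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(times < 0)) stop("times must be non-negative (trial-relative)")
  if (!is.null(trial_id) && length(trial_id) != length(times))
    stop("trial_id length does not match times")
  if (!is.null(stim)) {
    stim <- as.data.frame(stim)
    if (nrow(stim) != length(times))
      stop("stim parameter rows do not match times")
  }
  structure(list(roi_id = roi_id, times = times, values = values,
                 stim = stim, trial_id = trial_id),
            class = "obs_set")
}

#' @export
print.obs_set <- function(x, ...) {
  cat("<obs_set> roi:", x$roi_id, "-", length(x$times), "observations, t in [",
      sprintf("%.3f", min(x$times)), ",", sprintf("%.3f", max(x$times)), ") s\n")
  if (!is.null(x$stim))
    cat("  stimulus parameters:", paste(names(x$stim), collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.obs_set <- function(x) length(x$times)

#' Pool several observation sets into one
#'
#' Concatenates observations (times, values, stimulus parameters, trial ids)
#' from multiple ROIs or conditions into a single `obs_set`, as used when
#' fitting one GP to a putative cluster or when building a bootstrap pool.
#'
#' @param ... `obs_set` objects, or a single list of them.
#' @param roi_id Identifier for the pooled set.
#' @return An `obs_set`.
#' @export
pool_observations <- function(..., roi_id = "pooled") {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "obs_set")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  times <- unlist(lapply(sets, `[[`, "times"))
  values <- unlist(lapply(sets, `[[`, "values"))
  trial <- if (all(vapply(sets, function(s) !is.null(s$trial_id), logical(1))))
    unlist(lapply(sets, `[[`, "trial_id")) else NULL
  stim <- NULL
  if (all(vapply(sets, function(s) !is.null(s$stim), logical(1)))) {
    common <- Reduce(intersect, lapply(sets, function(s) names(s$stim)))
    if (length(common))
      stim <- do.call(rbind, lapply(sets, function(s) s$stim[common]))
  }
  obs_set(times, values, roi_id = roi_id, stim = stim, trial_id = trial)
}

#' Subset an observation set by index
#'
#' @param obs An [obs_set()].
#' @param idx Integer or logical index into the observations.
#' @param roi_id Identifier for the subset (defaults to the parent's).
#' @return An [obs_set()].
#' @export
obs_subset <- function(obs, idx, roi_id = obs$roi_id) {
  obs_set(obs$times[idx], obs$values[idx], roi_id = roi_id,
          stim = if (!is.null(obs$stim)) obs$stim[idx, , drop = FALSE],
          trial_id = obs$trial_id[idx])
}
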