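# Dataset and model persistence (JSON with full-precision doubles, CSV,
# Newick), and run configuration.
#
# The canonical dataset layout mirrors the group structure
#   /rois/{id}/{times,values,trial_id,stim/...}
#   /stimulus/{trace,timebase,protocol}
#   /meta
# stored in a single JSON document. Integers round-trip bitwise; doubles
# round-trip to full printed precision (within 1e-12).

#' Write a dataset to disk
#'
#' Serializes a dataset (a named list of [obs_set()] plus optional stimulus
#' trace and metadata) into a single JSON document following the layout
#' `/rois/{id}/{times,values,trial_id,stim}`, `/stimulus`, `/meta`. All
#' times are seconds, angles degrees, contrast percent.
#'
#' @param dataset Either a named list of [obs_set()] or a list with
#'   elements `rois` (named list of obs_set), `stimulus` (data.frame from
#'   [generate_stimulus()], optional) and `meta` (list, optional).
#' @param path Output file path.
#' @export
write_dataset <- function(dataset, path) {
  if (!is.null(names(dataset)) && all(vapply(dataset, inherits, logical(1),
                                             "obs_set")))
    dataset <- list(rois = dataset)
  stopifnot(!is.null(dataset$rois), length(dataset$rois) >= 1L)
  doc <- list(
    rois = lapply(dataset$rois, function(o) {
      stopifnot(inherits(o, "obs_set"))
      out <- list(times = o$times, values = o$values)
      if (!is.null(o$trial_id)) out$trial_id <- as.integer(o$trial_id)
      if (!is.null(o$stim)) out$stim <- as.list(o$stim)
      out
    }),
    meta = c(list(units = list(times = "seconds", values = "a.u.",
                               frequency = "Hz", contrast = "percent",
                               direction = "degrees")),
             dataset$meta))
  if (!is.null(dataset$stimulus)) {
    st <- dataset$stimulus
    doc$stimulus <- list(timebase = st$time, trace = st$value,
                         frequency = st$frequency, contrast = st$contrast,
                         direction = st$direction,
                         trial_id = as.integer(st$trial_id))
    proto <- attr(st, "protocol")
    if (!is.null(proto)) doc$stimulus$protocol <- unclass(proto)
  }
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null", dataframe = "columns")
  invisible(path)
}

#' Read a dataset from disk
#'
#' Inverse of [write_dataset()]; validates the group layout and the
#' parallel-array invariants, naming the offending group or ROI in errors.
#'
#' @param path Path to a dataset file written by [write_dataset()].
#' @return List with `rois` (named list of [obs_set()]), `stimulus`
#'   (data.frame or `NULL`) and `meta`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$rois)) stop("dataset is missing required group '/rois'")
  if (!length(doc$rois)) stop("dataset group '/rois' is empty")
  rois <- lapply(names(doc$rois), function(id) {
    r <- doc$rois[[id]]
    if (is.null(r$times) || is.null(r$values))
      stop("ROI '", id, "' is missing times or values")
    if (length(r$times) != length(r$values) ||
        (!is.null(r$trial_id) && length(r$trial_id) != length(r$times)))
      stop("ROI '", id, "' has mismatched array lengths")
    stim <- if (!is.null(r$stim)) as.data.frame(r$stim)
    if (!is.null(stim) && nrow(stim) != length(r$times))
      stop("ROI '", id, "' has mismatched array lengths")
    obs_set(r$times, r$values, roi_id = id, stim = stim,
            trial_id = r$trial_id)
  })
  names(rois) <- names(doc$rois)
  stimulus <- NULL
  if (!is.null(doc$stimulus)) {
    s <- doc$stimulus
    stimulus <- data.frame(time = s$timebase, value = s$trace)
    for (f in c("frequency", "contrast", "direction", "trial_id"))
      if (!is.null(s[[f]]) && length(s[[f]]) == nrow(stimulus))
        stimulus[[f]] <- s[[f]]
    if (!is.null(s$protocol))
      attr(stimulus, "protocol") <- s$protocol
  }
  list(rois = rois, stimulus = stimulus, meta = doc$meta)
}

#' Save / load a fitted GP model
#'
#' Serializes the model state (kernel effects, hyperparameters, inducing
#' inputs, training reference, warp knots, objective) to JSON; loading
#' rebuilds the posterior-query cache, so predictions from the reloaded
#' model are identical.
#'
#' @param model A `fitted_gp`.
#' @param path File path.
#' @return `save_gp` returns `path` invisibly; `load_gp` the `fitted_gp`.
#' @export
save_gp <- function(model, path) {
  stopifnot(inherits(model, "fitted_gp"))
  doc <- list(
    effects = lapply(model$kernel$effects, unclass),
    hyp = model$hyp,
    X = as.data.frame(model$X), y = model$y, center = model$center,
    Z = if (!is.null(model$Z)) as.data.frame(model$Z),
    sparse = model$sparse, objective = model$objective,
    n_obs = model$n_obs,
    warp = if (!is.null(model$warp)) unclass(model$warp),
    encoding = if (!is.null(model$encoding)) unclass(model$encoding),
    config = unclass(model$config))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_gp
#' @export
load_gp <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  effects <- lapply(doc$effects, function(e)
    rbf_effect(e$name, e$columns, e$interaction))
  hyp <- list(effects = lapply(doc$hyp$effects, function(h)
    list(lengthscale = h$lengthscale, signal_sd = h$signal_sd)),
    noise_sd = doc$hyp$noise_sd)
  warp <- if (!is.null(doc$warp))
    structure(doc$warp, class = "warp_fun")
  encoding <- if (!is.null(doc$encoding)) {
    enc <- doc$encoding
    structure(list(columns = enc$columns,
                   center = stats::setNames(unlist(enc$center), enc$columns),
                   scale = stats::setNames(unlist(enc$scale), enc$columns),
                   effects = lapply(enc$effects, function(e)
                     rbf_effect(e$name, e$columns, e$interaction))),
              class = "predictor_encoding")
  }
  model <- structure(list(
    kernel = compose_effect_kernel(effects), hyp = hyp,
    X = as.matrix(doc$X), y = doc$y, center = doc$center,
    Z = if (!is.null(doc$Z)) as.matrix(doc$Z), sparse = doc$sparse,
    objective = doc$objective, n_obs = doc$n_obs, warp = warp,
    encoding = encoding, restart = NA_integer_,
    config = do.call(fit_config, as.list(doc$config))),
    class = "fitted_gp")
  model$cache <- build_gp_cache(model)
  model
}

#' Default run configuration
#'
#' All pipeline defaults in one nested list: fitting (300 inducing inputs,
#' 25 iterations, 6 restarts), warp (500 ms windows at 1/16 s spacing),
#' equality testing (500 bootstrap replicates of 300 observations, grid
#' spacing 1/64 s, headline z = 3, alpha = 0.01), clustering (alpha
#' criterion, 99.5th percentile alternative), ANOVA (alpha = 0.01, patience
#' 1), and design (150 blue-noise parameters, batch size 30, 64 x 64 map).
#' Every entry can be overridden and the resolved configuration is persisted
#' alongside results.
#'
#' @param ... Named overrides, e.g. `fit = list(n_iter = 10)`; merged
#'   recursively.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    fit = list(n_inducing = 300, n_iter = 25, n_restarts = 6),
    warp = list(window = 0.5, spacing = 1 / 16, normalize = TRUE,
                variant = "inverse"),
    equality = list(n_reps = 500, sample_size = 300, grid_spacing = 1 / 64,
                    z = 3, alpha = 0.01),
    cluster = list(criterion = "alpha", percentile = 0.995, alpha = 0.01),
    anova = list(alpha = 0.01, patience = 1),
    design = list(frequency = c(1, 8), contrast = c(10, 100),
                  min_frequency = 1, min_contrast = 10, n_blue_noise = 150,
                  min_dist = NULL, batch_size = 30, resolution = 64,
                  rounds = 3),
    seed = 1L)
  over <- list(...)
  merge_rec <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]))
        merge_rec(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  structure(merge_rec(cfg, over), class = "run_config")
}

#' Read / write a run configuration (YAML)
#'
#' Unknown keys in the file raise an error naming the offending key.
#'
#' @param path YAML file path.
#' @param config A `run_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- default_config()
  check <- function(b, r, prefix = "") {
    for (nm in names(r)) {
      if (!nm %in% names(b))
        stop("unknown configuration key: ", prefix, nm)
      if (is.list(r[[nm]]) && is.list(b[[nm]]))
        check(b[[nm]], r[[nm]], paste0(prefix, nm, "."))
    }
  }
  check(unclass(base), raw)
  do.call(default_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
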