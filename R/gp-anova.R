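# GP-ANOVA: stimulus parameters as GP predictors, additive/interaction RBF
# kernels, and forward likelihood-ratio kernel selection.

#' Encode stimulus parameters as GP predictor columns
#'
#' Builds the predictor matrix for GP-ANOVA models: time (optionally
#' warped), oscillation phase as the circular pair
#' `(cos(2 pi t f), sin(2 pi t f))`, direction as
#' `(cos(2 pi a / 360), sin(2 pi a / 360))`, and frequency and contrast
#' linearly. All columns are z-scored with statistics computed from the
#' training data and reused for prediction grids; circular pairs lie on the
#' unit circle before z-scoring. Columns that a requested effect needs but
#' the observations lack raise an error.
#'
#' @param obs An [obs_set()] whose `stim` carries the needed parameters
#'   (`frequency`, `contrast`, `direction`, `trial_time`).
#' @param effects List of [rbf_effect()] candidates whose columns determine
#'   which encodings are built.
#' @return Object of class `predictor_encoding` holding the built column
#'   names and the z-scoring statistics; apply it with the internal matrix
#'   builder used by [fit_gp()].
#' @export
encode_predictors <- function(obs, effects) {
  stopifnot(inherits(obs, "obs_set"))
  if (inherits(effects, "rbf_effect")) effects <- list(effects)
  needed <- unique(unlist(lapply(effects, `[[`, "columns")))
  raw <- raw_predictor_frame(obs, needed, check = TRUE)
  mu <- vapply(raw, mean, numeric(1))
  sdv <- vapply(raw, stats::sd, numeric(1))
  sdv[!is.finite(sdv) | sdv < 1e-12] <- 1   # constant columns pass through
  structure(list(columns = names(raw), center = mu, scale = sdv,
                 effects = effects), class = "predictor_encoding")
}

# raw (pre z-score) predictor columns for an obs_set or a data.frame of
# raw stimulus parameters
raw_predictor_frame <- function(data, columns, check = FALSE) {
  get_par <- function(nm) {
    if (inherits(data, "obs_set")) {
      if (nm == "time") return(data$times)
      v <- data$stim[[nm]]
    } else {
      v <- data[[nm]]
      if (nm == "time" && is.null(v)) v <- data[["times"]]
    }
    v
  }
  need_par <- function(nm, for_col) {
    v <- get_par(nm)
    if (is.null(v) || all(is.na(v)))
      stop("stimulus parameter '", nm, "' required for predictor column '",
           for_col, "' is missing")
    v[is.na(v)] <- 0
    v
  }
  out <- list()
  for (col in columns) {
    out[[col]] <- switch(col,
      time = need_par("time", col),
      trial_time = need_par("trial_time", col),
      frequency = need_par("frequency", col),
      contrast = need_par("contrast", col),
      phase_cos = cos(2 * pi * need_par("trial_time", col) *
                        need_par("frequency", col)),
      phase_sin = sin(2 * pi * need_par("trial_time", col) *
                        need_par("frequency", col)),
      dir_cos = cos(2 * pi * need_par("direction", col) / 360),
      dir_sin = sin(2 * pi * need_par("direction", col) / 360),
      stop("unknown predictor column: ", col))
  }
  as.data.frame(out)
}

# z-scored predictor matrix for training or new data under an encoding
encoding_matrix <- function(encoding, data, warp = NULL) {
  stopifnot(inherits(encoding, "predictor_encoding"))
  raw <- raw_predictor_frame(data, encoding$columns)
  X <- as.matrix(raw)
  if (!is.null(warp)) {
    for (tc in intersect(c("time", "trial_time"), colnames(X)))
      X[, tc] <- warp_forward(warp, X[, tc])
  }
  X <- sweep(sweep(X, 2, encoding$center[colnames(X)]), 2,
             encoding$scale[colnames(X)], "/")
  X
}

#' Candidate effect sets per stimulus protocol
#'
#' Returns the default GP-ANOVA candidates: for the sine stimulus, phase,
#' frequency, contrast, the frequency-by-contrast interaction, the full
#' phase-frequency-contrast interaction and trial time; for the moving bar,
#' time, direction and the time-by-direction interaction.
#'
#' @param stimulus `"sine"` or `"moving_bar"`.
#' @return Named list of [rbf_effect()] objects.
#' @export
candidate_effects <- function(stimulus = c("sine", "moving_bar")) {
  stimulus <- match.arg(stimulus)
  if (stimulus == "sine") {
    list(
      phase = rbf_effect("phase", c("phase_cos", "phase_sin")),
      frequency = rbf_effect("frequency", "frequency"),
      contrast = rbf_effect("contrast", "contrast"),
      `frequency:contrast` = rbf_effect("frequency:contrast",
                                        c("frequency", "contrast")),
      `phase:frequency:contrast` = rbf_effect(
        "phase:frequency:contrast",
        c("phase_cos", "phase_sin", "frequency", "contrast")),
      time = rbf_effect("time", "trial_time"))
  } else {
    list(
      time = rbf_effect("time", "time"),
      direction = rbf_effect("direction", c("dir_cos", "dir_sin")),
      `time:direction` = rbf_effect("time:direction",
                                    c("time", "dir_cos", "dir_sin")))
  }
}

#' Likelihood-ratio test for a nested kernel addition
#'
#' Computes `Lambda = 2 * (l1 - l0)` for the maximized objectives of the
#' model without and with the candidate effect, and the upper-tail p-value
#' of the chi-squared distribution with `added_df` degrees of freedom. A
#' negative `Lambda` (optimizer failure on the larger model) is clamped to
#' zero with a warning.
#'
#' @param objective_without,objective_with Maximized log marginal
#'   likelihoods (or variational bounds) of the nested pair.
#' @param added_df Degrees of freedom added by the candidate (2 per effect:
#'   lengthscale and signal variance).
#' @param alpha Significance level (default 0.01).
#' @return Object of class `lrt_result`: `lambda`, `df`, `p`, `reject`
#'   (`TRUE` = the addition significantly improves the model).
#' @export
likelihood_ratio_test <- function(objective_without, objective_with,
                                  added_df = 2, alpha = 0.01) {
  lambda <- 2 * (objective_with - objective_without)
  if (lambda < 0) {
    warning("negative likelihood ratio (optimizer failure on the larger ",
            "model); clamped to 0")
    lambda <- 0
  }
  p <- stats::pchisq(lambda, df = added_df, lower.tail = FALSE)
  structure(list(lambda = lambda, df = added_df, p = p,
                 reject = p < alpha, alpha = alpha), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> Lambda = %.4g, df = %d, p = %.4g -> %s\n",
              x$lambda, x$df, x$p,
              if (x$reject) "effect retained" else "effect rejected"))
  invisible(x)
}

#' Forward selection of stimulus-effect kernels
#'
#' Greedy kernel construction: the first pass adopts the single candidate
#' with the best objective unconditionally; each later pass fits every
#' remaining candidate added to the current kernel, takes the best by
#' objective and adopts it only if its likelihood-ratio test rejects at
#' `alpha` (2 degrees of freedom per effect). Accepted effects are retained
#' in all later passes. Selection stops after `patience` consecutive
#' rejecting passes or when no candidates remain. Objective ties are broken
#' by candidate name (lexicographic). Fit errors for a candidate are logged
#' in the audit and treated as non-improvements.
#'
#' @param obs An [obs_set()] with the needed stimulus parameters.
#' @param candidates Named list of [rbf_effect()] (default
#'   [candidate_effects()] for the sine stimulus).
#' @param config [fit_config()] used for every candidate fit.
#' @param alpha LRT level (default 0.01).
#' @param patience Consecutive rejecting passes tolerated before stopping
#'   (default 1).
#' @param warp Optional warp for time columns.
#' @param seed Optional integer seed.
#' @return Object of class `effect_selection`: `effects` (accepted list),
#'   `model` (final `fitted_gp`), `audit` (one row per candidate per pass:
#'   pass, candidate, objective, lambda, df, p, decision), `encoding`.
#' @export
forward_select_effects <- function(obs, candidates = candidate_effects("sine"),
                                   config = fit_config(), alpha = 0.01,
                                   patience = 1, warp = NULL, seed = NULL) {
  stopifnot(length(candidates) >= 1L)
  if (is.null(names(candidates)))
    names(candidates) <- vapply(candidates, `[[`, character(1), "name")
  encoding <- encode_predictors(obs, candidates)
  accepted <- list()
  current_obj <- NA_real_
  current_model <- NULL
  audit <- data.frame(pass = integer(0), candidate = character(0),
                      objective = numeric(0), lambda = numeric(0),
                      df = integer(0), p = numeric(0),
                      decision = character(0))
  remaining <- names(candidates)
  pass <- 0L
  rejects <- 0L
  fit_i <- 0L
  while (length(remaining) > 0L && rejects < patience + (pass == 0L)) {
    pass <- pass + 1L
    objs <- rep(NA_real_, length(remaining)); names(objs) <- remaining
    fits <- list()
    for (nm in remaining) {
      fit_i <- fit_i + 1L
      spec <- compose_effect_kernel(c(accepted, candidates[nm]))
      fit <- tryCatch(
        fit_gp(obs, kernel = spec, config = config, warp = warp,
               encoding = encoding,
               seed = if (!is.null(seed)) seed + 101L * fit_i),
        error = function(e) e)
      if (inherits(fit, "error")) next
      objs[nm] <- fit$objective
      fits[[nm]] <- fit
    }
    ok <- names(objs)[is.finite(objs)]
    if (!length(ok)) break
    best <- ok[order(-objs[ok], ok)][1]
    if (pass == 1L) {
      accepted <- candidates[best]
      current_obj <- objs[[best]]
      current_model <- fits[[best]]
      for (nm in remaining)
        audit[nrow(audit) + 1L, ] <- list(pass, nm, objs[[nm]], NA_real_,
                                          NA_integer_, NA_real_,
                                          if (nm == best) "adopted" else
                                            if (is.finite(objs[[nm]]))
                                              "not best" else "fit failed")
      remaining <- setdiff(remaining, best)
      next
    }
    lrt <- likelihood_ratio_test(current_obj, objs[[best]], added_df = 2,
                                 alpha = alpha)
    for (nm in remaining) {
      dec <- if (!is.finite(objs[[nm]])) "fit failed"
        else if (nm != best) "not best"
        else if (lrt$reject) "adopted" else "rejected"
      audit[nrow(audit) + 1L, ] <- list(
        pass, nm, objs[[nm]],
        if (nm == best) lrt$lambda else NA_real_,
        if (nm == best) lrt$df else NA_integer_,
        if (nm == best) lrt$p else NA_real_, dec)
    }
    if (lrt$reject) {
      accepted <- c(accepted, candidates[best])
      current_obj <- objs[[best]]
      current_model <- fits[[best]]
      remaining <- setdiff(remaining, best)
      rejects <- 0L
    } else {
      rejects <- rejects + 1L
    }
  }
  structure(list(effects = accepted, model = current_model, audit = audit,
                 encoding = encoding, alpha = alpha),
            class = "effect_selection")
}

#' @export
print.effect_selection <- function(x, ...) {
  cat("<effect_selection> accepted:",
      if (length(x$effects)) paste(names(x$effects), collapse = ", ") else
        "(none)", "\n")
  cat("  passes:", max(x$audit$pass), "- candidate fits:", nrow(x$audit), "\n")
  invisible(x)
}

#' Export a selection audit to CSV
#'
#' One row per candidate per pass with the objective, likelihood-ratio
#' statistic, degrees of freedom, p-value and decision.
#'
#' @param selection An `effect_selection`.
#' @param path Output file path.
#' @export
export_selection_csv <- function(selection, path) {
  utils::write.csv(selection$audit, path, row.names = FALSE)
  invisible(path)
}
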