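#' Kernel hyperparameters for a radial basis function effect
#'
#' Bundles the three hyperparameters of an RBF kernel with additive Gaussian
#' observation noise: the lengthscale `l` (in predictor units), the signal
#' standard deviation and the noise standard deviation (both in value units).
#'
#' @param lengthscale Positive scalar; distance over which the latent function
#'   decorrelates.
#' @param signal_sd Positive scalar; prior standard deviation of the latent
#'   function.
#' @param noise_sd Positive scalar; standard deviation of the additive
#'   observation noise.
#' @return An object of class `kernel_hyp`.
#' @export
kernel_hyp <- function(lengthscale, signal_sd, noise_sd) {
  h <- list(lengthscale = lengthscale, signal_sd = signal_sd,
            noise_sd = noise_sd)
  for (nm in names(h)) {
    v <- h[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("kernel hyperparameter '", nm, "' must be a strictly positive scalar")
  }
  structure(h, class = "kernel_hyp")
}

# squared Euclidean distances between rows of X and X2
sq_dist <- function(X, X2 = NULL) {
  X <- as.matrix(X)
  X2 <- if (is.null(X2)) X else as.matrix(X2)
  if (ncol(X) != ncol(X2))
    stop("predictor dimensionality mismatch: ", ncol(X), " vs ", ncol(X2))
  d2 <- outer(rowSums(X^2), rowSums(X2^2), "+") - 2 * tcrossprod(X, X2)
  d2[d2 < 0] <- 0
  d2
}

#' RBF covariance matrix
#'
#' Evaluates the radial basis function kernel
#' `signal_sd^2 * exp(-||x - x'||^2 / (2 l^2))` between two point sets, with
#' optional additive noise variance on the diagonal when the two sets are the
#' same.
#'
#' @param X Numeric matrix (or vector, taken as one column) of predictor
#'   points, one row per point.
#' @param X2 Second point set sharing the dimensionality of `X`; `NULL` means
#'   `X` itself.
#' @param hyp A [kernel_hyp()] object.
#' @param include_noise If `TRUE` and `X2` is `NULL` (or identical to `X`),
#'   add `noise_sd^2` to the diagonal.
#' @return Covariance matrix of dimension `nrow(X)` by `nrow(X2)`.
#' @export
rbf_kernel_matrix <- function(X, X2 = NULL, hyp, include_noise = FALSE) {
  if (!inherits(hyp, "kernel_hyp")) hyp <- do.call(kernel_hyp, as.list(hyp))
  X <- as.matrix(X)
  same <- is.null(X2) || (is.matrix(X2) && identical(dim(X), dim(X2)) &&
                            isTRUE(all.equal(X, as.matrix(X2))))
  K <- hyp$signal_sd^2 * exp(-sq_dist(X, X2) / (2 * hyp$lengthscale^2))
  if (include_noise) {
    if (!same)
      stop("include_noise is only meaningful when X2 is NULL or identical to X")
    diag(K) <- diag(K) + hyp$noise_sd^2
  }
  K
}

#' Define one additive RBF effect of a kernel
#'
#' An effect is one additive summand of a composite GP kernel: an RBF over a
#' set of predictor columns. An effect spanning several columns uses a single
#' shared lengthscale, so (for z-scored predictors) it acts as an interaction
#' term in which a change of one predictor trades off against an equal change
#' of another.
#'
#' @param name Short identifier, e.g. `"time"`, `"frequency"`,
#'   `"frequency:contrast"`.
#' @param columns Character vector of predictor-column names the effect spans.
#' @param interaction Logical; defaults to `TRUE` when more than one column is
#'   spanned.
#' @return An object of class `rbf_effect`.
#' @export
rbf_effect <- function(name, columns, interaction = length(columns) > 1L) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(columns), length(columns) >= 1L)
  structure(list(name = name, columns = columns, interaction = interaction),
            class = "rbf_effect")
}

#' Compose a kernel from additive effects
#'
#' Builds a composite kernel: the sum over effects of RBF kernels (each with
#' its own lengthscale and signal variance) plus a single additive Gaussian
#' noise term. Duplicate effects (same column set) are rejected.
#'
#' @param effects A list of [rbf_effect()] objects (a single effect is
#'   accepted bare).
#' @return An object of class `kernel_spec`.
#' @export
compose_effect_kernel <- function(effects) {
  if (inherits(effects, "rbf_effect")) effects <- list(effects)
  stopifnot(length(effects) >= 1L)
  for (e in effects)
    if (!inherits(e, "rbf_effect")) stop("all effects must be rbf_effect objects")
  keys <- vapply(effects, function(e) paste(sort(e$columns), collapse = "+"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate effects over the same columns: ", keys[duplicated(keys)][1])
  names(effects) <- vapply(effects, `[[`, character(1), "name")
  structure(list(effects = effects), class = "kernel_spec")
}

# number of hyperparameters to optimize: (log l, log signal_sd) per effect
# plus one log noise_sd
n_kernel_params <- function(spec) 2L * length(spec$effects) + 1L

# unpack a log-parameter vector into per-effect hyperparameters + noise sd
unpack_params <- function(spec, logp) {
  ne <- length(spec$effects)
  stopifnot(length(logp) == 2L * ne + 1L)
  hyps <- vector("list", ne)
  for (i in seq_len(ne)) {
    hyps[[i]] <- list(lengthscale = exp(logp[2 * i - 1]),
                      signal_sd = exp(logp[2 * i]))
  }
  names(hyps) <- names(spec$effects)
  list(effects = hyps, noise_sd = exp(logp[2 * ne + 1]))
}

# covariance of a composite kernel between rows of X and X2 (no noise term).
# X, X2 are full predictor matrices with named columns; each effect selects
# its columns. Returns the summed effect covariance.
spec_kernel_matrix <- function(spec, hyp, X, X2 = NULL) {
  X <- as.matrix(X)
  X2m <- if (is.null(X2)) X else as.matrix(X2)
  K <- matrix(0, nrow(X), nrow(X2m))
  for (i in seq_along(spec$effects)) {
    e <- spec$effects[[i]]
    h <- hyp$effects[[i]]
    cols <- effect_cols(e, X)
    d2 <- sq_dist(X[, cols, drop = FALSE], X2m[, cols, drop = FALSE])
    K <- K + h$signal_sd^2 * exp(-d2 / (2 * h$lengthscale^2))
  }
  K
}

# per-effect squared-distance matrices, precomputed once per fit
spec_sq_dists <- function(spec, X, X2 = NULL) {
  X <- as.matrix(X)
  X2m <- if (is.null(X2)) X else as.matrix(X2)
  lapply(spec$effects, function(e) {
    cols <- effect_cols(e, X)
    sq_dist(X[, cols, drop = FALSE], X2m[, cols, drop = FALSE])
  })
}

# kernel matrix from precomputed squared distances
spec_kernel_from_d2 <- function(spec, hyp, d2list) {
  K <- 0
  for (i in seq_along(spec$effects)) {
    h <- hyp$effects[[i]]
    K <- K + h$signal_sd^2 * exp(-d2list[[i]] / (2 * h$lengthscale^2))
  }
  K
}

# resolve effect columns against a predictor matrix
effect_cols <- function(e, X) {
  cn <- colnames(X)
  if (is.null(cn)) {
    if (identical(e$columns, "time") && ncol(X) == 1L) return(1L)
    stop("predictor matrix has no column names; cannot resolve effect '",
         e$name, "'")
  }
  idx <- match(e$columns, cn)
  if (anyNA(idx))
    stop("effect '", e$name, "' needs missing predictor column(s): ",
         paste(e$columns[is.na(idx)], collapse = ", "))
  idx
}

# prior (latent) variance at a point: sum of effect signal variances
spec_prior_var <- function(spec, hyp) {
  sum(vapply(hyp$effects, function(h) h$signal_sd^2, numeric(1)))
}

# Cholesky with escalating jitter: 1e-8 up to 1e-4 in decades, then error.
chol_safe <- function(M, jitter0 = 1e-8, jitter_max = 1e-4) {
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (!is.null(R)) return(R)
  scale <- mean(diag(M))
  j <- jitter0
  while (j <= jitter_max) {
    R <- tryCatch(chol(M + diag(j * max(scale, 1), nrow(M))),
                  error = function(e) NULL)
    if (!is.null(R)) return(R)
    j <- j * 10
  }
  stop("covariance matrix is not positive definite even after jitter up to ",
       jitter_max)
}
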