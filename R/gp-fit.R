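# Dense and sparse (variational inducing-point) GP machinery.
#
# Hyperparameters are optimized in log space with L-BFGS-B; the "iterations
# per fit" cap is the optimizer iteration cap. Inducing inputs are a random
# subset of the training inputs, held fixed during optimization (see the
# methods vignette for the rationale).

#' Log marginal likelihood of a zero-mean GP
#'
#' Exact (dense) evaluation of `log p(y | X)` for the multivariate normal
#' with covariance `k(X, X) + I * noise_sd^2` under a single RBF kernel.
#'
#' @param obs An [obs_set()]; times are the predictor.
#' @param hyp A [kernel_hyp()] object.
#' @param center Value subtracted from the observations before evaluation
#'   (default 0; the fitting routine uses the median).
#' @return Scalar log marginal likelihood.
#' @export
log_marginal_likelihood <- function(obs, hyp, center = 0) {
  stopifnot(inherits(obs, "obs_set"), length(obs$times) >= 1L)
  if (!inherits(hyp, "kernel_hyp")) hyp <- do.call(kernel_hyp, as.list(hyp))
  X <- matrix(obs$times, ncol = 1, dimnames = list(NULL, "time"))
  y <- obs$values - center
  K <- rbf_kernel_matrix(X, hyp = hyp, include_noise = TRUE)
  L <- tryCatch(chol(K), error = function(e)
    stop("covariance matrix is singular (duplicated inputs with zero noise?)"))
  a <- backsolve(L, backsolve(L, y, transpose = TRUE))
  -0.5 * sum(y * a) - sum(log(diag(L))) - length(y) / 2 * log(2 * pi)
}

# dense negative log marginal likelihood + analytic gradient in log-params.
# d2list: per-effect squared-distance matrices for the training inputs.
dense_nll <- function(logp, spec, d2list, y) {
  hyp <- unpack_params(spec, logp)
  K <- spec_kernel_from_d2(spec, hyp, d2list)
  diag(K) <- diag(K) + hyp$noise_sd^2
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = rep(0, length(logp))))
  a <- backsolve(L, backsolve(L, y, transpose = TRUE))
  n <- length(y)
  nll <- 0.5 * sum(y * a) + sum(log(diag(L))) + n / 2 * log(2 * pi)
  Kinv <- chol2inv(L)
  W <- tcrossprod(a) - Kinv              # dLML/dK = W/2
  g <- numeric(length(logp))
  for (i in seq_along(spec$effects)) {
    h <- hyp$effects[[i]]
    Ke <- h$signal_sd^2 * exp(-d2list[[i]] / (2 * h$lengthscale^2))
    g[2 * i - 1] <- -0.5 * sum(W * (Ke * d2list[[i]] / h$lengthscale^2))
    g[2 * i] <- -0.5 * sum(W * (2 * Ke))
  }
  g[length(logp)] <- -0.5 * sum(diag(W)) * 2 * hyp$noise_sd^2
  list(value = nll, grad = g)
}

# variational sparse lower bound (negative, for minimization) with fixed
# inducing inputs Z. Collapsed bound: log N(y | 0, Qnn + s2 I) -
# tr(Knn - Qnn) / (2 s2), evaluated with Cholesky factors.
# d2mm / d2nm: precomputed per-effect squared distances Z-Z and X-Z.
sparse_nll <- function(logp, spec, y, d2mm, d2nm) {
  hyp <- unpack_params(spec, logp)
  s <- hyp$noise_sd
  n <- length(y)
  Kmm <- spec_kernel_from_d2(spec, hyp, d2mm)
  Knm <- spec_kernel_from_d2(spec, hyp, d2nm)
  L <- tryCatch(chol_safe(Kmm), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  A <- backsolve(L, t(Knm), transpose = TRUE) / s      # M x n
  B <- diag(nrow(Kmm)) + tcrossprod(A)
  LB <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(LB)) return(1e10)
  Ay <- A %*% y
  cvec <- backsolve(LB, Ay, transpose = TRUE) / s
  knn_sum <- n * spec_prior_var(spec, hyp)
  elbo <- -n / 2 * log(2 * pi) - sum(log(diag(LB))) - n * log(s) -
    0.5 * sum(y^2) / s^2 + 0.5 * sum(cvec^2) -
    0.5 * knn_sum / s^2 + 0.5 * sum(A^2)
  -elbo
}

# forward-difference gradient for the sparse bound (few parameters); the
# optimizer always evaluates fn at a point before gr, so the last fn value
# is cached and reused as the FD base point
sparse_memo <- new.env(parent = emptyenv())

sparse_nll_memo <- function(logp, spec, y, d2mm, d2nm) {
  v <- sparse_nll(logp, spec, y, d2mm, d2nm)
  sparse_memo$p <- logp
  sparse_memo$v <- v
  v
}

sparse_nll_grad <- function(logp, spec, y, d2mm, d2nm, eps = 1e-5) {
  f0 <- if (!is.null(sparse_memo$p) && identical(sparse_memo$p, logp))
    sparse_memo$v else sparse_nll(logp, spec, y, d2mm, d2nm)
  vapply(seq_along(logp), function(i) {
    lp <- logp; lp[i] <- lp[i] + eps
    (sparse_nll(lp, spec, y, d2mm, d2nm) - f0) / eps
  }, numeric(1))
}

#' Fitting configuration
#'
#' Bundles the sparse-GP fitting controls: number of inducing inputs,
#' optimizer iteration cap per fit, and number of random restarts (the best
#' restart by objective is kept).
#'
#' @param n_inducing Number of inducing inputs (default 300); when it is at
#'   least the number of observations the exact dense GP is fitted instead.
#' @param n_iter Optimizer (L-BFGS) iteration cap per restart (default 25).
#' @param n_restarts Number of random restarts (default 6).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_inducing = 300, n_iter = 25, n_restarts = 6) {
  stopifnot(n_inducing >= 2, n_iter >= 1, n_restarts >= 1)
  structure(list(n_inducing = n_inducing, n_iter = n_iter,
                 n_restarts = n_restarts), class = "fit_config")
}

#' Fit a (sparse) GP to one observation set
#'
#' Maximizes the log marginal likelihood (exact when `n_inducing >= n`) or
#' its variational inducing-point lower bound over the kernel
#' hyperparameters, with L-BFGS on log-transformed parameters, and returns
#' the best of `n_restarts` seeded restarts. Per restart, the lengthscale is
#' initialized log-uniformly over `[0.01, 1]` times the predictor range and
#' the signal/noise standard deviations from the data standard deviation.
#'
#' @param obs An [obs_set()].
#' @param kernel A `kernel_spec` from [compose_effect_kernel()]; default is a
#'   single RBF effect over time.
#' @param config A [fit_config()].
#' @param warp Optional [build_time_warp()] warp applied to observation times
#'   (and, transparently, to prediction grids).
#' @param encoding Optional `predictor_encoding` from [encode_predictors()]
#'   for multi-predictor (GP-ANOVA) models; when given, the kernel effects
#'   must reference its columns.
#' @param init Optional warm start: a hyperparameter set shaped like the
#'   `hyp` field of a `fitted_gp` (per-effect lengthscale/signal sd plus
#'   noise sd). The first restart starts exactly there; further restarts
#'   use the usual stratified initialization.
#' @param seed Optional integer seed; restarts are seeded `seed + restart`.
#' @return An object of class `fitted_gp` with elements `hyp` (per-effect
#'   lengthscale/signal sd and the noise sd), `Z` (inducing inputs),
#'   `objective` (achieved log marginal likelihood or lower bound), and a
#'   posterior-query cache. Posterior queries on the returned object are
#'   deterministic.
#' @export
fit_gp <- function(obs, kernel = NULL, config = fit_config(), warp = NULL,
                   encoding = NULL, init = NULL, seed = NULL) {
  stopifnot(inherits(obs, "obs_set"))
  n <- length(obs$times)
  if (n < 2L) stop("need at least 2 observations to fit a GP")
  if (is.null(kernel)) kernel <- compose_effect_kernel(rbf_effect("time", "time"))
  if (!is.null(seed)) set.seed(seed)

  X <- build_predictors(obs, encoding, warp)
  center <- stats::median(obs$values)
  y <- obs$values - center
  sdy <- stats::sd(y)
  if (!is.finite(sdy) || sdy == 0) sdy <- max(abs(y), 1e-3)

  sparse <- config$n_inducing < n
  d2list <- if (!sparse) spec_sq_dists(kernel, X) else NULL
  Z <- NULL; d2mm <- NULL; d2nm <- NULL
  if (sparse) {
    Z <- X[sample.int(n, config$n_inducing), , drop = FALSE]
    d2mm <- spec_sq_dists(kernel, Z)
    d2nm <- spec_sq_dists(kernel, X, Z)
  }

  ranges <- vapply(kernel$effects, function(e) {
    cols <- effect_cols(e, X)
    r <- max(apply(X[, cols, drop = FALSE], 2, function(v) diff(range(v))))
    if (r <= 0) r <- 1
    r
  }, numeric(1))

  ne <- length(kernel$effects)
  lower <- c(rbind(log(ranges * 1e-3), rep(log(sdy * 1e-3), ne)),
             log(sdy * 1e-4))
  upper <- c(rbind(log(ranges * 10), rep(log(sdy * 1e2), ne)),
             log(sdy * 1e2))

  best <- NULL
  diagnostics <- character(0)
  for (r in seq_len(config$n_restarts)) {
    if (!is.null(seed)) set.seed(seed + r)
    # lengthscale starts log-uniform over [0.01, 1] x predictor range,
    # stratified across restarts so short and long scales are both visited
    # restart 1 is anchored at the short end of the band: relaxing an
    # overfitted lengthscale upward is reliable, whereas a start longer
    # than the signal's period collapses into the all-noise basin
    u <- (r - 1) / max(config$n_restarts - 1, 1) * 0.85 +
      stats::runif(ne, 0, 0.12)
    u <- pmin(pmax(u, 0.001), 0.999)
    l0 <- log(ranges) + (1 - u) * log(0.01)
    s0 <- log(sdy * stats::runif(ne, 0.5, 1.2))
    p0 <- c(rbind(l0, s0), log(sdy * stats::runif(1, 0.3, 0.8)))
    if (!is.null(init) && r == 1L) {
      li <- vapply(init$effects, `[[`, numeric(1), "lengthscale")
      si <- vapply(init$effects, `[[`, numeric(1), "signal_sd")
      p0 <- c(rbind(log(li), log(si)), log(init$noise_sd))
    }
    p0 <- pmin(pmax(p0, lower), upper)
    res <- tryCatch({
      if (!sparse) {
        stats::optim(p0, fn = function(p) dense_nll(p, kernel, d2list, y)$value,
                     gr = function(p) dense_nll(p, kernel, d2list, y)$grad,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = config$n_iter))
      } else {
        stats::optim(p0, fn = sparse_nll_memo, gr = sparse_nll_grad,
                     spec = kernel, y = y, d2mm = d2mm, d2nm = d2nm,
                     method = "L-BFGS-B", lower = lower, upper = upper,
                     control = list(maxit = config$n_iter))
      }
    }, error = function(e) e)
    if (inherits(res, "error") || !is.finite(res$value) || res$value >= 1e10) {
      diagnostics <- c(diagnostics, sprintf(
        "restart %d: %s", r,
        if (inherits(res, "error")) conditionMessage(res) else "diverged"))
      next
    }
    if (is.null(best) || res$value < best$value)
      best <- list(value = res$value, par = res$par, restart = r)
  }
  if (is.null(best))
    stop("all restarts diverged:\n", paste(diagnostics, collapse = "\n"))

  hyp <- unpack_params(kernel, best$par)
  model <- structure(list(
    kernel = kernel, hyp = hyp, X = X, y = y, center = center,
    Z = Z, sparse = sparse, objective = -best$value,
    n_obs = n, warp = warp, encoding = encoding,
    restart = best$restart, config = config,
    diagnostics = diagnostics), class = "fitted_gp")
  model$cache <- build_gp_cache(model)
  model
}

# prediction cache: Cholesky factors shared by all posterior queries
build_gp_cache <- function(model) {
  hyp <- model$hyp; spec <- model$kernel
  if (!model$sparse) {
    K <- spec_kernel_matrix(spec, hyp, model$X)
    diag(K) <- diag(K) + hyp$noise_sd^2
    L <- chol_safe(K)
    alpha <- backsolve(L, backsolve(L, model$y, transpose = TRUE))
    list(L = L, alpha = alpha)
  } else {
    s <- hyp$noise_sd
    Kmm <- spec_kernel_matrix(spec, hyp, model$Z)
    Knm <- spec_kernel_matrix(spec, hyp, model$X, model$Z)
    L <- chol_safe(Kmm)
    A <- backsolve(L, t(Knm), transpose = TRUE) / s
    B <- diag(nrow(Kmm)) + tcrossprod(A)
    LB <- chol_safe(B)
    cvec <- backsolve(LB, A %*% model$y, transpose = TRUE) / s
    list(L = L, LB = LB, cvec = cvec)
  }
}

# build the (possibly warped / encoded) predictor matrix for an obs_set
build_predictors <- function(obs, encoding = NULL, warp = NULL) {
  if (!is.null(encoding)) return(encoding_matrix(encoding, obs, warp))
  t <- obs$times
  if (!is.null(warp)) t <- warp_forward(warp, t)
  matrix(t, ncol = 1, dimnames = list(NULL, "time"))
}

# predictor matrix for new inputs: numeric vector of times, or a data.frame /
# matrix of raw predictors matching the model's encoding
new_predictors <- function(model, newdata) {
  if (!is.null(model$encoding))
    return(encoding_matrix(model$encoding, newdata, model$warp))
  if (is.data.frame(newdata)) newdata <- newdata$time
  if (!is.numeric(newdata))
    stop("newdata must be a numeric vector of times for a time-only model")
  t <- as.numeric(newdata)
  if (!is.null(model$warp)) t <- warp_forward(model$warp, t)
  matrix(t, ncol = 1, dimnames = list(NULL, "time"))
}

#' @export
print.fitted_gp <- function(x, ...) {
  cat("<fitted_gp>", if (x$sparse) sprintf("sparse (M = %d)", nrow(x$Z))
      else "exact", "- n =", x$n_obs, "\n")
  cat("  objective:", sprintf("%.3f", x$objective),
      sprintf("(restart %d)", x$restart), "\n")
  for (nm in names(x$hyp$effects)) {
    h <- x$hyp$effects[[nm]]
    cat(sprintf("  %s: lengthscale %.4g, signal sd %.4g\n", nm,
                h$lengthscale, h$signal_sd))
  }
  cat(sprintf("  noise sd %.4g\n", x$hyp$noise_sd))
  invisible(x)
}
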