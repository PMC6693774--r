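# Hierarchical clustering of per-ROI GP mean functions and top-down
# statistical validation of dendrogram splits with the EC equality test.

#' Fit GP models for a set of ROIs with a shared warm start
#'
#' Fits one GP per ROI. By default a single model is first fitted to a
#' pooled subsample of all ROIs' observations and every per-ROI fit is
#' warm-started at its hyperparameters: the pooled fit sees enough data to
#' land in the structure-resolving likelihood basin, and the warm start
#' keeps the (much smaller) per-ROI fits in the same basin instead of
#' collapsing into the all-noise optimum.
#'
#' @param observations Named list of [obs_set()].
#' @param config [fit_config()] for the per-ROI fits.
#' @param warm Use the pooled warm start (default `TRUE`).
#' @param pool_cap Observation cap for the pooled fit (default 600).
#' @param warp Optional shared warp.
#' @param seed Optional integer seed.
#' @return Named list of `fitted_gp`.
#' @export
fit_roi_models <- function(observations, config = fit_config(),
                           warm = TRUE, pool_cap = 600, warp = NULL,
                           seed = NULL) {
  stopifnot(length(observations) >= 1L)
  init <- NULL
  if (warm) {
    pool <- pool_observations(observations)
    if (!is.null(seed)) set.seed(seed)
    if (length(pool) > pool_cap)
      pool <- obs_subset(pool, sort(sample.int(length(pool), pool_cap)))
    pool_cfg <- fit_config(config$n_inducing, max(config$n_iter, 20),
                           max(config$n_restarts, 2))
    init <- fit_gp(pool, config = pool_cfg, warp = warp, seed = seed)$hyp
  }
  out <- lapply(seq_along(observations), function(i)
    fit_gp(observations[[i]], config = config, warp = warp, init = init,
           seed = if (!is.null(seed)) seed + i))
  names(out) <- names(observations)
  out
}

#' Hierarchically cluster per-ROI GP mean functions
#'
#' Evaluates each model's posterior mean on a shared grid and applies
#' agglomerative clustering with Euclidean distance and the Ward criterion.
#'
#' @param models Named list of `fitted_gp` models, one per ROI.
#' @param grid Shared prediction grid.
#' @param normalize If `TRUE`, z-score each mean vector before clustering
#'   (default `FALSE`: raw mean signals are clustered).
#' @return Object of class `roi_dendrogram`: the `hclust` tree, the ROI ids,
#'   the grid and the matrix of mean vectors.
#' @export
cluster_mean_functions <- function(models, grid, normalize = FALSE) {
  stopifnot(length(models) >= 2L)
  ids <- names(models)
  if (is.null(ids)) ids <- paste0("roi", seq_along(models))
  means <- t(vapply(models, function(m) predict(m, grid)$mean,
                    numeric(length(grid))))
  bad <- !apply(means, 1, function(v) all(is.finite(v)))
  if (any(bad))
    stop("non-finite mean vector for ROI(s): ",
         paste(ids[bad], collapse = ", "))
  rownames(means) <- ids
  cl_mat <- if (normalize) t(scale(t(means))) else means
  hc <- stats::hclust(stats::dist(cl_mat), method = "ward.D2")
  hc$labels <- ids
  structure(list(hclust = hc, roi_ids = ids, grid = grid, means = means),
            class = "roi_dendrogram")
}

#' @export
print.roi_dendrogram <- function(x, ...) {
  cat("<roi_dendrogram>", length(x$roi_ids),
      "ROIs, Ward linkage on Euclidean distances\n")
  invisible(x)
}

# leaves under each side of an hclust internal node (row of merge)
node_children <- function(hc, node) {
  get_leaves <- function(id) {
    if (id < 0) return(-id)
    unlist(lapply(hc$merge[id, ], get_leaves))
  }
  list(left = get_leaves(hc$merge[node, 1]),
       right = get_leaves(hc$merge[node, 2]))
}

#' Test one dendrogram split with the GP equality test
#'
#' Pools the observations of the ROIs on each side of the node, fits one GP
#' per side, and runs the EC equality test against a bootstrap null drawn
#' from the node-pooled observations. The split is accepted (the two
#' children are deemed distinct) when the empirical p-value falls below
#' `alpha`; alternatively a percentile criterion (observed EC exceeding the
#' given null percentile) can be used.
#'
#' @param obs_left,obs_right Lists of [obs_set()] (one per ROI on each
#'   side); singleton sides are allowed.
#' @param grid Prediction grid.
#' @param z,alpha Headline threshold and level (defaults 3 and 0.01).
#' @param criterion `"alpha"` (default; reject equality if p < alpha) or
#'   `"percentile"` (observed EC must exceed the `percentile` quantile of
#'   the null).
#' @param percentile Null percentile for the percentile criterion (default
#'   0.995).
#' @param n_reps,sample_size Bootstrap settings; `sample_size` is reduced to
#'   half the pool (with a warning) when the pool is too small.
#' @param pool_warm_start Fit the node-pooled observations once (capped at
#'   `pool_cap` samples) and warm-start the side and replicate fits from
#'   that fit's hyperparameters (default `TRUE`); keeps the chance-region
#'   rates of the side fits and the null replicates comparable.
#' @param pool_cap Observation cap for the pooled warm-start fit.
#' @param match_sample_sizes If `TRUE` (default), the observed EC is
#'   computed from side fits on random subsamples of `sample_size`
#'   observations per side, fitted with the same configuration as the null
#'   replicates, so the observed statistic and the null are exchangeable
#'   when the split is uninformative; `FALSE` fits each side on all of its
#'   observations.
#' @param config,boot_config,warp,seed As in [equality_test()].
#' @return List with `ec`, `p`, `decision` (`TRUE` = split accepted) and
#'   the full `ec_test` object.
#' @export
test_split_node <- function(obs_left, obs_right, grid = NULL, z = 3,
                            alpha = 0.01,
                            criterion = c("alpha", "percentile"),
                            percentile = 0.995, n_reps = 500,
                            sample_size = 300, config = fit_config(),
                            boot_config = NULL, warp = NULL,
                            pool_warm_start = TRUE, pool_cap = 600,
                            match_sample_sizes = TRUE, seed = NULL) {
  criterion <- match.arg(criterion)
  if (inherits(obs_left, "obs_set")) obs_left <- list(obs_left)
  if (inherits(obs_right, "obs_set")) obs_right <- list(obs_right)
  o1 <- pool_observations(obs_left, roi_id = "left")
  o2 <- pool_observations(obs_right, roi_id = "right")
  pool_n <- length(o1) + length(o2)
  if (pool_n < 2 * sample_size) {
    sample_size <- floor(pool_n / 2)
    warning("bootstrap sample size reduced to ", sample_size,
            " (pool of ", pool_n, " observations)")
  }
  init <- NULL
  if (pool_warm_start) {
    node_pool <- pool_observations(o1, o2)
    if (!is.null(seed)) set.seed(seed)
    if (length(node_pool) > pool_cap)
      node_pool <- obs_subset(node_pool,
                              sort(sample.int(length(node_pool), pool_cap)))
    pool_cfg <- fit_config(config$n_inducing, max(config$n_iter, 20),
                           max(config$n_restarts, 2))
    init <- fit_gp(node_pool, config = pool_cfg, warp = warp,
                   seed = seed)$hyp
  }
  if (match_sample_sizes) {
    if (length(o1) > sample_size)
      o1 <- obs_subset(o1, sort(sample.int(length(o1), sample_size)))
    if (length(o2) > sample_size)
      o2 <- obs_subset(o2, sort(sample.int(length(o2), sample_size)))
    if (is.null(boot_config))
      boot_config <- fit_config(config$n_inducing, config$n_iter, 1)
    config <- boot_config
  }
  tst <- equality_test(o1, o2, grid = grid, z = z, alpha = alpha,
                       n_reps = n_reps, sample_size = sample_size,
                       config = config, boot_config = boot_config,
                       warp = warp, init = init, seed = seed)
  zi <- which.min(abs(tst$z_grid - z))
  decision <- if (criterion == "alpha") tst$reject else
    tst$ec[zi] > stats::quantile(tst$null[, zi], percentile, type = 1)
  list(ec = tst$ec[zi], p = tst$p_value, decision = decision, test = tst)
}

#' Validate a dendrogram top-down and return the accepted partition
#'
#' Starting at the root, each node's split is tested with
#' [test_split_node()]; an accepted split recurses into both children,
#' while a rejected split stops and the node's leaves form one accepted
#' cluster. The result is a frontier of the tree: every ROI belongs to
#' exactly one accepted cluster. An audit trail records the tested nodes in
#' traversal order.
#'
#' @param dendrogram A `roi_dendrogram` from [cluster_mean_functions()].
#' @param observations Named list of [obs_set()] keyed by ROI id.
#' @param ... Passed to [test_split_node()] (grid, alpha, bootstrap
#'   settings, configs, warp).
#' @param seed Optional integer seed; node tests are seeded deterministically
#'   from it.
#' @return Object of class `cluster_assignment`: `assignment` (data.frame
#'   `roi_id`, `cluster`), `n_clusters`, `audit` (data.frame `node`, `ec`,
#'   `p`, `decision` in traversal order).
#' @export
prune_dendrogram <- function(dendrogram, observations, ..., seed = NULL) {
  stopifnot(inherits(dendrogram, "roi_dendrogram"))
  hc <- dendrogram$hclust
  ids <- dendrogram$roi_ids
  missing_ids <- setdiff(ids, names(observations))
  if (length(missing_ids))
    stop("observations missing for ROI(s): ",
         paste(missing_ids, collapse = ", "))
  audit <- data.frame(node = integer(0), ec = integer(0), p = numeric(0),
                      decision = logical(0))
  clusters <- list()
  node_count <- 0L

  visit <- function(node) {
    # node > 0: internal node (row of merge); node < 0: leaf
    if (node < 0) {
      clusters[[length(clusters) + 1L]] <<- ids[-node]
      return(invisible())
    }
    ch <- node_children(hc, node)
    node_count <<- node_count + 1L
    res <- test_split_node(
      lapply(ids[ch$left], function(i) observations[[i]]),
      lapply(ids[ch$right], function(i) observations[[i]]),
      ...,
      seed = if (!is.null(seed)) seed + 17L * node_count)
    audit[nrow(audit) + 1L, ] <<- list(node, res$ec, res$p, res$decision)
    if (res$decision) {
      visit(hc$merge[node, 1])
      visit(hc$merge[node, 2])
    } else {
      clusters[[length(clusters) + 1L]] <<- ids[c(ch$left, ch$right)]
    }
  }
  visit(nrow(hc$merge))

  assignment <- do.call(rbind, lapply(seq_along(clusters), function(k)
    data.frame(roi_id = clusters[[k]], cluster = k)))
  assignment <- assignment[match(ids, assignment$roi_id), ]
  rownames(assignment) <- NULL
  structure(list(assignment = assignment, n_clusters = length(clusters),
                 audit = audit, dendrogram = dendrogram),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("<cluster_assignment>", x$n_clusters, "accepted cluster(s) over",
      nrow(x$assignment), "ROIs;", nrow(x$audit), "node(s) tested\n")
  invisible(x)
}

#' Response-quality pre-filter for clustering
#'
#' Optional gate emulating a baseline-variability criterion: the baseline
#' standard deviation is computed from the posterior mean over the 500 ms
#' preceding the light step, and ROIs whose step-response amplitude is
#' within `k` baseline sds of their overall mean signal are flagged for
#' exclusion.
#'
#' @param models Named list of `fitted_gp`.
#' @param step_time Light-step onset time in seconds (default 2 for the
#'   chirp protocol).
#' @param step_window Seconds after the step over which the response
#'   amplitude is taken (default 1).
#' @param k Exclusion threshold in baseline sds (default 2).
#' @return Logical vector (TRUE = keep), named by ROI.
#' @export
filter_responsive_rois <- function(models, step_time = 2, step_window = 1,
                                   k = 2) {
  vapply(models, function(m) {
    gb <- seq(max(step_time - 0.5, 0), step_time, length.out = 32)
    gs <- seq(step_time, step_time + step_window, length.out = 64)
    base <- predict(m, gb)$mean
    step <- predict(m, gs)$mean
    overall <- mean(c(base, step))
    amp <- max(abs(step - overall))
    # baseline variability of the observed activity: spread of the mean
    # signal in the baseline window plus the fitted observation noise
    base_sd <- sqrt(stats::sd(base)^2 + m$hyp$noise_sd^2)
    amp > k * base_sd
  }, logical(1))
}

#' Export a dendrogram in Newick format
#'
#' Merge heights become branch lengths via [ape::as.phylo()].
#'
#' @param dendrogram A `roi_dendrogram`.
#' @param path Output file path.
#' @export
export_dendrogram_newick <- function(dendrogram, path) {
  ape::write.tree(ape::as.phylo(dendrogram$hclust), file = path)
  invisible(path)
}

#' Export a cluster partition to CSV
#'
#' @param assignment A `cluster_assignment`.
#' @param path Output file path; columns `(roi_id, cluster)`.
#' @export
export_partition_csv <- function(assignment, path) {
  utils::write.csv(assignment$assignment, path, row.names = FALSE)
  invisible(path)
}
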