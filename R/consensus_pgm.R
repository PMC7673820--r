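# End-to-end model interface: expression + base partitions in, classed fit
# object out. Mirrors the pipeline order: CH weights -> weighted consensus ->
# binarization -> KNN Laplacian -> multi-restart factor fit -> argmax
# assignment.

#' Consensus clustering of cells by graph-regularized Bernoulli factorization
#'
#' Fuses M base clusterings of the same cells into a weighted consensus
#' co-membership matrix (weights proportional to each base clustering's
#' Calinski-Harabasz index in log1p-CPM feature space), binarizes it at
#' `wt`, and factorizes the result with a symmetric Bernoulli factor model:
#' each consensus entry is Bernoulli with probability
#' \eqn{1 - e^{-\sum_z h_{iz} h_{jz}}}, factor columns carry
#' automatic-relevance-determination scale priors that prune unused columns
#' (so the cluster count C is determined automatically), and a
#' k-nearest-neighbour graph Laplacian penalty on the expression feature
#' space ties factors to the data manifold, buffering weak base
#' clusterings. Hard labels are the row-wise argmax of the fitted factor
#' matrix.
#'
#' @param x Expression matrix (cells x genes). A `"counts"`-layer matrix is
#'   CPM-normalized and log1p-transformed internally; a `"cpm"` layer is
#'   log1p-transformed; a `"logcpm"` layer is used as-is.
#' @param partitions List of `cell_partition` base clusterings over the
#'   same cells (a single partition is accepted and gets weight 1).
#' @param wt Consensus binarization threshold in (0, 1); default 0.5.
#' @param knn_k Neighbourhood size of the regularization graph; default 10.
#' @param n_pcs Optional number of principal components to reduce the
#'   feature space to before the KNN graph and CH scores; default `NULL`
#'   (no reduction).
#' @param ch_variant Calinski-Harabasz formula variant, see
#'   [calinski_harabasz()].
#' @param binarize Use the binarized consensus in the likelihood (default
#'   `TRUE`); `FALSE` keeps the weighted consensus, an exploratory variant.
#' @param control A [pgm_control()] list of model parameters (Q, alpha,
#'   hyperparameters, stopping rule, restarts, seed).
#' @param truth Optional reference `cell_partition`; when given, adjusted
#'   Rand index and normalized mutual information of the result against it
#'   are stored in the fit.
#' @return An object of class `consensus_pgm` with components `assignment`
#'   (a `cluster_assignment`), `fit` (the winning `pgm_fit`), `weights`
#'   (`ensemble_weights`), `consensus` (the matrix used in the likelihood),
#'   `graph`, `control`, `n_cells`, `n_methods`, `metrics` (ARI/NMI if
#'   `truth` given) and `call`. Methods: `print`, `summary`, `coef`
#'   (the factor matrix), `fitted` (labels as a named factor), `plot`
#'   (objective trace).
#' @examples
#' sim <- simulate_ensemble(simulation_scenario(n_cells = 60, n_clusters = 3,
#'                                              seed = 7))
#' fit <- consensus_pgm(sim$expression, sim$partitions,
#'                      control = pgm_control(q_max = 10, n_restarts = 2,
#'                                            seed = 7),
#'                      truth = sim$truth)
#' fit
#' @export
consensus_pgm <- function(x, partitions, wt = 0.5, knn_k = 10,
                          n_pcs = NULL,
                          ch_variant = c("standard", "printed"),
                          binarize = TRUE,
                          control = pgm_control(), truth = NULL) {
  ch_variant <- match.arg(ch_variant)
  cl <- match.call()
  if (inherits(partitions, "cell_partition")) partitions <- list(partitions)
  if (length(partitions) < 1L) stop("need at least one base partition")

  features <- switch(expr_layer(x),
                     counts = log_transform(cpm_normalize(x)),
                     cpm = log_transform(x),
                     logcpm = x)
  if (!is.null(n_pcs)) {
    n_pcs <- min(n_pcs, nrow(features) - 1L, ncol(features))
    features <- stats::prcomp(features, rank. = n_pcs)$x
  }

  scores <- vapply(partitions, function(p)
    calinski_harabasz(features, p, variant = ch_variant), numeric(1))
  names(scores) <- vapply(partitions, `[[`, character(1), "method")
  weights <- normalize_weights(scores)

  w <- consensus_matrix(partitions, weights)
  w_used <- if (binarize) binarize_consensus(w, wt) else w

  graph <- if (control$alpha > 0) knn_graph(features, k = knn_k) else NULL
  fit <- pgm_fit(w_used, graph, control)
  assignment <- assign_clusters(fit)

  metrics <- NULL
  if (!is.null(truth)) {
    pred <- as_partition(assignment)
    metrics <- c(ari = adjusted_rand_index(pred, truth),
                 nmi = normalized_mutual_information(pred, truth))
  }
  structure(list(assignment = assignment, fit = fit, weights = weights,
                 consensus = w_used, graph = graph, control = control,
                 n_cells = nrow(w_used), n_methods = length(partitions),
                 wt = if (binarize) wt else NA_real_,
                 metrics = metrics, call = cl),
            class = "consensus_pgm")
}

#' @method print consensus_pgm
#' @export
print.consensus_pgm <- function(x, ...) {
  cat("Consensus clustering (graph-regularized Bernoulli factorization)\n")
  cat("  cells: ", x$n_cells, ", base methods: ", x$n_methods,
      ", alpha = ", x$control$alpha,
      if (x$control$alpha == 0) " (graph regularization off)", "\n", sep = "")
  cat("  recovered clusters C = ", x$assignment$n_clusters, "\n", sep = "")
  cat("  objective = ", format(x$fit$objective),
      " (restart ", x$fit$restart_index, "/",
      x$control$n_restarts, ")\n", sep = "")
  if (!is.null(x$metrics))
    cat("  vs truth: ARI = ", round(x$metrics["ari"], 4),
        ", NMI = ", round(x$metrics["nmi"], 4), "\n", sep = "")
  invisible(x)
}

#' @method summary consensus_pgm
#' @export
summary.consensus_pgm <- function(object, ...) {
  out <- list(n_cells = object$n_cells,
              n_methods = object$n_methods,
              n_clusters = object$assignment$n_clusters,
              cluster_sizes = table(object$assignment$label),
              weights = data.frame(method = object$weights$methods,
                                   ch_score = object$weights$scores,
                                   weight = object$weights$weights),
              beta = object$fit$beta,
              objective = object$fit$objective,
              converged = object$fit$converged,
              metrics = object$metrics)
  class(out) <- "summary.consensus_pgm"
  out
}

#' @method print summary.consensus_pgm
#' @export
print.summary.consensus_pgm <- function(x, ...) {
  cat("Consensus clustering summary\n")
  cat(" ", x$n_cells, "cells,", x$n_methods, "base methods,",
      x$n_clusters, "recovered clusters\n")
  cat("  cluster sizes:\n")
  print(x$cluster_sizes)
  cat("  ensemble weights:\n")
  print(x$weights, row.names = FALSE)
  cat("  objective:", format(x$objective),
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  if (!is.null(x$metrics))
    cat("  ARI =", round(x$metrics["ari"], 4),
        " NMI =", round(x$metrics["nmi"], 4), "\n")
  invisible(x)
}

#' @export
coef.consensus_pgm <- function(object, ...) object$fit$h_star

#' @export
fitted.consensus_pgm <- function(object, ...) {
  stats::setNames(factor(object$assignment$label),
                  object$assignment$cell_id)
}

#' @export
plot.consensus_pgm <- function(x, ...) {
  graphics::plot(seq_along(x$fit$objective_trace), x$fit$objective_trace,
                 type = "l", xlab = "iteration",
                 ylab = "objective (negative log joint)",
                 main = "Objective trace of the winning restart", ...)
  invisible(x)
}

#' Grid search over the prior scale b and regularization strength alpha
#'
#' Refits the model for every (b, alpha) pair and scores the result against
#' a reference partition. Uses a reduced restart count by default, since a
#' full multi-restart fit at every grid cell is rarely worth it at desk
#' scale.
#'
#' @inheritParams consensus_pgm
#' @param truth Reference `cell_partition` to score against (required).
#' @param b_grid Values of the hyperparameter b; default `seq(0.1, 0.6,
#'   by = 0.1)`.
#' @param alpha_grid Values of alpha; default `seq(50, 950, by = 100)`.
#' @param control Base control; its `hyper_b` and `alpha` are overridden at
#'   each grid cell.
#' @return Data frame with one row per grid cell: `b`, `alpha`, `ari`,
#'   `nmi`, `n_clusters`, `objective`.
#' @export
parameter_sweep <- function(x, partitions, truth,
                            b_grid = seq(0.1, 0.6, by = 0.1),
                            alpha_grid = seq(50, 950, by = 100),
                            wt = 0.5, knn_k = 10,
                            control = pgm_control(n_restarts = 5)) {
  if (length(b_grid) == 0L || length(alpha_grid) == 0L)
    stop("empty parameter grid")
  grid <- expand.grid(b = b_grid, alpha = alpha_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    ctrl <- control
    ctrl$hyper_b <- grid$b[i]
    ctrl$alpha <- grid$alpha[i]
    res <- consensus_pgm(x, partitions, wt = wt, knn_k = knn_k,
                         control = ctrl, truth = truth)
    data.frame(b = grid$b[i], alpha = grid$alpha[i],
               ari = unname(res$metrics["ari"]),
               nmi = unname(res$metrics["nmi"]),
               n_clusters = res$assignment$n_clusters,
               objective = res$fit$objective)
  })
  do.call(rbind, rows)
}
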