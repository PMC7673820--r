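# Core factor model. The binarized consensus matrix W is modelled entrywise
# as Bernoulli with success probability 1 - exp(-sum_z h_iz h_jz); each
# factor column carries a zero-mean Gaussian prior with scale beta_z, and the
# beta_z carry an inverse-Gamma(a, b) hyperprior. Small beta_z drive whole
# columns of H toward zero, so the number of surviving columns is the number
# of clusters (automatic relevance determination). A KNN-graph Laplacian
# penalty alpha * tr(H' L H) ties the factors to the expression manifold.
#
# The negative log joint (additive constants dropped, pairs i < j only):
#   F(H, beta) = sum_{i<j} [ (1 - w_ij) s_ij - w_ij log(1 - exp(-s_ij)) ]
#              + sum_z [ sum_i h_iz^2 / (2 beta_z) + (n/2) log beta_z ]
#              + sum_z [ (a + 1) log beta_z + b / beta_z ]
#              + alpha * tr(H' L H),      s_ij = sum_z h_iz h_jz.
# H is lowered by a damped multiplicative rule (never leaves the nonnegative
# orthant, zeros stay zero); beta has an exact closed-form minimizer.

#' Control parameters for the consensus factor model
#'
#' @param q_max Initial number of factor columns Q (upper bound on the
#'   cluster count); default 25.
#' @param alpha Graph regularization strength; `alpha = 0` disables the
#'   Laplacian penalty entirely. Default 100.
#' @param hyper_a Shape hyperparameter of the inverse-Gamma prior on the
#'   column scales; default 1.
#' @param hyper_b Scale hyperparameter of the same prior; default 0.3.
#' @param rho Convergence threshold on the Frobenius norm of the change in
#'   beta between iterations; default 1e-5.
#' @param max_iter Maximum iterations per restart; default 100.
#' @param n_restarts Number of random restarts, the best (lowest objective)
#'   of which is returned; default 50.
#' @param seed Base RNG seed; restart r uses `seed + r - 1`.
#' @param prune_tol Columns whose entries all fall below this value are
#'   considered pruned away; default 1e-4.
#' @param eps Numerical floor applied to `1 - exp(-s)` and to update
#'   denominators; default 1e-12.
#' @return A validated list of class `pgm_control`.
#' @export
pgm_control <- function(q_max = 25L, alpha = 100, hyper_a = 1, hyper_b = 0.3,
                        rho = 1e-5, max_iter = 100L, n_restarts = 50L,
                        seed = 1L, prune_tol = 1e-4, eps = 1e-12) {
  stopifnot(q_max >= 1, alpha >= 0, hyper_a > 0, hyper_b > 0, rho > 0,
            max_iter >= 1, n_restarts >= 1, prune_tol > 0, eps > 0)
  structure(list(q_max = as.integer(q_max), alpha = alpha,
                 hyper_a = hyper_a, hyper_b = hyper_b, rho = rho,
                 max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), prune_tol = prune_tol, eps = eps),
            class = "pgm_control")
}

#' Random initialization of the factor matrix
#'
#' Entries drawn independently uniform on (0.01, 1), deterministic given the
#' seed.
#'
#' @param n Number of cells.
#' @param q_max Number of factor columns.
#' @param seed RNG seed.
#' @return Nonnegative n x q_max matrix.
#' @export
init_factors <- function(n, q_max, seed = 1L) {
  stopifnot(n >= 1, q_max >= 1)
  with_seed(seed, matrix(stats::runif(n * q_max, 0.01, 1), n, q_max))
}

# 1 - exp(-S) computed stably and floored away from zero where it divides or
# is logged.
.bern_prob <- function(s, eps) pmax(-expm1(-s), eps)

#' Negative log joint objective of the factor model
#'
#' Evaluates the penalized negative log joint probability (additive
#' constants dropped): Bernoulli likelihood of the binarized consensus over
#' unordered cell pairs, half-normal column priors with scales `beta`,
#' inverse-Gamma hyperprior on `beta`, plus `alpha` times the graph penalty.
#'
#' @param w Binarized (or weighted, if exploring that variant) symmetric
#'   consensus matrix.
#' @param h Nonnegative n x Q factor matrix.
#' @param beta Positive length-Q scale vector.
#' @param graph Optional `knn_graph`; required when `alpha > 0`.
#' @param alpha Graph regularization strength.
#' @param hyper_a,hyper_b Inverse-Gamma hyperparameters.
#' @param eps Floor applied inside `log(1 - exp(-s))`.
#' @return A single number (lower is better).
#' @export
pgm_objective <- function(w, h, beta, graph = NULL, alpha = 0,
                          hyper_a = 1, hyper_b = 0.3, eps = 1e-12) {
  h <- as.matrix(h)
  n <- nrow(h)
  if (nrow(w) != n || ncol(w) != n)
    stop("consensus matrix and factor matrix disagree on the number of cells")
  if (any(beta <= 0)) stop("beta must be strictly positive")
  s <- tcrossprod(h)
  p <- .bern_prob(s, eps)
  ut <- upper.tri(s)
  lik <- sum((1 - w[ut]) * s[ut]) - sum(w[ut] * log(p[ut]))
  prior_h <- sum(sweep(h^2, 2L, 2 * beta, "/")) + (n / 2) * sum(log(beta))
  prior_b <- (hyper_a + 1) * sum(log(beta)) + hyper_b * sum(1 / beta)
  reg <- 0
  if (alpha > 0) {
    if (is.null(graph)) stop("`graph` is required when alpha > 0")
    reg <- alpha * graph_penalty(h, graph)
  }
  lik + prior_h + prior_b + reg
}

#' One damped multiplicative update of the factor matrix
#'
#' \deqn{h_{iz} \leftarrow \tfrac12 h_{iz} + \tfrac12 h_{iz}
#'   \frac{\sum_{j \ne i} w_{ij} h_{jz} / (1 - e^{-s_{ij}})
#'         + 2\alpha \sum_j v_{ij} h_{jz}}
#'        {\sum_{j \ne i} h_{jz} + h_{iz}/\beta_z + 2\alpha d_i h_{iz}}}
#' The ratio is the negative over positive part of the objective gradient
#' (the factor 2 on the graph terms is the gradient of the quadratic
#' penalty \eqn{\alpha\,\mathrm{tr}(H^\top L H)}, whose derivative is
#' \eqn{2\alpha L H}), so fixed points of the update are exactly stationary
#' points of the objective; the damping halves the step. Nonnegativity is
#' preserved and exact zeros stay zero.
#'
#' @inheritParams pgm_objective
#' @return Updated factor matrix of the same shape.
#' @export
update_h <- function(w, h, beta, graph = NULL, alpha = 0, eps = 1e-12) {
  h <- as.matrix(h)
  n <- nrow(h)
  q <- ncol(h)
  s <- tcrossprod(h)
  p <- .bern_prob(s, eps)
  wn <- w
  diag(wn) <- 0
  num <- (wn / p) %*% h
  den <- matrix(colSums(h), n, q, byrow = TRUE) - h +
    sweep(h, 2L, beta, "/")
  if (alpha > 0) {
    if (is.null(graph)) stop("`graph` is required when alpha > 0")
    num <- num + 2 * alpha * (graph$adjacency %*% h)
    den <- den + 2 * alpha * (graph$degrees * h)
  }
  0.5 * h + 0.5 * h * num / pmax(den, eps)
}

#' Closed-form update of the column scales
#'
#' \deqn{\beta_z \leftarrow \frac{2b + \sum_i h_{iz}^2}{n + 2a + 2}}
#' the exact minimizer of the objective in beta for fixed H.
#'
#' @param h Nonnegative n x Q factor matrix.
#' @param hyper_a,hyper_b Inverse-Gamma hyperparameters.
#' @return Positive length-Q vector.
#' @export
update_beta <- function(h, hyper_a = 1, hyper_b = 0.3) {
  h <- as.matrix(h)
  (2 * hyper_b + colSums(h^2)) / (nrow(h) + 2 * hyper_a + 2)
}

#' Fit the graph-regularized Bernoulli consensus factor model
#'
#' Runs `n_restarts` independent restarts. Each restart initializes H at
#' random (seed `seed + r - 1` for restart r), then alternates the
#' multiplicative H update and the closed-form beta update until the change
#' in beta falls below `rho` or `max_iter` is reached. The restart with the
#' lowest final objective wins. Restarts that produce a non-finite
#' objective are abandoned (recorded in `failed_restarts`); an error is
#' raised only if every restart fails.
#'
#' @param w Binarized symmetric consensus matrix (diagonal 1).
#' @param graph Optional `knn_graph` over the same cells; required when
#'   `control$alpha > 0`.
#' @param control A [pgm_control()] list.
#' @return An object of class `pgm_fit`: list with `h_star`, `beta`,
#'   `objective`, `objective_trace`, `n_iterations`, `restart_index`,
#'   `converged`, `restart_objectives`, `failed_restarts` and `control`.
#' @export
pgm_fit <- function(w, graph = NULL, control = pgm_control()) {
  stopifnot(inherits(control, "pgm_control"))
  if (!isSymmetric(unname(w), tol = 1e-8))
    stop("consensus matrix must be symmetric")
  n <- nrow(w)
  if (control$alpha > 0 && is.null(graph))
    stop("`graph` is required when alpha > 0")
  best <- NULL
  restart_obj <- rep(NA_real_, control$n_restarts)
  failed <- character(0)
  for (r in seq_len(control$n_restarts)) {
    h <- init_factors(n, control$q_max, seed = control$seed + r - 1L)
    beta <- update_beta(h, control$hyper_a, control$hyper_b)
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    ok <- TRUE
    while (iter < control$max_iter) {
      iter <- iter + 1L
      h <- update_h(w, h, beta, graph, control$alpha, control$eps)
      beta_new <- update_beta(h, control$hyper_a, control$hyper_b)
      obj <- pgm_objective(w, h, beta_new, graph, control$alpha,
                           control$hyper_a, control$hyper_b, control$eps)
      if (!is.finite(obj)) {
        failed <- c(failed, sprintf(
          "restart %d: non-finite objective at iteration %d", r, iter))
        ok <- FALSE
        break
      }
      trace <- c(trace, obj)
      delta <- sqrt(sum((beta_new - beta)^2))
      beta <- beta_new
      if (delta < control$rho) {
        converged <- TRUE
        break
      }
    }
    if (!ok) next
    restart_obj[r] <- trace[length(trace)]
    if (is.null(best) || restart_obj[r] < best$objective) {
      best <- list(h_star = h, beta = beta,
                   objective = restart_obj[r], objective_trace = trace,
                   n_iterations = iter, restart_index = r,
                   converged = converged)
    }
  }
  if (is.null(best))
    stop("all restarts failed:\n", paste(failed, collapse = "\n"))
  best$restart_objectives <- restart_obj
  best$failed_restarts <- failed
  best$control <- control
  rownames(best$h_star) <- rownames(w)
  class(best) <- "pgm_fit"
  best
}

#' @method print pgm_fit
#' @export
print.pgm_fit <- function(x, ...) {
  cat("Consensus factor model fit\n")
  cat("  cells:      ", nrow(x$h_star), "\n", sep = "")
  cat("  columns Q:  ", ncol(x$h_star),
      " (", sum(apply(x$h_star, 2L, max) > x$control$prune_tol),
      " surviving pruning)\n", sep = "")
  cat("  objective:  ", format(x$objective), "\n", sep = "")
  cat("  restart:    ", x$restart_index, " of ",
      x$control$n_restarts, "\n", sep = "")
  cat("  iterations: ", x$n_iterations,
      if (x$converged) " (converged)" else " (iteration cap)", "\n", sep = "")
  invisible(x)
}
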