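# Ensemble stage: base partitions become binary co-membership matrices,
# internal-validity (Calinski-Harabasz) scores become normalized weights, and
# the weighted sum is thresholded into the binary consensus matrix the factor
# model consumes.

#' Co-membership matrix of a partition
#'
#' Binary symmetric n x n matrix with entry 1 where two cells share a cluster
#' (diagonal all 1).
#'
#' @param p A `cell_partition`.
#' @return Integer 0/1 matrix with cell identifiers as dimnames and the
#'   method name in attribute `"method"`.
#' @export
comembership <- function(p) {
  stopifnot(inherits(p, "cell_partition"))
  b <- outer(p$label, p$label, "==") * 1L
  dimnames(b) <- list(p$cell_id, p$cell_id)
  attr(b, "method") <- p$method
  b
}

#' Calinski-Harabasz index of a partition
#'
#' Ratio of between-cluster to within-cluster scatter in a feature space,
#' used here as a label-free quality score for weighting base clusterings.
#' The default is the standard index
#' \deqn{CH = \frac{\sum_k |C_k| \, \|z_k - z\|^2 / (K-1)}
#'                 {\sum_k \sum_{x \in C_k} \|x - z_k\|^2 / (N-K)}}
#' with cluster centroids \eqn{z_k} and global centroid \eqn{z}.
#' `variant = "printed"` keeps an alternative form (unweighted between-cluster
#' trace and the reciprocal \eqn{(K-1)/(N-K)} factor) for reproduction of
#' reports that used it; since weights only need to rank partitions, the
#' standard form is the default.
#'
#' @param x Numeric feature matrix, cells in rows (typically the log1p-CPM
#'   expression matrix). If it has row names they are used to align `p`.
#' @param p A `cell_partition` with at least two clusters and fewer clusters
#'   than cells.
#' @param variant `"standard"` (default) or `"printed"`.
#' @param zero_within What to do when the within-cluster scatter is exactly
#'   zero: `"error"` (default) or `"infinite"` (return `Inf`).
#' @return A positive number (larger = better-separated clustering).
#' @export
calinski_harabasz <- function(x, p, variant = c("standard", "printed"),
                              zero_within = c("error", "infinite")) {
  variant <- match.arg(variant)
  zero_within <- match.arg(zero_within)
  stopifnot(inherits(p, "cell_partition"))
  x <- as.matrix(x)
  if (!is.null(rownames(x))) p <- align_partition(p, rownames(x))
  if (nrow(x) != length(p$cell_id))
    stop("feature matrix and partition cover different numbers of cells")
  f <- factor(p$label)
  n <- nrow(x)
  k <- nlevels(f)
  if (k < 2L) stop("Calinski-Harabasz needs at least 2 clusters")
  if (n <= k) stop("Calinski-Harabasz needs more cells than clusters (N - K = 0)")
  sizes <- as.numeric(table(f))
  centroids <- rowsum(x, f) / sizes
  global <- colMeans(x)
  centroid_sq <- rowSums(sweep(centroids, 2L, global)^2)
  within <- sum((x - centroids[as.integer(f), , drop = FALSE])^2)
  if (within == 0) {
    if (zero_within == "error")
      stop("within-cluster scatter is zero; index undefined")
    return(Inf)
  }
  if (variant == "standard") {
    between <- sum(sizes * centroid_sq)
    (between / (k - 1)) / (within / (n - k))
  } else {
    sum(centroid_sq) / within * (k - 1) / (n - k)
  }
}

#' Normalize positive quality scores into ensemble weights
#'
#' @param scores Positive numeric vector of length M (one score per base
#'   method), optionally named.
#' @return An object of class `ensemble_weights`: list with `scores`,
#'   `weights` (summing to 1) and `methods`.
#' @export
normalize_weights <- function(scores) {
  scores <- unlist(scores)
  if (length(scores) < 1L) stop("need at least one score")
  if (anyNA(scores) || any(scores <= 0))
    stop("all scores must be positive")
  w <- scores / sum(scores)
  structure(list(scores = unname(scores), weights = unname(w),
                 methods = if (is.null(names(scores)))
                   paste0("method_", seq_along(scores)) else names(scores)),
            class = "ensemble_weights")
}

#' @method print ensemble_weights
#' @export
print.ensemble_weights <- function(x, ...) {
  cat("Ensemble weights (", length(x$weights), " base methods)\n", sep = "")
  print(data.frame(method = x$methods, score = x$scores,
                   weight = x$weights))
  invisible(x)
}

#' Weighted consensus matrix of an ensemble
#'
#' \eqn{W = \sum_p u_p B_p}: the convex combination of co-membership
#' matrices, entry \eqn{w_{ij}} measuring how strongly the ensemble places
#' cells i and j in the same cluster.
#'
#' @param partitions List of `cell_partition` objects over the same cells
#'   (aligned to the first partition's cell ordering).
#' @param weights An `ensemble_weights` object, or a positive numeric vector
#'   of scores to be normalized. Defaults to equal weights.
#' @return Numeric n x n matrix with attributes `binarized = FALSE` and
#'   `threshold = NA`.
#' @export
consensus_matrix <- function(partitions, weights = NULL) {
  if (inherits(partitions, "cell_partition")) partitions <- list(partitions)
  m <- length(partitions)
  if (m < 1L) stop("need at least one base partition")
  if (is.null(weights)) weights <- normalize_weights(rep(1, m))
  if (!inherits(weights, "ensemble_weights"))
    weights <- normalize_weights(weights)
  if (length(weights$weights) != m)
    stop("number of weights (", length(weights$weights),
         ") does not match number of partitions (", m, ")")
  ref <- partitions[[1L]]$cell_id
  w <- matrix(0, length(ref), length(ref), dimnames = list(ref, ref))
  for (i in seq_len(m)) {
    p <- align_partition(partitions[[i]], ref)
    w <- w + weights$weights[i] * comembership(p)
  }
  attr(w, "binarized") <- FALSE
  attr(w, "threshold") <- NA_real_
  w
}

#' Binarize a weighted consensus matrix
#'
#' Entries strictly greater than the threshold become 1 ("more than half of
#' the methods agree" at the default 0.5), all others 0; the diagonal is
#' forced to 1.
#'
#' @param w Weighted consensus matrix from [consensus_matrix()].
#' @param wt Threshold in (0, 1); default 0.5.
#' @return Binary matrix with attributes `binarized = TRUE` and
#'   `threshold = wt`.
#' @export
binarize_consensus <- function(w, wt = 0.5) {
  if (isTRUE(attr(w, "binarized")))
    stop("consensus matrix is already binarized")
  if (!is.numeric(wt) || length(wt) != 1L || wt <= 0 || wt >= 1)
    stop("`wt` must be a single number strictly between 0 and 1")
  b <- (w > wt) * 1
  diag(b) <- 1
  dimnames(b) <- dimnames(w)
  attr(b, "binarized") <- TRUE
  attr(b, "threshold") <- wt
  b
}
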