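# KNN graph over cells in expression feature space; its Laplacian supplies
# the manifold penalty that regularizes the factor model.

#' k-nearest-neighbour graph of cells
#'
#' Finds the k nearest neighbours of every cell by Euclidean distance in the
#' given feature space (self excluded, distance ties broken by lowest cell
#' index) and symmetrizes the directed relation by logical OR: cells i and j
#' are adjacent if either is among the other's k nearest neighbours.
#'
#' @param x Numeric feature matrix, cells in rows (typically log1p-CPM).
#' @param k Number of neighbours, `1 <= k < n`.
#' @return An object of class `knn_graph`: list with binary `adjacency`
#'   (zero diagonal), integer `degrees`, `laplacian` (`L = D - V`) and `k`.
#' @export
knn_graph <- function(x, k = 10) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is.numeric(k) || length(k) != 1L || k < 1L)
    stop("`k` must be a positive integer")
  k <- as.integer(k)
  if (k >= n)
    stop("`k` (", k, ") must be smaller than the number of cells (", n, ")")
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    # order() is stable, so equal distances resolve to the lowest index
    a[i, order(d[i, ])[seq_len(k)]] <- 1
  }
  v <- 1 * ((a + t(a)) > 0)
  dimnames(v) <- list(rownames(x), rownames(x))
  deg <- rowSums(v)
  lap <- diag(deg, n) - v
  dimnames(lap) <- dimnames(v)
  structure(list(adjacency = v, degrees = deg, laplacian = lap, k = k),
            class = "knn_graph")
}

#' @method print knn_graph
#' @export
print.knn_graph <- function(x, ...) {
  cat("KNN graph: ", nrow(x$adjacency), " cells, k = ", x$k, ", ",
      sum(x$adjacency) / 2, " edges\n", sep = "")
  invisible(x)
}

#' Graph smoothness penalty of a factor matrix
#'
#' \deqn{R_1 = \tfrac12 \sum_{i,j} \sum_z (h_{iz} - h_{jz})^2 v_{ij}
#'           = \mathrm{tr}(H^\top L H),}
#' zero when adjacent cells have identical factor profiles. Summed over all
#' factor columns, which is the form whose gradient \eqn{\alpha L H} appears
#' in the multiplicative update.
#'
#' @param h Numeric n x Q factor matrix.
#' @param g A `knn_graph` over the same n cells.
#' @return Nonnegative number.
#' @export
graph_penalty <- function(h, g) {
  stopifnot(inherits(g, "knn_graph"))
  h <- as.matrix(h)
  if (nrow(h) != nrow(g$adjacency))
    stop("factor matrix has ", nrow(h), " rows but the graph has ",
         nrow(g$adjacency), " cells")
  sum(h * (g$laplacian %*% h))
}
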