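# Hard assignments are read off the fitted factor matrix by row-wise argmax;
# the number of distinct argmax columns is the recovered cluster count.

#' Extract hard cluster assignments from a fitted factor matrix
#'
#' Each cell is assigned to the column holding its row maximum (ties broken
#' by lowest column index); the distinct columns used are relabelled to
#' consecutive integers 1..C in order of first appearance, and C is the
#' recovered cluster count. Rows whose entries are all at or below
#' `prune_tol` are still assigned by argmax but flagged as low-confidence.
#'
#' @param h_star Fitted factor matrix (or a `pgm_fit` object).
#' @param prune_tol Threshold below which a whole row counts as
#'   low-confidence; defaults to the fit's own `prune_tol` when a `pgm_fit`
#'   is supplied, else 1e-4.
#' @param cell_ids Cell identifiers (defaults to row names).
#' @return An object of class `cluster_assignment`: list with `cell_id`,
#'   integer `label` in 1..C, `n_clusters`, `source_columns` (the original
#'   H column index behind each output label) and `low_confidence` (cell
#'   identifiers of flagged rows).
#' @export
assign_clusters <- function(h_star, prune_tol = NULL, cell_ids = NULL) {
  if (inherits(h_star, "pgm_fit")) {
    if (is.null(prune_tol)) prune_tol <- h_star$control$prune_tol
    h_star <- h_star$h_star
  }
  if (is.null(prune_tol)) prune_tol <- 1e-4
  h <- as.matrix(h_star)
  if (is.null(cell_ids)) cell_ids <- rownames(h)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(h)))
  argmax <- max.col(h, ties.method = "first")
  cols <- unique(argmax)
  labels <- match(argmax, cols)
  low <- cell_ids[apply(h, 1L, max) <= prune_tol]
  structure(list(cell_id = as.character(cell_ids),
                 label = as.integer(labels),
                 n_clusters = length(cols),
                 source_columns = cols,
                 low_confidence = low),
            class = "cluster_assignment")
}

#' @method print cluster_assignment
#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Cluster assignment: ", length(x$cell_id), " cells in ",
      x$n_clusters, " clusters\n", sep = "")
  print(table(cluster = x$label))
  if (length(x$low_confidence))
    cat("low-confidence cells: ", length(x$low_confidence), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cluster_assignment <- function(x, ...) {
  data.frame(cell_id = x$cell_id, cluster = x$label,
             stringsAsFactors = FALSE)
}

#' Convert a cluster assignment to a cell partition
#'
#' @param x A `cluster_assignment`.
#' @param method Method name for the resulting partition.
#' @return A `cell_partition`.
#' @export
as_partition <- function(x, method = "consensus_pgm") {
  stopifnot(inherits(x, "cluster_assignment"))
  partition(x$label, cell_ids = x$cell_id, method = method)
}
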