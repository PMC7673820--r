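# External validation indices computed from the contingency table of two
# partitions over the same cells.

.contingency <- function(p1, p2) {
  if (inherits(p1, "cell_partition") && inherits(p2, "cell_partition")) {
    if (!setequal(p1$cell_id, p2$cell_id))
      stop("the two partitions cover different cell sets")
    p2 <- align_partition(p2, p1$cell_id)
    l1 <- p1$label
    l2 <- p2$label
  } else {
    l1 <- if (inherits(p1, "cell_partition")) p1$label else as.character(p1)
    l2 <- if (inherits(p2, "cell_partition")) p2$label else as.character(p2)
    if (length(l1) != length(l2))
      stop("label vectors have different lengths")
  }
  table(l1, l2)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} -
#'   \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}
#'   {\tfrac12[\sum_i\binom{a_i}{2}+\sum_j\binom{b_j}{2}] -
#'   \sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}/\binom{n}{2}}}
#' over the contingency table with cell counts \eqn{n_{ij}} and margins
#' \eqn{a_i, b_j}. Equals 1 for identical partitions (including the
#' degenerate cases where the denominator vanishes) and is near 0 for
#' independent ones.
#'
#' @param p1,p2 `cell_partition` objects over the same cells (aligned by
#'   cell identifier), or plain label vectors of equal length.
#' @return A number no greater than 1.
#' @export
adjusted_rand_index <- function(p1, p2) {
  tab <- .contingency(p1, p2)
  comb2 <- function(x) x * (x - 1) / 2
  n <- sum(tab)
  if (n < 2) stop("need at least two cells")
  sum_nij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_nij - expected) / (maximum - expected)
}

#' Normalized mutual information between two partitions
#'
#' \deqn{NMI = \frac{2 \sum_{ij} p_{ij} \log\frac{p_{ij}}{p_i p_j}}
#'   {-\sum_i p_i \log p_i - \sum_j p_j \log p_j}}
#' with joint frequencies \eqn{p_{ij} = n_{ij}/n} and margins
#' \eqn{p_i, p_j}; terms with \eqn{p_{ij} = 0} contribute zero, and the
#' logarithm base cancels in the ratio. When both partitions are a single
#' cluster (zero denominator) the partitions are identical and 1 is
#' returned.
#'
#' @inheritParams adjusted_rand_index
#' @return A number in \[0, 1\].
#' @export
normalized_mutual_information <- function(p1, p2) {
  tab <- .contingency(p1, p2)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  h1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h2 <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (h1 + h2 == 0) return(1)
  outer_p <- outer(pi_, pj_)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer_p[nz]))
  2 * mi / (h1 + h2)
}
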