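# Synthetic benchmark generator. Produces a ground-truth partition, an
# expression-like matrix with marker-gene block structure, and a set of base
# clusterings degraded from the truth by merge/split operations and
# independent label noise — everything the pipeline consumes, reproducible
# from one seed.

#' Define a simulation scenario
#'
#' Cells belong to `n_clusters` ground-truth types. Genes are split into one
#' contiguous marker block per type; a cell's expression is Gaussian noise
#' around a baseline of `5 * noise_sd`, elevated by `separation` on its own
#' type's marker block, floored at zero, with a fraction `zero_inflation` of
#' entries independently zeroed (mimicking dropout). Each of `n_methods`
#' base clusterings is the truth degraded by optional merge/split operations
#' and per-cell label noise.
#'
#' @param n_cells Number of cells; default 200.
#' @param n_genes Number of genes; default 50.
#' @param n_clusters Number of ground-truth cell types; default 5.
#' @param cluster_proportions Mixing proportions (default equal); must sum
#'   to 1.
#' @param separation Mean shift on a type's marker genes, in feature units;
#'   default 5 (well-separated at the default noise).
#' @param noise_sd Within-type Gaussian noise standard deviation; default 1.
#' @param zero_inflation Probability that an entry is zeroed (mimicking
#'   dropout); optional, default 0, in \[0, 1).
#' @param n_methods Number of base clusterings M; default 4.
#' @param label_noise Per-method label noise rates in \[0, 1); default
#'   `c(0.05, 0.10, 0.15, 0.20)`.
#' @param structural_ops Optional list (length `n_methods`) of per-method
#'   operation lists; see [perturb_partition()].
#' @param seed RNG seed driving the whole scenario.
#' @return A validated list of class `sim_scenario`.
#' @export
simulation_scenario <- function(n_cells = 200L, n_genes = 50L,
                                n_clusters = 5L,
                                cluster_proportions = NULL,
                                separation = 5, noise_sd = 1,
                                zero_inflation = 0,
                                n_methods = 4L,
                                label_noise = c(0.05, 0.10, 0.15, 0.20),
                                structural_ops = NULL,
                                seed = 1L) {
  stopifnot(n_cells >= 1, n_genes >= 1, n_methods >= 1,
            separation >= 0, noise_sd > 0,
            zero_inflation >= 0, zero_inflation < 1)
  if (n_clusters > n_cells)
    stop("more ground-truth clusters (", n_clusters, ") than cells (",
         n_cells, ")")
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  if (length(cluster_proportions) != n_clusters)
    stop("`cluster_proportions` must have length `n_clusters`")
  if (abs(sum(cluster_proportions) - 1) > 1e-8)
    stop("`cluster_proportions` must sum to 1")
  if (length(label_noise) == 1L)
    label_noise <- rep(label_noise, n_methods)
  if (length(label_noise) != n_methods)
    stop("`label_noise` must have length `n_methods`")
  if (any(label_noise < 0 | label_noise >= 1))
    stop("label noise rates must lie in [0, 1)")
  if (!is.null(structural_ops) && length(structural_ops) != n_methods)
    stop("`structural_ops` must be NULL or a list of length `n_methods`")
  structure(list(n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 n_clusters = as.integer(n_clusters),
                 cluster_proportions = cluster_proportions,
                 separation = separation, noise_sd = noise_sd,
                 zero_inflation = zero_inflation,
                 n_methods = as.integer(n_methods),
                 label_noise = label_noise,
                 structural_ops = structural_ops,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate a ground-truth expression matrix and partition
#'
#' @param s A [simulation_scenario()].
#' @return List with `expression` (a counts-layer expression matrix) and
#'   `truth` (a `cell_partition` of the generating types).
#' @export
simulate_truth <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  n <- s$n_cells
  g <- s$n_genes
  c_true <- s$n_clusters
  sizes <- floor(s$cluster_proportions * n)
  # distribute the rounding remainder over the first clusters
  rem <- n - sum(sizes)
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  if (any(sizes == 0)) stop("a cluster received zero cells; increase n_cells")
  labels <- rep(paste0("type", seq_len(c_true)), times = sizes)
  blocks <- split(seq_len(g),
                  sort(rep_len(seq_len(c_true), g)))
  baseline <- 5 * s$noise_sd
  mu <- matrix(baseline, n, g)
  for (k in seq_len(c_true))
    mu[labels == paste0("type", k), blocks[[k]]] <-
      baseline + s$separation
  x <- with_seed(s$seed, {
    vals <- mu + matrix(stats::rnorm(n * g, sd = s$noise_sd), n, g)
    vals <- pmax(vals, 0)
    if (s$zero_inflation > 0)
      vals[matrix(stats::runif(n * g) < s$zero_inflation, n, g)] <- 0
    vals
  })
  rownames(x) <- paste0("cell_", seq_len(n))
  colnames(x) <- paste0("gene_", seq_len(g))
  list(expression = expression_matrix(x, layer = "counts"),
       truth = partition(labels, cell_ids = rownames(x), method = "truth"))
}

#' Degrade a partition into a surrogate base clustering
#'
#' Structural operations run first — `list(op = "merge", clusters =
#' c("A", "B"))` fuses two clusters into one, `list(op = "split", cluster =
#' "A")` divides one uniformly into two — then each cell is independently
#' reassigned, with probability `label_noise`, to a uniformly random
#' existing cluster.
#'
#' @param truth A `cell_partition`.
#' @param label_noise Reassignment probability in \[0, 1).
#' @param structural_ops Optional list of operation lists (see above).
#' @param seed RNG seed.
#' @param method Method name for the perturbed partition.
#' @return A `cell_partition`.
#' @export
perturb_partition <- function(truth, label_noise = 0, structural_ops = NULL,
                              seed = 1L, method = "perturbed") {
  stopifnot(inherits(truth, "cell_partition"),
            label_noise >= 0, label_noise < 1)
  labels <- truth$label
  labels <- with_seed(seed, {
    for (op in structural_ops) {
      if (identical(op$op, "merge")) {
        cl <- as.character(op$clusters)
        if (length(cl) != 2L || !all(cl %in% labels))
          stop("merge references missing cluster(s): ",
               paste(setdiff(cl, labels), collapse = ", "))
        labels[labels %in% cl] <- paste(cl, collapse = "+")
      } else if (identical(op$op, "split")) {
        cl <- as.character(op$cluster)
        idx <- which(labels == cl)
        if (length(idx) == 0L)
          stop("split references missing cluster: ", cl)
        half <- stats::runif(length(idx)) < 0.5
        labels[idx] <- paste0(cl, ifelse(half, ".1", ".2"))
      } else {
        stop("unknown structural op: ", format(op$op))
      }
    }
    if (label_noise > 0) {
      pool <- unique(labels)
      hit <- stats::runif(length(labels)) < label_noise
      labels[hit] <- sample(pool, sum(hit), replace = TRUE)
    }
    labels
  })
  partition(labels, cell_ids = truth$cell_id, method = method)
}

#' Uniformly random partition (an uninformative base clustering)
#'
#' @param cell_ids Cell identifiers.
#' @param n_clusters Number of clusters to draw labels from.
#' @param seed RNG seed.
#' @param method Method name.
#' @return A `cell_partition` with labels drawn i.i.d. uniform.
#' @export
random_partition <- function(cell_ids, n_clusters, seed = 1L,
                             method = "random") {
  stopifnot(n_clusters >= 1)
  labels <- with_seed(seed,
    sample(paste0("rand", seq_len(n_clusters)),
           length(cell_ids), replace = TRUE))
  partition(labels, cell_ids = cell_ids, method = method)
}

#' Simulate a full ensemble benchmark
#'
#' Draws the ground truth and the M degraded base clusterings of a
#' scenario. Per-method seeds are derived deterministically from the
#' scenario seed.
#'
#' @param s A [simulation_scenario()].
#' @return List with `expression`, `truth`, `partitions` (list of M
#'   `cell_partition`s) and `scenario` (the input scenario, echoed).
#' @export
simulate_ensemble <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  base <- simulate_truth(s)
  parts <- vector("list", s$n_methods)
  for (m in seq_len(s$n_methods)) {
    ops <- if (is.null(s$structural_ops)) NULL else s$structural_ops[[m]]
    parts[[m]] <- perturb_partition(
      base$truth, label_noise = s$label_noise[m], structural_ops = ops,
      seed = s$seed + 1000L + m, method = paste0("method_", m))
  }
  list(expression = base$expression, truth = base$truth,
       partitions = parts, scenario = s)
}
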