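# Expression matrices are plain numeric matrices, cells in rows and genes in
# columns, with a "layer" attribute tracking the normalization state
# ("counts", "cpm" or "logcpm"). Keeping them as base matrices means all of
# base R's matrix machinery applies directly.

#' Construct a validated cell-by-gene expression matrix
#'
#' Wraps a nonnegative numeric matrix as a cells x genes expression matrix
#' with unique cell and gene identifiers and a layer tag recording its
#' normalization state.
#'
#' @param values Numeric matrix, cells in rows, genes in columns. All entries
#'   must be finite and nonnegative.
#' @param cell_ids Character vector of unique cell identifiers (defaults to
#'   the row names of `values`; generated as `cell_1..n` when absent).
#' @param gene_ids Character vector of unique gene identifiers (defaults to
#'   the column names; generated when absent).
#' @param layer One of `"counts"`, `"cpm"`, `"logcpm"`.
#' @return A numeric matrix with `dimnames` set and a `"layer"` attribute.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              layer = c("counts", "cpm", "logcpm")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) == 0L || ncol(values) == 0L)
    stop("expression matrix must have at least one cell and one gene")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression matrix contains NA or non-finite entries")
  if (any(values < 0))
    stop("expression matrix contains negative entries")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length of `cell_ids` does not match the number of rows")
  if (length(gene_ids) != ncol(values))
    stop("length of `gene_ids` does not match the number of columns")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  dimnames(values) <- list(cell_ids, gene_ids)
  attr(values, "layer") <- layer
  values
}

#' Layer tag of an expression matrix
#'
#' @param x Expression matrix.
#' @return `"counts"`, `"cpm"` or `"logcpm"` (a matrix without a tag is
#'   treated as raw counts).
#' @export
expr_layer <- function(x) {
  layer <- attr(x, "layer")
  if (is.null(layer)) "counts" else layer
}

#' Read an expression matrix from disk
#'
#' Reads either a MatrixMarket file (`.mtx`, with plain-text row/column name
#' sidecars `<stem>.rownames.txt` and `<stem>.colnames.txt`, one identifier
#' per line) or a delimited text file (`.csv` comma-separated, anything else
#' tab-separated) with a header row and the identifiers in the first column.
#' The on-disk orientation is declared via `orientation`; the returned matrix
#' is always cells x genes.
#'
#' @param path Path to the file.
#' @param orientation Orientation of the file on disk.
#' @return An expression matrix with `layer = "counts"`.
#' @export
read_expression <- function(path,
                            orientation = c("cells_by_genes", "genes_by_cells")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    rn_path <- paste0(stem, ".rownames.txt")
    cn_path <- paste0(stem, ".colnames.txt")
    if (!file.exists(rn_path) || !file.exists(cn_path))
      stop("MatrixMarket sidecars not found: expected ", rn_path,
           " and ", cn_path)
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = function(e) stop("failed to parse ", path, ": ",
                                           conditionMessage(e)))
    rownames(m) <- readLines(rn_path)
    colnames(m) <- readLines(cn_path)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e)))
    ids <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  }
  if (orientation == "genes_by_cells") m <- t(m)
  expression_matrix(m, layer = "counts")
}

#' Write an expression matrix as tab-delimited text
#'
#' @param x Expression matrix.
#' @param path Output path; a header row and a leading identifier column are
#'   written so that [read_expression()] round-trips.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(cell_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Counts-per-million normalization
#'
#' Each cell's counts are divided by the cell's total count and multiplied by
#' one million, so every row of the result sums to 1e6.
#'
#' @param x Expression matrix with `layer = "counts"`.
#' @return Expression matrix with `layer = "cpm"`.
#' @export
cpm_normalize <- function(x) {
  if (expr_layer(x) != "counts")
    stop("cpm_normalize() expects a counts-layer matrix, got layer '",
         expr_layer(x), "'")
  totals <- rowSums(x)
  if (any(totals == 0)) {
    bad <- rownames(x)[totals == 0]
    stop("cells with zero total count cannot be normalized: ",
         paste(bad, collapse = ", "))
  }
  out <- x / totals * 1e6
  attr(out, "layer") <- "cpm"
  out
}

#' Log transform of CPM values
#'
#' Elementwise natural `log(1 + value)`, the feature space used downstream
#' for the k-nearest-neighbour graph and the Calinski-Harabasz index.
#'
#' @param x Expression matrix with `layer = "cpm"`.
#' @return Expression matrix with `layer = "logcpm"`.
#' @export
log_transform <- function(x) {
  if (expr_layer(x) != "cpm")
    stop("log_transform() expects a cpm-layer matrix, got layer '",
         expr_layer(x), "'")
  out <- log1p(x)
  attr(out, "layer") <- "logcpm"
  out
}

#' Fraction of exactly-zero entries
#'
#' @param x Expression matrix (any layer).
#' @return Proportion of entries equal to zero, in \[0, 1\].
#' @export
zero_fraction <- function(x) {
  if (length(x) == 0L) stop("empty matrix")
  mean(x == 0)
}
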