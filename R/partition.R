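# A partition is a labelling of cells produced by one clustering method.
# Labels are kept as character tokens verbatim; no coercion to integers.

#' Construct a cell partition
#'
#' @param labels Vector of cluster labels, one per cell (coerced to
#'   character; tokens are preserved verbatim).
#' @param cell_ids Character vector of unique cell identifiers; defaults to
#'   `names(labels)`, or `cell_1..n` when unnamed.
#' @param method Name of the clustering method that produced the labels.
#' @return An object of class `cell_partition`: a list with elements
#'   `cell_id`, `label` and `method`.
#' @export
partition <- function(labels, cell_ids = names(labels), method = "unknown") {
  if (length(labels) == 0L) stop("a partition needs at least one cell")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_along(labels))
  cell_ids <- as.character(cell_ids)
  labels <- as.character(labels)
  if (length(cell_ids) != length(labels))
    stop("`cell_ids` and `labels` must have the same length")
  if (anyNA(labels)) stop("every cell must have exactly one label")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_id: ",
         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", "))
  structure(list(cell_id = cell_ids, label = labels,
                 method = as.character(method)[1L]),
            class = "cell_partition")
}

#' @method print cell_partition
#' @export
print.cell_partition <- function(x, ...) {
  cat("Cell partition (", x$method, "): ", length(x$cell_id), " cells, ",
      length(unique(x$label)), " clusters\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.cell_partition <- function(x, ...) {
  data.frame(cell_id = x$cell_id, label = x$label,
             stringsAsFactors = FALSE)
}

#' Reorder a partition to a reference cell ordering
#'
#' @param p A `cell_partition`.
#' @param cell_ids Reference cell identifiers; every one must be present in
#'   `p`, otherwise an error lists the missing cells.
#' @return The partition restricted and reordered to `cell_ids`.
#' @export
align_partition <- function(p, cell_ids) {
  stopifnot(inherits(p, "cell_partition"))
  idx <- match(cell_ids, p$cell_id)
  if (anyNA(idx))
    stop("partition '", p$method, "' is missing cells: ",
         paste(cell_ids[is.na(idx)], collapse = ", "))
  partition(p$label[idx], cell_ids = cell_ids, method = p$method)
}

#' Read cluster labels from a two-column delimited file
#'
#' The file holds `cell_id` and `label` columns (comma-separated for `.csv`,
#' otherwise tab-separated).
#'
#' @param path Path to the label file.
#' @param header Whether the file carries a header row.
#' @param method Method name to attach (defaults to the file stem).
#' @param reference Optional character vector of cell identifiers; the
#'   partition is reordered to it and missing cells raise an error.
#' @return A `cell_partition`.
#' @export
read_labels <- function(path, header = TRUE, method = NULL, reference = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(method))
    method <- sub("\\.[^.]*$", "", basename(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("label file must have two columns: ", path)
  p <- partition(df[[2L]], cell_ids = df[[1L]], method = method)
  if (!is.null(reference)) p <- align_partition(p, reference)
  p
}

#' Write cluster labels to a two-column delimited file
#'
#' @param p A `cell_partition`.
#' @param path Output path (tab-separated, with header).
#' @export
write_labels <- function(p, path) {
  stopifnot(inherits(p, "cell_partition"))
  utils::write.table(
    data.frame(cell_id = p$cell_id, label = p$label),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
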