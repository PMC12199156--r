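#' Construct an expression dataset
#'
#' Container for a cells-by-genes expression matrix with a cell-to-group
#' annotation. Sparse (`Matrix::dgCMatrix`) and dense matrices are both
#' accepted; the matrix is stored with cells as rows.
#'
#' @param x numeric matrix, cells in rows, genes in columns. Row names are
#'   cell identifiers, column names gene symbols (supplied separately via
#'   `cells`/`genes` if absent).
#' @param groups character or factor of group labels, one per cell, named by
#'   cell id or in matrix row order.
#' @param genes,cells optional identifier vectors overriding dimnames.
#' @param normalized logical; `TRUE` if `x` already holds normalized values.
#' @return an object of class `expression_dataset` with components `x`,
#'   `genes`, `cells`, `groups` (factor named by cell) and `normalized`.
#' @export
expression_dataset <- function(x, groups, genes = colnames(x),
                               cells = rownames(x), normalized = FALSE) {
  if (is.null(genes) || is.null(cells)) {
    stop("gene and cell identifiers are required", call. = FALSE)
  }
  if (nrow(x) != length(cells) || ncol(x) != length(genes)) {
    stop(sprintf("matrix is %d x %d but %d cells and %d genes were given",
                 nrow(x), ncol(x), length(cells), length(genes)),
         call. = FALSE)
  }
  if (!normalized) {
    v <- if (inherits(x, "sparseMatrix")) x@x else as.numeric(x)
    if (length(v) > 0 && (any(!is.finite(v)) || any(v < 0))) {
      stop("raw counts must be finite and non-negative", call. = FALSE)
    }
  }
  g <- groups
  if (!is.null(names(g))) g <- g[cells]
  if (length(g) != length(cells) || anyNA(g)) {
    stop("every cell needs exactly one group label", call. = FALSE)
  }
  g <- factor(as.character(g))
  names(g) <- cells
  dimnames(x) <- list(cells, genes)
  structure(list(x = x, genes = genes, cells = cells, groups = g,
                 normalized = normalized),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d cells x %d genes, %d groups (%s)\n",
              length(x$cells), length(x$genes), nlevels(x$groups),
              if (x$normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' Read single-cell expression data with cell-group annotation
#'
#' Reads either a Matrix Market sparse triplet (`.mtx`) with companion gene
#' and barcode line files, or a dense delimited table with row/column names,
#' and joins a cell annotation table. Cells missing from the annotation are
#' dropped with a warning giving the count; an empty overlap between matrix
#' barcodes and annotation is an error.
#'
#' @param matrix_path path to a `.mtx` file or a dense TSV/CSV.
#' @param genes_path,barcodes_path one identifier per line, required for MTX
#'   input, ignored for dense tables (which carry dimnames).
#' @param annotation_path TSV with columns `cell_id` and `group`.
#' @param orientation `"genes_x_cells"` (the common cellranger layout,
#'   default) or `"cells_x_genes"`.
#' @param sep field separator for dense tables (default tab).
#' @return an [expression_dataset()] with `normalized = FALSE`.
#' @export
read_expression <- function(matrix_path, genes_path = NULL,
                            barcodes_path = NULL, annotation_path,
                            orientation = c("genes_x_cells", "cells_x_genes"),
                            sep = "\t") {
  orientation <- match.arg(orientation)
  for (p in c(matrix_path, annotation_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(barcodes_path)) {
      stop("MTX input requires genes_path and barcodes_path", call. = FALSE)
    }
    m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
    genes <- readLines(genes_path)
    cells <- readLines(barcodes_path)
  } else {
    df <- utils::read.delim(matrix_path, header = TRUE, sep = sep,
                            row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    genes <- if (orientation == "genes_x_cells") rownames(m) else colnames(m)
    cells <- if (orientation == "genes_x_cells") colnames(m) else rownames(m)
  }
  if (orientation == "genes_x_cells") m <- Matrix::t(m)
  if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
    stop(sprintf("dimension mismatch: matrix %d x %d vs %d cells, %d genes",
                 nrow(m), ncol(m), length(cells), length(genes)),
         call. = FALSE)
  }

  ann <- utils::read.delim(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("cell_id", "group") %in% names(ann))) {
    stop("annotation table needs columns 'cell_id' and 'group'", call. = FALSE)
  }
  keep <- cells %in% ann$cell_id
  if (!any(keep)) {
    stop("no overlap between matrix barcodes and annotation cell_id",
         call. = FALSE)
  }
  if (any(!keep)) {
    warning(sprintf("dropping %d cell(s) absent from the annotation",
                    sum(!keep)), call. = FALSE)
    m <- m[keep, , drop = FALSE]
    cells <- cells[keep]
  }
  groups <- ann$group[match(cells, ann$cell_id)]
  names(groups) <- cells
  expression_dataset(m, groups, genes = genes, cells = cells,
                     normalized = FALSE)
}

#' Total-count normalize and log-transform an expression matrix
#'
#' Scales each cell's counts to sum to `scale` (the standard per-cell
#' library-size normalization) and, by default, applies `log(1 + x)`.
#' All-zero cells cannot be rescaled and are left at zero with a warning.
#'
#' @param ds an [expression_dataset()] with `normalized = FALSE`.
#' @param scale target per-cell total (default `1e4`).
#' @param log_transform apply `log1p` after scaling (default `TRUE`).
#' @return the dataset with transformed matrix and `normalized = TRUE`.
#' @export
normalize_expression <- function(ds, scale = 1e4, log_transform = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (ds$normalized) {
    stop("dataset is already normalized", call. = FALSE)
  }
  totals <- Matrix::rowSums(ds$x)
  if (any(totals == 0)) {
    warning(sprintf("%d cell(s) have zero total counts and stay all-zero",
                    sum(totals == 0)), call. = FALSE)
  }
  f <- ifelse(totals > 0, scale / totals, 0)
  if (inherits(ds$x, "sparseMatrix")) {
    x <- methods::as(Matrix::Diagonal(x = f) %*% ds$x, "CsparseMatrix")
  } else {
    x <- ds$x * f  # '*' recycles column-wise, i.e. per cell (row)
  }
  if (log_transform) {
    if (inherits(x, "sparseMatrix")) x@x <- log1p(x@x) else x <- log1p(x)
  }
  dimnames(x) <- list(ds$cells, ds$genes)
  out <- ds
  out$x <- x
  out$normalized <- TRUE
  out
}

#' Per-group mean expression profile
#'
#' Arithmetic mean of expression over the cells of each group, for a gene
#' subset or all genes. This is the quantity both factors of the
#' co-expression score are built from.
#'
#' @param ds an [expression_dataset()].
#' @param genes gene symbols to include (default all).
#' @return a `group_profile` list: `groups` (levels), `mean_expr`
#'   (groups x genes matrix) and `group_sizes`.
#' @export
group_mean_expression <- function(ds, genes = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(genes)) genes <- ds$genes
  if (length(genes) == 0) stop("empty gene subset", call. = FALSE)
  missing <- setdiff(genes, ds$genes)
  if (length(missing) > 0) {
    stop("genes not in dataset: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  x <- ds$x[, genes, drop = FALSE]
  sizes <- table(ds$groups)
  sums <- rowsum(as.matrix(x), ds$groups)
  mean_expr <- sums / as.vector(sizes[rownames(sums)])
  structure(list(groups = rownames(mean_expr),
                 mean_expr = mean_expr,
                 group_sizes = as.vector(sizes[rownames(mean_expr)])),
            class = "group_profile")
}

# Drop groups below a minimum size; warns and returns the reduced dataset.
.enforce_min_cells <- function(ds, min_cells) {
  sizes <- table(ds$groups)
  small <- names(sizes)[sizes < min_cells]
  if (length(small) == 0) return(ds)
  warning(sprintf("excluding group(s) with fewer than %d cells: %s",
                  min_cells, paste(small, collapse = ", ")), call. = FALSE)
  keep <- !(as.character(ds$groups) %in% small)
  if (!any(keep)) stop("no group meets the minimum cell count", call. = FALSE)
  expression_dataset(ds$x[keep, , drop = FALSE],
                     droplevels(ds$groups[keep]),
                     genes = ds$genes, cells = ds$cells[keep],
                     normalized = ds$normalized)
}
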