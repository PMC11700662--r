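#' Construct a gene expression matrix (GEM)
#'
#' The GEM is a genes x cells matrix of non-negative expression values plus
#' per-cell metadata. Every cell carries an `age_group` label (`"young"` or
#' `"old"`) and a free-form `cell_type` label.
#'
#' @param values Numeric matrix, genes in rows, cells in columns; all entries
#'   finite and >= 0.
#' @param gene_ids,cell_ids Character vectors of unique identifiers matching
#'   the matrix dimensions. Defaults to `dimnames(values)`.
#' @param cell_meta Data frame with columns `cell_id`, `age_group`,
#'   `cell_type`, covering every cell.
#' @param preprocessed Logical; whether [preprocess_gem()] has been applied.
#' @return An object of class `"ExpressionMatrix"`.
#' @seealso [read_expression()], [preprocess_gem()]
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values), cell_meta,
                              preprocessed = FALSE) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values))
    stop("gene axis mismatch: ", length(gene_ids), " gene ids for ",
         nrow(values), " rows")
  if (length(cell_ids) != ncol(values))
    stop("cell axis mismatch: ", length(cell_ids), " cell ids for ",
         ncol(values), " columns")
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids")
  if (anyDuplicated(cell_ids)) stop("duplicated cell ids")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("negative expression values")
  cell_meta <- as.data.frame(cell_meta)
  req <- c("cell_id", "age_group", "cell_type")
  if (!all(req %in% names(cell_meta)))
    stop("cell_meta must have columns: ", paste(req, collapse = ", "))
  cell_meta$cell_id <- as.character(cell_meta$cell_id)
  missing <- setdiff(cell_ids, cell_meta$cell_id)
  if (length(missing))
    stop("cell_meta missing cells: ", paste(utils::head(missing, 5),
                                            collapse = ", "))
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), req,
                         drop = FALSE]
  rownames(cell_meta) <- NULL
  bad <- setdiff(unique(cell_meta$age_group), c("young", "old"))
  if (length(bad))
    stop("unknown age_group value(s): ", paste(bad, collapse = ", "))
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta, preprocessed = isTRUE(preprocessed)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (x$preprocessed) "preprocessed" else "raw"))
  tab <- table(x$cell_meta$age_group)
  cat("  age groups:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  cat("  cell types:", paste(unique(x$cell_meta$cell_type), collapse = ", "),
      "\n")
  invisible(x)
}

#' Dimensions of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return `c(n_genes, n_cells)`.
#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix with cell metadata
#'
#' Supported formats: MatrixMarket coordinate (`mtx`, 1-based indices, with
#' newline-delimited gene and cell label files) and dense `csv`/`tsv` with a
#' header row of cell ids and gene ids in the first column. Metadata is a
#' CSV/TSV keyed by `cell_id` with `age_group` and `cell_type` columns. The
#' input orientation is declared, never guessed.
#'
#' @param path Matrix file.
#' @param format One of `"mtx"`, `"csv"`, `"tsv"`.
#' @param meta_path Metadata file (delimiter inferred from extension; `csv`
#'   unless the file ends in `.tsv`/`.txt`).
#' @param orientation `"genes-by-cells"` (default) or `"cells-by-genes"`.
#' @param gene_path,cell_path Label files, required for `format = "mtx"`
#'   (one id per line, matrix row/column order before orientation is
#'   applied).
#' @return An `ExpressionMatrix` with `preprocessed = FALSE`.
#' @export
read_expression <- function(path, format = c("csv", "tsv", "mtx"), meta_path,
                            orientation = c("genes-by-cells",
                                            "cells-by-genes"),
                            gene_path = NULL, cell_path = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  for (f in c(path, meta_path, gene_path, cell_path))
    if (!file.exists(f)) stop("file not found: ", f)
  if (format == "mtx") {
    if (is.null(gene_path) || is.null(cell_path))
      stop("mtx format requires gene_path and cell_path label files")
    m <- as.matrix(Matrix::readMM(path))
    rows <- readLines(gene_path)
    cols <- readLines(cell_path)
    if (length(rows) != nrow(m))
      stop("row label file length ", length(rows),
           " does not match matrix row count ", nrow(m))
    if (length(cols) != ncol(m))
      stop("column label file length ", length(cols),
           " does not match matrix column count ", ncol(m))
    dimnames(m) <- list(rows, cols)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- read.delim(path, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
  }
  if (orientation == "cells-by-genes") m <- t(m)
  meta <- read_cell_meta(meta_path)
  expression_matrix(m, cell_meta = meta, preprocessed = FALSE)
}

#' Read per-cell metadata
#' @param path CSV/TSV file with columns `cell_id`, `age_group`, `cell_type`.
#' @return A data frame.
#' @export
read_cell_meta <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  read.delim(path, sep = sep, stringsAsFactors = FALSE)
}

#' Write an expression matrix (and metadata) to disk
#'
#' Round-trips with [read_expression()]. For `mtx`, label files are written
#' next to the matrix as `<path>.genes` and `<path>.cells`.
#'
#' @param gem An `ExpressionMatrix`.
#' @param path Output matrix file.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`.
#' @param meta_path Optional metadata output file (CSV unless ending in
#'   `.tsv`).
#' @return `path`, invisibly.
#' @export
write_expression <- function(gem, path, format = c("csv", "tsv", "mtx"),
                             meta_path = NULL) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(gem$values, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(gem$gene_ids, paste0(path, ".genes"))
    writeLines(gem$cell_ids, paste0(path, ".cells"))
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = gem$gene_ids, gem$values,
                     check.names = FALSE)
    write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(meta_path)) {
    sep <- if (grepl("\\.(tsv|txt)$", meta_path)) "\t" else ","
    write.table(gem$cell_meta, meta_path, sep = sep, row.names = FALSE,
                quote = FALSE)
  }
  invisible(path)
}

#' Normalize and log-transform a GEM
#'
#' Each cell's counts are scaled so the column total equals `scale_target`
#' (all-zero columns are left untouched), then `log(1 + x)` is applied
#' elementwise in the configured base. The transform is monotone within each
#' column, so within-cell expression ranks are preserved. Calling it twice is
#' an error, never a silent re-transform.
#'
#' @param gem A raw `ExpressionMatrix`.
#' @param scale_target Positive library-size target (default 10000).
#' @param log_base Logarithm base (default natural).
#' @return The preprocessed `ExpressionMatrix`.
#' @export
#' @examples
#' gem <- expression_matrix(matrix(c(1, 3), 2), cell_meta = data.frame(
#'   cell_id = "c1", age_group = "young", cell_type = "t"))
#' preprocess_gem(gem, scale_target = 4)$values  # log(2), log(4)
preprocess_gem <- function(gem, scale_target = 1e4, log_base = exp(1)) {
  stopifnot(inherits(gem, "ExpressionMatrix"))
  if (gem$preprocessed)
    stop("ExpressionMatrix is already preprocessed")
  stopifnot(scale_target > 0)
  totals <- colSums(gem$values)
  fac <- ifelse(totals > 0, scale_target / totals, 1)
  v <- sweep(gem$values, 2L, fac, "*")
  v <- log1p(v) / log(log_base)
  gem$values <- v
  gem$preprocessed <- TRUE
  gem
}
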