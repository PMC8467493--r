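#' Construct a labeled expression dataset
#'
#' Bundles a cells x genes expression matrix (non-negative values, typically
#' on the log2(TPM+1) scale) with one class label per cell. This container is
#' the common currency of every stage of the pipeline: feature selection,
#' ranking, cross-validation and rule extraction all consume and return it.
#'
#' @param x Numeric matrix, cells in rows and genes in columns. Row names are
#'   taken as cell identifiers and column names as gene identifiers; both must
#'   be present and unique. All entries must be finite and non-negative.
#' @param labels Character or factor vector of class tags, one per cell, in
#'   the row order of `x` (or named by cell id, in which case it is reordered
#'   to match).
#' @return An object of class `labeled_dataset`: a list with elements `x`
#'   (the matrix) and `labels` (a factor aligned with `rownames(x)`).
#' @examples
#' m <- matrix(runif(12), 4, 3,
#'             dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
#' ds <- labeled_dataset(m, c("A", "A", "B", "B"))
#' ds
#' @export
labeled_dataset <- function(x, labels) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix (cells x genes)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("'x' must carry cell ids as rownames and gene ids as colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate cell ids")
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene ids")
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  if (any(x < 0))
    stop("expression matrix contains negative values")
  if (!is.null(names(labels))) {
    missing <- setdiff(rownames(x), names(labels))
    if (length(missing))
      stop("unlabeled cell(s): ", paste(utils::head(missing, 5), collapse = ", "))
    labels <- labels[rownames(x)]
  }
  if (length(labels) != nrow(x))
    stop("'labels' must provide exactly one class tag per cell")
  if (anyNA(labels))
    stop("missing class label(s)")
  structure(list(x = x, labels = droplevels(as.factor(labels))),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d cells x %d genes, %d classes\n",
              nrow(x$x), ncol(x$x), nlevels(x$labels)))
  sz <- table(x$labels)
  cat("class sizes:\n")
  print(sz)
  invisible(x)
}

#' @export
dim.labeled_dataset <- function(x) dim(x$x)

n_cells <- function(ds) nrow(ds$x)
n_genes <- function(ds) ncol(ds$x)

#' Read a labeled dataset from disk
#'
#' Reads an expression matrix in either a dense delimited dialect or sparse
#' matrix-market triplet form, joins it with a two-column label file, and
#' validates the result. The dense dialect has a header row of gene ids and a
#' first column of cell ids; tab and comma delimiters are sniffed
#' automatically and gzip-compressed files are accepted. The matrix-market
#' form stores cells as rows and genes as columns, with sidecar text files
#' listing one cell id (rows) and one gene id (columns) per line.
#'
#' @param matrix_path Path to the matrix file (`.tsv`/`.csv`, optionally
#'   gzip-compressed, or `.mtx`).
#' @param labels_path Path to a two-column delimited file (cell id, class tag),
#'   no header required (a header line is tolerated if its first field is not
#'   a matrix cell id).
#' @param format One of `"auto"` (by file extension), `"dense"`, `"mtx"`.
#' @param cells_path,genes_path Sidecar id files, required for `"mtx"`.
#' @return A [labeled_dataset()].
#' @export
read_dataset <- function(matrix_path, labels_path,
                         format = c("auto", "dense", "mtx"),
                         cells_path = NULL, genes_path = NULL) {
  format <- match.arg(format)
  for (p in c(matrix_path, labels_path, cells_path, genes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  if (format == "auto")
    format <- if (grepl("\\.mtx(\\.gz)?$", matrix_path)) "mtx" else "dense"
  if (format == "dense") {
    m <- read_dense_matrix(matrix_path)
  } else {
    if (is.null(cells_path) || is.null(genes_path))
      stop("matrix-market input needs 'cells_path' and 'genes_path' sidecars")
    sp <- Matrix::readMM(matrix_path)
    cells <- readLines(cells_path)
    genes <- readLines(genes_path)
    if (nrow(sp) != length(cells) || ncol(sp) != length(genes))
      stop("matrix-market dimensions do not match sidecar id files")
    m <- as.matrix(sp)
    dimnames(m) <- list(cells, genes)
  }
  lab <- read_label_file(labels_path, rownames(m))
  extra <- setdiff(names(lab), rownames(m))
  if (length(extra))
    stop("labeled cell(s) absent from matrix: ",
         paste(utils::head(extra, 5), collapse = ", "))
  labeled_dataset(m, lab)
}

sniff_delim <- function(line) {
  if (lengths(regmatches(line, gregexpr("\t", line))) > 0) "\t" else ","
}

read_dense_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- sniff_delim(first)
  df <- utils::read.table(path, header = TRUE, sep = delim, row.names = 1L,
                          check.names = FALSE, comment.char = "",
                          quote = "\"", stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric values in expression matrix")
  m
}

read_label_file <- function(path, cell_ids) {
  first <- readLines(path, n = 1L)
  delim <- sniff_delim(first)
  df <- utils::read.table(path, header = FALSE, sep = delim,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2) stop("label file must have two columns: cell id, class")
  # tolerate a header row
  if (!(df[1, 1] %in% cell_ids) && nrow(df) > 1) df <- df[-1, , drop = FALSE]
  if (anyDuplicated(df[[1]])) stop("duplicate cell ids in label file")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Write a labeled dataset in the dense dialect
#'
#' Writes the matrix with gene ids as header and cell ids as first column,
#' plus a two-column label file. Values round-trip exactly (written with
#' full precision).
#'
#' @param ds A [labeled_dataset()].
#' @param matrix_path,labels_path Output paths.
#' @param sep Field delimiter (default tab).
#' @return Invisibly, the dataset.
#' @export
write_dataset <- function(ds, matrix_path, labels_path, sep = "\t") {
  stopifnot(inherits(ds, "labeled_dataset"))
  df <- data.frame(cell_id = rownames(ds$x), ds$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     matrix_path, sep = sep, quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(rownames(ds$x), as.character(ds$labels)),
                     labels_path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(ds)
}

#' Drop rare cell types
#'
#' Retains only the cells whose class has strictly more than `min_cells`
#' members, mirroring the usual pre-filter applied before training cell-type
#' classifiers on annotated single-cell data. Classes with exactly
#' `min_cells` cells are dropped (strict inequality).
#'
#' @param ds A [labeled_dataset()].
#' @param min_cells Size threshold; classes must exceed it (default 100).
#' @return A filtered [labeled_dataset()].
#' @export
filter_cell_types <- function(ds, min_cells = 100) {
  stopifnot(inherits(ds, "labeled_dataset"))
  sz <- table(ds$labels)
  keep_classes <- names(sz)[sz > min_cells]
  if (!length(keep_classes)) stop("no class passes filter")
  keep <- ds$labels %in% keep_classes
  labeled_dataset(ds$x[keep, , drop = FALSE], droplevels(ds$labels[keep]))
}

#' Tabulate class sizes
#'
#' @param ds A [labeled_dataset()].
#' @return A named integer vector (class tag -> cell count); counts sum to
#'   the number of cells.
#' @export
class_sizes <- function(ds) {
  stopifnot(inherits(ds, "labeled_dataset"))
  tab <- table(ds$labels)
  stats::setNames(as.integer(tab), names(tab))
}

#' Published cell-type size table
#'
#' The 32-class tissue-by-cell-type size table of the metastatic lung
#' adenocarcinoma atlas deposited as GEO accession GSE131907 (180,035 cells
#' after filtering classes to >100 cells), shipped as plain text for
#' bookkeeping checks and examples.
#'
#' @return A data.frame with columns `class`, `cell_type`, `n_cells`.
#' @export
reference_class_sizes <- function() {
  path <- system.file("extdata", "gse131907_class_sizes.tsv",
                      package = "scMarkerRules", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}
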