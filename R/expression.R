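#' Construct an ExpressionMatrix
#'
#' The canonical input container: a nonnegative genes x cells matrix of
#' expression values (counts, FPKM or TPM), with unique gene and cell
#' identifiers and optional per-cell stage (phenotype) labels.
#'
#' @param values Numeric genes x cells matrix, all values >= 0.
#' @param gene_ids Character vector of unique gene identifiers (rows).
#' @param cell_ids Character vector of unique cell identifiers (columns).
#' @param stage_labels Optional character vector of stage/phenotype labels,
#'   one per cell.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `gene_ids`, `cell_ids`, `stage_labels`.
#' @examples
#' x <- expression_matrix(matrix(1:6, 3, 2), c("g1", "g2", "g3"), c("c1", "c2"))
#' dim(x$values)
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              stage_labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or use dimnames)", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values)) {
    stop("length(gene_ids) must equal nrow(values)", call. = FALSE)
  }
  if (length(cell_ids) != ncol(values)) {
    stop("length(cell_ids) must equal ncol(values)", call. = FALSE)
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g)) {
    stop("duplicate gene IDs: ", paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  if (length(dup_c)) {
    stop("duplicate cell IDs: ", paste(dup_c, collapse = ", "), call. = FALSE)
  }
  if (anyNA(values)) stop("expression values contain NA", call. = FALSE)
  if (any(values < 0)) stop("expression values must be nonnegative", call. = FALSE)
  if (!is.null(stage_labels)) {
    stage_labels <- as.character(stage_labels)
    if (length(stage_labels) != ncol(values)) {
      stop("stage_labels must cover every cell", call. = FALSE)
    }
    if (anyNA(stage_labels)) stop("stage_labels contain NA", call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(
    list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
         stage_labels = stage_labels),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$stage_labels)) {
    tab <- table(x$stage_labels)
    cat("stages:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression matrix from disk
#'
#' Supports dense TSV/CSV (first column gene IDs, header row cell IDs) and
#' MatrixMarket triplets (`matrix.mtx` + `genes.tsv` + `barcodes.tsv`, the
#' common scRNA-seq layout with genes as rows).
#'
#' @param path For dense formats, the file; for `"mtx"`, either the directory
#'   containing the triplet or the `matrix.mtx` file itself.
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"mtx"`. `"auto"` picks by
#'   file extension (`.mtx`/directory -> mtx, `.csv` -> csv, else tsv).
#' @param metadata Optional path to a metadata TSV with columns `cell_id` and
#'   `stage` (optional `phenotype`); stage labels are attached in cell order.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                            metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (dir.exists(path) || grepl("\\.mtx$", path)) {
      "mtx"
    } else if (grepl("\\.csv$", path)) "csv" else "tsv"
  }
  x <- switch(format,
    tsv = read_dense(path, sep = "\t"),
    csv = read_dense(path, sep = ","),
    mtx = read_mtx_triplet(path)
  )
  if (!is.null(metadata)) {
    meta <- read_metadata(metadata)
    missing <- setdiff(x$cell_ids, meta$cell_id)
    if (length(missing)) {
      stop("metadata lacks stage labels for cells: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    x$stage_labels <- meta$stage[match(x$cell_ids, meta$cell_id)]
  }
  x
}

read_dense <- function(path, sep) {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  gene_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path,
                              call. = FALSE)
  expression_matrix(vals, gene_ids = gene_ids, cell_ids = colnames(df)[-1L])
}

read_mtx_triplet <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
  } else {
    mtx <- path
    path <- dirname(path)
  }
  genes_f <- file.path(path, "genes.tsv")
  bc_f <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, genes_f, bc_f)) {
    if (!file.exists(f)) stop("missing MTX sidecar or matrix file: ", f,
                              call. = FALSE)
  }
  m <- as.matrix(Matrix::readMM(mtx))
  genes <- readLines(genes_f)
  # 10x-style genes.tsv may carry a second symbol column
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1L), 1L)
  barcodes <- readLines(bc_f)
  if (length(genes) != nrow(m) || length(barcodes) != ncol(m)) {
    stop(sprintf(
      "MTX dimensions (%d x %d) do not match sidecars (%d genes, %d barcodes)",
      nrow(m), ncol(m), length(genes), length(barcodes)), call. = FALSE)
  }
  expression_matrix(m, gene_ids = genes, cell_ids = barcodes)
}

#' Read a cell metadata table
#'
#' @param path TSV with columns `cell_id`, `stage`, optional `phenotype`.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
  if (!all(c("cell_id", "stage") %in% names(meta))) {
    stop("metadata must have columns `cell_id` and `stage`", call. = FALSE)
  }
  meta$cell_id <- as.character(meta$cell_id)
  meta$stage <- as.character(meta$stage)
  meta
}

#' Write an expression matrix (and optional metadata) to dense TSV
#'
#' Values are formatted with `%.17g` so a write/read round trip reproduces the
#' matrix bit-exactly.
#'
#' @param x An [expression_matrix()].
#' @param path Output TSV path.
#' @param metadata_path Optional path for a `cell_id`/`stage` metadata TSV
#'   (written only when `x` carries stage labels).
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, metadata_path = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  chr <- matrix(sprintf("%.17g", x$values), nrow = nrow(x$values))
  lines <- c(
    paste(c("gene_id", x$cell_ids), collapse = "\t"),
    vapply(seq_len(nrow(chr)), function(i) {
      paste(c(x$gene_ids[i], chr[i, ]), collapse = "\t")
    }, character(1L))
  )
  writeLines(lines, path)
  if (!is.null(metadata_path) && !is.null(x$stage_labels)) {
    utils::write.table(
      data.frame(cell_id = x$cell_ids, stage = x$stage_labels),
      metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
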