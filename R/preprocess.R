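#' Z-score expression per gene
#'
#' Each gene's values are centred at its mean over all cells and divided by
#' its population standard deviation (denominator N). Genes with zero
#' standard deviation are set to all-zero rows and flagged in `constant`, so
#' dimensions are preserved and downstream binarization maps them to the
#' up-state deterministically.
#'
#' @param x An [expression_matrix()].
#' @return An object of class `ZScoredMatrix`: list with `values` (genes x
#'   cells z-scores), `gene_means`, `gene_sds` (population SD), `constant`
#'   (logical per gene), `gene_ids`, `cell_ids`, `stage_labels`.
#' @export
zscore_genes <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  n <- ncol(x$values)
  if (n < 2L) stop("z-scoring needs at least 2 cells", call. = FALSE)
  mu <- rowMeans(x$values)
  centred <- x$values - mu
  sd_pop <- sqrt(rowMeans(centred^2))
  constant <- sd_pop == 0
  z <- centred / ifelse(constant, 1, sd_pop)
  z[constant, ] <- 0
  structure(
    list(values = z, gene_means = mu, gene_sds = sd_pop, constant = constant,
         gene_ids = x$gene_ids, cell_ids = x$cell_ids,
         stage_labels = x$stage_labels),
    class = "ZScoredMatrix"
  )
}

#' Select highly variable genes
#'
#' Ranks genes by variance across cells (by default on the log1p scale, which
#' tames the mean-variance coupling of expression data) and keeps the top
#' `ceiling(fraction * n_genes)`. Ties at the cutoff are broken by ascending
#' gene ID, so the selection is deterministic.
#'
#' @param x An [expression_matrix()].
#' @param fraction Fraction of genes to keep, in (0, 1]. The analyses this
#'   package targets use 0.05 for bulk and 0.10 for single-cell data.
#' @param scale `"log1p"` (default) or `"raw"`: scale on which the ranking
#'   variance is computed.
#' @return An object of class `HVGSelection`: list with `selected_gene_ids`
#'   (ordered, most variable first), `fraction`, `scale` and
#'   `variance_per_gene` (named, all input genes).
#' @export
select_hvgs <- function(x, fraction, scale = c("log1p", "raw")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  scale <- match.arg(scale)
  if (!is_fraction(fraction)) {
    stop("`fraction` must be a single value in (0, 1]", call. = FALSE)
  }
  m1 <- nrow(x$values)
  if (m1 < 2L) stop("need at least 2 genes to select HVGs", call. = FALSE)
  vals <- if (scale == "log1p") log1p(x$values) else x$values
  v <- apply(vals, 1L, stats::var)
  names(v) <- x$gene_ids
  m <- as.integer(ceiling(fraction * m1))
  ord <- order(-v, x$gene_ids)
  structure(
    list(selected_gene_ids = x$gene_ids[ord][seq_len(m)],
         fraction = fraction, scale = scale, variance_per_gene = v),
    class = "HVGSelection"
  )
}

#' Binarize gene states
#'
#' Maps each z-scored value to 1 when `z >= 0` (expression at or above the
#' gene's mean) and 0 otherwise, restricted to the selected highly variable
#' genes, in selection order. The result is the cells x genes binary state
#' matrix whose rows are the network states of individual cells.
#'
#' @param z A [zscore_genes()] result.
#' @param hvgs An [select_hvgs()] result, or a character vector of gene IDs.
#' @return An object of class `BinaryStateMatrix`: list with `states` (cells
#'   x M matrix over \{0, 1\}), `gene_ids`, `cell_ids`, `stage_labels`.
#' @export
binarize <- function(z, hvgs) {
  stopifnot(inherits(z, "ZScoredMatrix"))
  ids <- if (inherits(hvgs, "HVGSelection")) hvgs$selected_gene_ids
         else as.character(hvgs)
  unknown <- setdiff(ids, z$gene_ids)
  if (length(unknown)) {
    stop("unknown HVG IDs: ", paste(utils::head(unknown, 5), collapse = ", "),
         call. = FALSE)
  }
  sub <- z$values[match(ids, z$gene_ids), , drop = FALSE]
  states <- t(ifelse(sub >= 0, 1, 0))
  storage.mode(states) <- "double"
  dimnames(states) <- list(z$cell_ids, ids)
  binary_state_matrix(states, stage_labels = z$stage_labels)
}

#' Construct a BinaryStateMatrix directly
#'
#' @param states Cells x genes matrix over \{0, 1\} with dimnames.
#' @param stage_labels Optional stage label per cell (row).
#' @return A `BinaryStateMatrix`.
#' @export
binary_state_matrix <- function(states, stage_labels = NULL) {
  states <- as.matrix(states)
  if (!all(states %in% c(0, 1))) {
    stop("binary states must be 0 or 1", call. = FALSE)
  }
  if (is.null(rownames(states))) {
    rownames(states) <- paste0("cell", seq_len(nrow(states)))
  }
  if (is.null(colnames(states))) {
    colnames(states) <- paste0("g", seq_len(ncol(states)))
  }
  if (!is.null(stage_labels) && length(stage_labels) != nrow(states)) {
    stop("stage_labels must cover every cell", call. = FALSE)
  }
  structure(
    list(states = states, gene_ids = colnames(states),
         cell_ids = rownames(states),
         stage_labels = if (is.null(stage_labels)) NULL
                        else as.character(stage_labels)),
    class = "BinaryStateMatrix"
  )
}

#' @export
print.BinaryStateMatrix <- function(x, ...) {
  cat(sprintf("BinaryStateMatrix: %d cells x %d genes (mean active %.1f)\n",
              nrow(x$states), ncol(x$states), mean(rowSums(x$states))))
  invisible(x)
}
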