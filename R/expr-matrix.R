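#' Expression matrix container
#'
#' A light genes-by-observations matrix wrapper used throughout the package.
#' Rows are genes (symbols, uppercased), columns are cells or bulk samples.
#' The `layer` tag records what the values mean: raw UMI `"counts"`,
#' library-size-normalized log values (`"normalized"`), or per-group Z-scores
#' (`"standardized"`). Operations check the tag so that, e.g., counts are
#' never standardized directly.
#'
#' @param values numeric matrix or `Matrix::sparseMatrix`, genes in rows.
#' @param gene_ids character vector of gene symbols (defaults to rownames).
#' @param obs_ids character vector of cell/sample ids (defaults to colnames).
#' @param layer one of `"counts"`, `"normalized"`, `"standardized"`.
#' @return An object of class `"expr_matrix"`.
#' @export
expr_matrix <- function(values, gene_ids = rownames(values),
                        obs_ids = colnames(values),
                        layer = c("counts", "normalized", "standardized")) {
  layer <- match.arg(layer)
  if (is.null(gene_ids) || is.null(obs_ids))
    stop("gene_ids and obs_ids are required (or set dimnames on 'values')")
  if (length(gene_ids) != nrow(values) || length(obs_ids) != ncol(values))
    stop("dimension mismatch: ", nrow(values), "x", ncol(values),
         " values vs ", length(gene_ids), " genes / ", length(obs_ids),
         " observations")
  gene_ids <- normalize_symbols(gene_ids)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers after uppercasing: ",
         paste(unique(gene_ids[duplicated(gene_ids)])[1:5], collapse = ", "))
  if (anyDuplicated(obs_ids))
    stop("duplicate observation identifiers")
  if (layer == "counts" && min_value(values) < 0)
    stop("counts layer contains negative values")
  rownames(values) <- gene_ids
  colnames(values) <- obs_ids
  structure(list(values = values, gene_ids = gene_ids, obs_ids = obs_ids,
                 layer = layer),
            class = "expr_matrix")
}

#' Normalize gene symbols
#'
#' Uppercases and strips surrounding whitespace. Idempotent; used everywhere
#' gene identifiers enter the package so that human/mouse symbol pairs such
#' as `Col1a1`/`COL1A1` match case-insensitively.
#'
#' @param x character vector of symbols.
#' @return normalized character vector.
#' @export
normalize_symbols <- function(x) toupper(trimws(as.character(x)))

min_value <- function(v) {
  if (methods::is(v, "sparseMatrix")) min(v@x, 0) else min(v)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix [%s]: %d genes x %d observations (%s storage)\n",
              x$layer, length(x$gene_ids), length(x$obs_ids),
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param i,j gene / observation indices (numeric, logical or character).
#' @param ... ignored.
#' @return an `expr_matrix` with the same layer tag.
#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$gene_ids)
  if (missing(j)) j <- seq_along(x$obs_ids)
  expr_matrix(x$values[i, j, drop = FALSE],
              layer = x$layer)
}

#' Extract the numeric values of an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param dense return a base dense matrix (default TRUE).
#' @return numeric matrix, genes in rows.
#' @export
expr_values <- function(x, dense = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  if (dense) as.matrix(x$values) else x$values
}
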