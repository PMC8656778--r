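#' Read an expression matrix
#'
#' Two on-disk formats are supported: `"tsv"` — a dense tab-delimited table
#' whose header row holds observation ids and whose first column holds gene
#' ids — and `"mtx_dir"` — a MatrixMarket directory containing `matrix.mtx`
#' (genes x cells triplets), `features.tsv` and `barcodes.tsv`.
#'
#' @param path file (tsv) or directory (mtx_dir).
#' @param fmt `"tsv"` or `"mtx_dir"`.
#' @param layer layer tag to attach, default `"counts"`.
#' @return an [expr_matrix].
#' @export
read_matrix <- function(path, fmt = c("tsv", "mtx_dir"),
                        layer = c("counts", "normalized", "standardized")) {
  fmt <- match.arg(fmt)
  layer <- match.arg(layer)
  if (fmt == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- genes
    expr_matrix(vals, layer = layer)
  } else {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc))
      if (!file.exists(f)) stop("missing file in mtx_dir: ", f)
    m <- Matrix::readMM(mtx)
    genes <- utils::read.delim(feat, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    cells <- utils::read.delim(bc, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stop("mtx_dir dimension mismatch: matrix is ", nrow(m), "x", ncol(m),
           " but features/barcodes list ", length(genes), "/", length(cells))
    expr_matrix(methods::as(m, "CsparseMatrix"), gene_ids = genes,
                obs_ids = cells, layer = layer)
  }
}

#' Write an expression matrix
#'
#' Inverse of [read_matrix]; a write-then-read round trip reproduces integer
#' count values exactly.
#'
#' @param mat an [expr_matrix].
#' @param path output file (tsv) or directory (mtx_dir; created if needed).
#' @param fmt `"tsv"` or `"mtx_dir"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(mat, path, fmt = c("tsv", "mtx_dir")) {
  fmt <- match.arg(fmt)
  stopifnot(inherits(mat, "expr_matrix"))
  if (fmt == "tsv") {
    tab <- data.frame(gene_id = mat$gene_ids,
                      as.matrix(mat$values), check.names = FALSE)
    colnames(tab) <- c("gene_id", mat$obs_ids)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(mat$values, sparse = TRUE),
                                "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(mat$gene_ids, file.path(path, "features.tsv"))
    writeLines(mat$obs_ids, file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read / write per-cell annotation tables
#'
#' Annotation tables are plain TSV with one row per observation and at least
#' an `obs_id` column; typical columns are donor, tissue, cell_type, cluster,
#' n_umi, n_genes, pct_mito, condition.
#'
#' @param path TSV file.
#' @return data.frame with one row per `obs_id`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"obs_id" %in% names(ann)) stop("annotation lacks an obs_id column")
  if (anyDuplicated(ann$obs_id)) stop("duplicate obs_id rows in annotation")
  ann
}

#' @rdname read_annotation
#' @param ann annotation data.frame.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
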