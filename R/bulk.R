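#' Build the phenotype marker matrix
#'
#' Assembles the "single-cell-derived marker file": rows are the union of
#' all cell types' differential genes, columns are cellular phenotypes
#' (cell type x pathway-active / inactive), and values are the mean
#' linear-scale expression (expm1 of the log-normalized values) of the gene
#' in that phenotype's cells. Phenotypes with zero cells are dropped with a
#' warning.
#'
#' @param mat normalized [expr_matrix] of the single-cell atlas.
#' @param ann annotation with obs_id and cell_type.
#' @param activity an `"scssa"` fit or data.frame with obs_id + active.
#' @param deg_tables list of [extract_degs] tables (one per cell type).
#' @return object of class `"marker_matrix"`: `values` (genes x phenotypes)
#'   and `phenotypes` (column, cell_type, active).
#' @export
build_marker_matrix <- function(mat, ann, activity, deg_tables) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "normalized")
    stop("build_marker_matrix expects normalized data")
  act <- if (inherits(activity, "scssa")) activity$results else activity
  degs <- unique(normalize_symbols(
    unlist(lapply(deg_tables, function(t) t$gene))))
  degs <- intersect(degs, mat$gene_ids)
  if (length(degs) == 0) stop("no DEG present in the matrix")
  cell_types <- unique(unlist(lapply(deg_tables,
                                     function(t) unique(t$cell_type))))
  lin <- expm1(as.matrix(mat$values)[degs, , drop = FALSE])
  idx <- match(mat$obs_ids, ann$obs_id)
  ct_of <- ann$cell_type[idx]
  active_of <- act$active[match(mat$obs_ids, act$obs_id)]
  cols <- list(); meta <- list()
  for (ct in cell_types) {
    for (flag in c(TRUE, FALSE)) {
      cells <- which(ct_of == ct & active_of %in% flag)
      cname <- paste0(ct, if (flag) "_active" else "_inactive")
      if (length(cells) == 0) {
        warning("phenotype '", cname, "' has zero cells; column dropped")
        next
      }
      cols[[cname]] <- rowMeans(lin[, cells, drop = FALSE])
      meta[[cname]] <- data.frame(column = cname, cell_type = ct,
                                  active = flag, stringsAsFactors = FALSE)
    }
  }
  if (length(cols) == 0) stop("no phenotype column could be built")
  values <- do.call(cbind, cols)
  rownames(values) <- degs
  structure(list(values = values,
                 phenotypes = do.call(rbind, unname(meta))),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("marker_matrix: %d marker genes x %d phenotypes (%d cell types)\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$phenotypes$cell_type))))
  invisible(x)
}

#' Export / import the marker matrix in the CIBERSORTx signature dialect
#'
#' Tab-delimited text with the gene column headed `GeneSymbol` followed by
#' one column per phenotype — the exact upload format of the CIBERSORTx
#' custom signature file, so the matrix can be used with the external
#' service as well as with [score_bulk]. Export then reimport reproduces
#' the matrix exactly.
#'
#' @param markers a `"marker_matrix"`.
#' @param path TSV path.
#' @return `path` invisibly (write) / a `"marker_matrix"` (read).
#' @export
write_cibersortx_signature <- function(markers, path) {
  tab <- data.frame(GeneSymbol = rownames(markers$values),
                    markers$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cibersortx_signature
#' @export
read_cibersortx_signature <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "GeneSymbol")
    stop("not a signature file: first column must be 'GeneSymbol'")
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- normalize_symbols(tab$GeneSymbol)
  cn <- colnames(values)
  structure(list(values = values,
                 phenotypes = data.frame(
                   column = cn,
                   cell_type = sub("_(active|inactive)$", "", cn),
                   active = grepl("_active$", cn),
                   stringsAsFactors = FALSE)),
            class = "marker_matrix")
}

#' Project phenotype signatures into bulk samples
#'
#' For every bulk sample, fits the sample's marker-gene expression vector
#' against the marker-matrix phenotype columns by non-negative least
#' squares and normalizes the coefficients to sum to one (relative mode:
#' per-sample phenotype fractions). The profibrotic score of a cell type is
#' the coefficient of its pathway-active column. This is a transparent
#' stand-in for support-vector deconvolution services; use
#' [write_cibersortx_signature] to run the same marker matrix through an
#' external tool. Bulk values are expected on a linear scale, matching the
#' marker matrix; per-sample rescaling does not change the normalized
#' coefficients.
#'
#' @param bulk [expr_matrix] of bulk samples (genes x samples, linear
#'   scale; any layer tag accepted).
#' @param markers a `"marker_matrix"`.
#' @return object of class `"bulk_scores"`: `coefficients` (samples x
#'   phenotypes, rows summing to 1), `profibrotic` (samples x cell types:
#'   the active-phenotype coefficients), `n_marker_genes`.
#' @export
score_bulk <- function(bulk, markers) {
  stopifnot(inherits(bulk, "expr_matrix"), inherits(markers, "marker_matrix"))
  common <- intersect(rownames(markers$values), bulk$gene_ids)
  if (length(common) == 0)
    stop("no marker gene overlaps the bulk matrix")
  A <- markers$values[common, , drop = FALSE]
  B <- as.matrix(bulk$values)[common, , drop = FALSE]
  ns <- ncol(B)
  coefs <- matrix(0, ns, ncol(A),
                  dimnames = list(bulk$obs_ids, colnames(A)))
  for (s in seq_len(ns)) {
    fit <- pracma::lsqnonneg(A, B[, s])
    x <- fit$x
    coefs[s, ] <- if (sum(x) > 0) x / sum(x) else NA_real_
  }
  act <- markers$phenotypes$column[markers$phenotypes$active]
  prof <- coefs[, act, drop = FALSE]
  colnames(prof) <- markers$phenotypes$cell_type[markers$phenotypes$active]
  structure(list(coefficients = coefs, profibrotic = prof,
                 n_marker_genes = length(common)),
            class = "bulk_scores")
}

#' @export
print.bulk_scores <- function(x, ...) {
  cat(sprintf("bulk_scores: %d samples x %d phenotypes (%d marker genes)\n",
              nrow(x$coefficients), ncol(x$coefficients), x$n_marker_genes))
  invisible(x)
}

#' @export
as.data.frame.bulk_scores <- function(x, ...) {
  data.frame(sample_id = rownames(x$coefficients), x$coefficients,
             check.names = FALSE, stringsAsFactors = FALSE)
}
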