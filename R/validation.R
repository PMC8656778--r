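#' Map signature genes into a dataset's gene namespace
#'
#' Applies a user-supplied two-column mapping table (columns `from`, `to`),
#' falling back to case-insensitive symbol identity for genes not listed.
#' This covers most human/mouse symbol pairs (e.g. Col1a1 vs COL1A1) without
#' an ortholog service.
#'
#' @param genes character vector of signature gene symbols.
#' @param mapping optional data.frame with columns `from` and `to`.
#' @return normalized character vector of mapped symbols.
#' @export
map_symbols <- function(genes, mapping = NULL) {
  genes <- normalize_symbols(genes)
  if (!is.null(mapping)) {
    from <- normalize_symbols(mapping$from)
    to <- normalize_symbols(mapping$to)
    hit <- match(genes, from)
    genes[!is.na(hit)] <- to[hit[!is.na(hit)]]
  }
  unique(genes)
}

#' Score signature activity per cell in a validation dataset
#'
#' Scores a gene signature (e.g. a cell-type-specific profibrotic
#' signature) in every cell of an independent dataset: expression is
#' standardized within each cell type (not cluster), genes are ranked per
#' cell, and the MWW-GST NES is computed per cell. NES values are returned
#' with the cell's condition label so activity can be compared across
#' conditions or time points.
#'
#' @param mat normalized [expr_matrix].
#' @param ann annotation with obs_id, cell_type and the `group_by` column.
#' @param signature a [gene_set] or character vector of signature genes.
#' @param group_by annotation column holding the condition label, default
#'   `"condition"`.
#' @param mapping optional symbol mapping table, see [map_symbols].
#' @return data.frame: obs_id, cell_type, condition, NES, p.
#' @export
signature_nes <- function(mat, ann, signature, group_by = "condition",
                          mapping = NULL) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "normalized") stop("signature_nes expects normalized data")
  genes <- if (inherits(signature, "gene_set")) signature$genes
           else normalize_symbols(signature)
  mapped <- map_symbols(genes, mapping)
  present <- intersect(mapped, mat$gene_ids)
  if (length(present) == 0)
    stop("no signature gene maps into the matrix; unmapped symbols: ",
         paste(utils::head(mapped, 10), collapse = ", "))
  if (!group_by %in% names(ann))
    stop("annotation lacks a '", group_by, "' column")
  idx <- match(mat$obs_ids, ann$obs_id)
  if (anyNA(idx)) stop("annotation is missing some cells in the matrix")
  cell_type <- ann$cell_type[idx]
  fit <- scssa(standardize_within_cluster(mat, cell_type),
               gs = gene_set("signature", present))
  data.frame(obs_id = mat$obs_ids, cell_type = cell_type,
             condition = ann[[group_by]][idx],
             NES = fit$results$NES, p = fit$results$p,
             stringsAsFactors = FALSE)
}

#' Pairwise condition comparisons of signature activity
#'
#' Compares per-cell NES between every pair of conditions with a two-sided
#' Wilcoxon rank-sum test and adjusts across pairs (Benjamini-Hochberg);
#' pairs are significant at q < 0.05. Pairs involving a condition with
#' fewer than two cells are skipped with a warning.
#'
#' @param nes_table output of [signature_nes] (needs columns NES and
#'   condition).
#' @param order optional condition ordering for the output table.
#' @return data.frame: cond1, cond2, n1, n2, delta (mean NES cond2 - cond1),
#'   p, q, significant.
#' @export
compare_conditions <- function(nes_table, order = NULL) {
  conds <- if (is.null(order)) unique(as.character(nes_table$condition))
           else order
  if (length(conds) < 2) stop("need at least two conditions")
  rows <- list()
  for (i in seq_len(length(conds) - 1)) {
    for (j in seq(i + 1, length(conds))) {
      x <- nes_table$NES[nes_table$condition == conds[i]]
      y <- nes_table$NES[nes_table$condition == conds[j]]
      if (length(x) < 2 || length(y) < 2) {
        warning("pair ", conds[i], " vs ", conds[j],
                " skipped: fewer than 2 cells in a condition")
        next
      }
      p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
      rows[[length(rows) + 1]] <-
        data.frame(cond1 = conds[i], cond2 = conds[j],
                   n1 = length(x), n2 = length(y),
                   delta = mean(y) - mean(x), p = p,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(cond1 = character(), cond2 = character(),
                      n1 = integer(), n2 = integer(), delta = numeric(),
                      p = numeric(), q = numeric(),
                      significant = logical()))
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < 0.05
  out
}
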