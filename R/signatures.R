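# Two-sided rank-sum p-values for every gene (rows of x) between two cell
# groups, normal approximation with tie correction — vectorized so that DEG
# extraction does not pay wilcox.test's per-call overhead on thousands of
# genes.
ranksum_rows <- function(x, g1, g2) {
  n1 <- length(g1); n2 <- length(g2); N <- n1 + n2
  sub <- x[, c(g1, g2), drop = FALSE]
  p <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    r <- rank(sub[i, ], ties.method = "average")
    tie <- tie_correction_term(r)
    u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie / (N * (N - 1)))
    if (sigma2 <= 0) { p[i] <- 1; next }
    z <- (abs(u1 - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    p[i] <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
  }
  p
}

#' Differential genes between pathway-active and inactive cells
#'
#' For one cell type, tests every gene between the pathway-active and
#' non-active cell populations with a two-sided Wilcoxon rank-sum test on
#' normalized expression, adjusts across genes (Benjamini-Hochberg) and
#' keeps genes at q < `fdr`. The log-fold change is
#' `ln(mean_active + eps) - ln(mean_inactive + eps)` on the normalized
#' scale. When the active population is a whole annotated subcluster with a
#' designated counterpart (e.g. a profibrotic versus a proinflammatory
#' subcluster of the same tubular cell type), pass `reference_cell_type`:
#' the comparison is then cell_type versus reference_cell_type, ignoring
#' per-cell active flags.
#'
#' @param mat normalized [expr_matrix].
#' @param ann annotation data.frame with obs_id and cell_type columns.
#' @param activity an `"scssa"` fit or its data.frame (obs_id + active).
#' @param cell_type cell type to analyse.
#' @param reference_cell_type optional explicit reference population.
#' @param fdr FDR cutoff for retained genes, default 0.05.
#' @param eps pseudocount for the fold change, default 1e-9.
#' @param min_cells minimum cells per group, default 3.
#' @return data.frame: cell_type, gene, log_fold_change, p, q, direction
#'   (`"up"` iff log_fold_change > 0); only q < `fdr` rows. Empty (with a
#'   warning) when either group is too small.
#' @export
extract_degs <- function(mat, ann, activity, cell_type,
                         reference_cell_type = NULL, fdr = 0.05,
                         eps = 1e-9, min_cells = 3) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "normalized") stop("extract_degs expects normalized data")
  act <- if (inherits(activity, "scssa")) activity$results else activity
  empty <- data.frame(cell_type = character(), gene = character(),
                      log_fold_change = numeric(), p = numeric(),
                      q = numeric(), direction = character(),
                      stringsAsFactors = FALSE)
  ct_cells <- ann$obs_id[ann$cell_type == cell_type]
  if (is.null(reference_cell_type)) {
    flags <- act$active[match(ct_cells, act$obs_id)]
    g1 <- ct_cells[flags %in% TRUE]
    g2 <- ct_cells[flags %in% FALSE]
  } else {
    g1 <- ct_cells
    g2 <- ann$obs_id[ann$cell_type == reference_cell_type]
  }
  g1 <- intersect(g1, mat$obs_ids); g2 <- intersect(g2, mat$obs_ids)
  if (length(g1) < min_cells || length(g2) < min_cells) {
    warning("cell type '", cell_type, "' skipped: groups of ", length(g1),
            " and ", length(g2), " cells (need >= ", min_cells, ")")
    return(empty)
  }
  v <- as.matrix(mat$values)
  p <- ranksum_rows(v, match(g1, mat$obs_ids), match(g2, mat$obs_ids))
  q <- stats::p.adjust(p, method = "BH")
  lfc <- log(rowMeans(v[, match(g1, mat$obs_ids), drop = FALSE]) + eps) -
    log(rowMeans(v[, match(g2, mat$obs_ids), drop = FALSE]) + eps)
  keep <- q < fdr
  out <- data.frame(cell_type = cell_type, gene = mat$gene_ids,
                    log_fold_change = lfc, p = p, q = q,
                    direction = ifelse(lfc > 0, "up", "down"),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$q, out$p), , drop = FALSE]
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of a query gene list against
#' a background universe (one-sided hypergeometric, identical to a one-sided
#' Fisher exact test), adjusts across sets (Benjamini-Hochberg) and applies
#' the reporting gates: q < `fdr`, pathway size strictly greater than
#' `min_size` genes, and enriched-gene ratio (overlap / pathway size)
#' strictly greater than `min_ratio`. Pathway size is counted within the
#' universe, so undetected genes do not dilute the ratio.
#'
#' @param genes query gene symbols (e.g. up-regulated DEGs).
#' @param gs_collection list of [gene_set]s.
#' @param universe background gene symbols; must contain `genes`.
#' @param min_size strict lower bound on pathway size, default 15.
#' @param min_ratio strict lower bound on overlap ratio, default 0.10.
#' @param fdr FDR cutoff, default 0.05.
#' @return data.frame: pathway, set_size, overlap, ratio, p, q — retained
#'   rows only, ordered by q.
#' @export
ora_enrich <- function(genes, gs_collection, universe, min_size = 15,
                       min_ratio = 0.10, fdr = 0.05) {
  genes <- unique(normalize_symbols(genes))
  universe <- unique(normalize_symbols(universe))
  if (!all(genes %in% universe))
    stop("query contains genes outside the universe")
  empty <- data.frame(pathway = character(), set_size = integer(),
                      overlap = integer(), ratio = numeric(),
                      p = numeric(), q = numeric(), stringsAsFactors = FALSE)
  if (length(genes) == 0 || length(gs_collection) == 0) return(empty)
  N <- length(universe); nq <- length(genes)
  rows <- lapply(gs_collection, function(gs) {
    set_u <- intersect(gs$genes, universe)
    K <- length(set_u)
    k <- length(intersect(genes, set_u))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
    data.frame(pathway = gs$name, set_size = K, overlap = k,
               ratio = if (K > 0) k / K else 0, p = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  keep <- tab$q < fdr & tab$set_size > min_size & tab$ratio > min_ratio
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$q, out$p), , drop = FALSE]
}
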