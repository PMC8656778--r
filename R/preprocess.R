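#' QC thresholds
#'
#' Cell-level quality-control cutoffs. Defaults retain cells with at least
#' 400 UMIs, at least 200 detected genes and at most 20% of UMIs mapped to
#' mitochondrial genes; all three bounds are inclusive (only strictly worse
#' cells are removed).
#'
#' @param min_umi minimum UMI count per cell.
#' @param min_genes minimum number of detected genes per cell.
#' @param max_pct_mito maximum mitochondrial UMI fraction, in [0, 1].
#' @return object of class `"qc_thresholds"`.
#' @export
qc_thresholds <- function(min_umi = 400, min_genes = 200,
                          max_pct_mito = 0.20) {
  stopifnot(min_umi >= 0, min_genes >= 0,
            max_pct_mito >= 0, max_pct_mito <= 1)
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 max_pct_mito = max_pct_mito),
            class = "qc_thresholds")
}

#' Per-cell QC metrics from a counts matrix
#'
#' @param mat an [expr_matrix] with layer `"counts"`.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes.
#' @return data.frame with obs_id, n_umi, n_genes, pct_mito.
#' @export
qc_metrics <- function(mat, mito_prefix = "MT-") {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "counts") stop("qc_metrics requires the counts layer")
  v <- mat$values
  n_umi <- as.numeric(Matrix::colSums(v))
  n_genes <- as.numeric(Matrix::colSums(v > 0))
  is_mt <- startsWith(mat$gene_ids, normalize_symbols(mito_prefix))
  mito <- if (any(is_mt)) as.numeric(Matrix::colSums(v[is_mt, , drop = FALSE]))
          else rep(0, ncol(v))
  pct_mito <- ifelse(n_umi > 0, mito / n_umi, 1)
  data.frame(obs_id = mat$obs_ids, n_umi = n_umi, n_genes = n_genes,
             pct_mito = pct_mito, stringsAsFactors = FALSE)
}

#' Filter low-quality cells
#'
#' Removes cells with fewer UMIs or detected genes than the thresholds, or a
#' mitochondrial fraction above the cap. Cells sitting exactly on a boundary
#' are kept ("fewer than" / "greater than" are strict). Idempotent.
#'
#' @param mat counts [expr_matrix].
#' @param ann annotation data.frame with obs_id rows matching `mat` (may be
#'   `NULL`; QC metrics are recomputed from the matrix either way).
#' @param th a [qc_thresholds] object.
#' @param mito_prefix mitochondrial gene prefix, default `"MT-"`.
#' @return list with elements `mat` (filtered counts) and `ann` (matching
#'   annotation including refreshed n_umi / n_genes / pct_mito columns).
#' @export
qc_filter <- function(mat, ann = NULL, th = qc_thresholds(),
                      mito_prefix = "MT-") {
  qm <- qc_metrics(mat, mito_prefix)
  keep <- qm$n_umi >= th$min_umi & qm$n_genes >= th$min_genes &
    qm$pct_mito <= th$max_pct_mito
  if (!any(keep)) stop("no cells survive QC filtering")
  out <- mat[, keep]
  qm <- qm[keep, , drop = FALSE]
  if (is.null(ann)) {
    ann_out <- qm
  } else {
    if (!"obs_id" %in% names(ann)) stop("annotation lacks an obs_id column")
    idx <- match(qm$obs_id, ann$obs_id)
    if (anyNA(idx)) stop("annotation is missing some cells in the matrix")
    ann_out <- ann[idx, , drop = FALSE]
    ann_out$n_umi <- qm$n_umi
    ann_out$n_genes <- qm$n_genes
    ann_out$pct_mito <- qm$pct_mito
    rownames(ann_out) <- NULL
  }
  list(mat = out, ann = ann_out)
}

#' Library-size normalization
#'
#' Scales each cell to `scale` total counts and applies log1p:
#' `log1p(count / cell_total * scale)`. Preserves the within-cell rank order
#' of genes and is invariant to multiplying a cell's counts by a constant.
#'
#' @param mat counts [expr_matrix]; all cell totals must be positive (QC
#'   upstream removes empty cells).
#' @param scale target library size, default 10000.
#' @return an [expr_matrix] with layer `"normalized"`.
#' @export
normalize_library_size <- function(mat, scale = 1e4) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "counts")
    stop("normalize_library_size requires the counts layer, got '",
         mat$layer, "'")
  tot <- as.numeric(Matrix::colSums(mat$values))
  if (any(tot <= 0)) stop("cells with zero total counts; run qc_filter first")
  v <- as.matrix(mat$values)
  v <- log1p(sweep(v, 2, tot / scale, "/"))
  expr_matrix(v, layer = "normalized")
}

#' Cluster cells on a PCA embedding
#'
#' Runs PCA on the normalized matrix (cells as observations, genes centered),
#' builds a k-nearest-neighbour graph on the top principal components and
#' partitions it with Louvain community detection. Deterministic for a fixed
#' seed; labels are contiguous integers starting at 1.
#'
#' @param mat normalized [expr_matrix].
#' @param n_pcs number of principal components, default 50 (reduced with a
#'   warning when the data admit fewer).
#' @param k neighbourhood size for the kNN graph, default 15.
#' @param resolution Louvain resolution parameter, default 1.
#' @param seed integer RNG seed.
#' @return integer vector of cluster labels, named by obs_id.
#' @export
cluster_cells <- function(mat, n_pcs = 50, k = 15, resolution = 1,
                          seed = 1L) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$layer != "normalized") stop("cluster_cells expects normalized data")
  x <- t(as.matrix(mat$values))
  n <- nrow(x)
  max_pcs <- min(dim(x)) - 1L
  if (n_pcs > max_pcs) {
    warning("n_pcs reduced from ", n_pcs, " to ", max_pcs)
    n_pcs <- max_pcs
  }
  # drop zero-variance genes so prcomp does not rescale them to NaN
  v <- apply(x, 2, stats::var)
  x <- x[, v > 0, drop = FALSE]
  if (ncol(x) == 0 || n_pcs < 1) {
    labels <- rep(1L, n)
    names(labels) <- mat$obs_ids
    return(labels)
  }
  set.seed(seed)
  pcs <- stats::prcomp(x, rank. = n_pcs, center = TRUE, scale. = FALSE)$x
  k_eff <- min(k, n - 1L)
  d <- as.matrix(stats::dist(pcs))
  edges <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k_eff + 1L)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::simplify(igraph::make_graph(edges, n = n, directed = FALSE))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(factor(igraph::membership(comm)))
  names(labels) <- mat$obs_ids
  labels
}
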