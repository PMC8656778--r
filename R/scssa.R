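#' Standardize expression within clusters
#'
#' Converts normalized expression to per-cluster Z-scores: within each
#' cluster, every gene is centered and scaled to unit variance across that
#' cluster's cells (population, i.e. N-denominator, standard deviation).
#' Genes with zero variance in a cluster are set to 0 there; a single-cell
#' cluster is all-zero with a warning. This is the step that makes the
#' downstream per-cell gene ranking relative to transcriptionally similar
#' cells rather than to the whole dataset.
#'
#' @param mat normalized [expr_matrix].
#' @param clusters vector of cluster labels, one per cell (any atomic type).
#' @param sd_type `"population"` (default) or `"sample"` denominator.
#' @return an [expr_matrix] with layer `"standardized"`.
#' @export
standardize_within_cluster <- function(mat, clusters,
                                       sd_type = c("population", "sample")) {
  stopifnot(inherits(mat, "expr_matrix"))
  sd_type <- match.arg(sd_type)
  if (mat$layer != "normalized")
    stop("standardize_within_cluster expects the normalized layer")
  if (length(clusters) != length(mat$obs_ids))
    stop("one cluster label per cell is required")
  v <- as.matrix(mat$values)
  out <- v
  for (cl in unique(clusters)) {
    idx <- which(clusters == cl)
    if (length(idx) == 1L) {
      warning("cluster '", cl, "' has a single cell; Z set to 0")
      out[, idx] <- 0
      next
    }
    sub <- v[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    cs <- sub - mu
    denom <- if (sd_type == "population") length(idx) else length(idx) - 1L
    sdv <- sqrt(rowSums(cs^2) / denom)
    z <- cs / sdv
    z[sdv == 0, ] <- 0
    out[, idx] <- z
  }
  expr_matrix(out, layer = "standardized")
}

#' Rank one cell's genes by Z-score
#'
#' The gene with the largest Z-score receives rank G (the number of genes),
#' so that a cell whose pathway genes sit at the top of its profile scores a
#' normalized enrichment near 1. Ties receive average ranks, hence the rank
#' sum is always G(G+1)/2.
#'
#' @param std standardized [expr_matrix].
#' @param obs_id id of the cell to rank.
#' @return named numeric vector of ranks over all genes.
#' @export
rank_cell <- function(std, obs_id) {
  stopifnot(inherits(std, "expr_matrix"))
  if (std$layer != "standardized") stop("rank_cell expects standardized data")
  j <- match(obs_id, std$obs_ids)
  if (is.na(j)) stop("unknown obs_id: ", obs_id)
  z <- as.numeric(std$values[, j])
  r <- rank(z, ties.method = "average")
  names(r) <- std$gene_ids
  r
}

# Rank-sum statistics for one ranked profile: T over the in-set indices,
# plus the tie term sum(t^3 - t) needed by the normal approximation.
mww_stats <- function(ranks, in_set) {
  G <- length(ranks)
  m <- sum(in_set)
  n <- G - m
  T_sum <- sum(ranks[in_set])
  U <- n * m + m * (m + 1) / 2 - T_sum
  nes <- 1 - U / (m * n)
  list(G = G, m = m, n = n, T = T_sum, U = U, NES = nes)
}

# One-sided (greater) normal-approximation p-value for the MWW statistic,
# with average-rank tie correction and continuity correction.
mww_pvalue <- function(T_sum, m, n, tie_term) {
  G <- m + n
  u1 <- T_sum - m * (m + 1) / 2          # Mann-Whitney U of the in-set
  mu <- m * n / 2
  sigma2 <- m * n / 12 * ((G + 1) - tie_term / (G * (G - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u1 - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' Mann-Whitney-Wilcoxon gene-set test for one ranked cell
#'
#' Computes the rank-sum statistic of the pathway genes in a single cell's
#' gene ranking and the normalized enrichment score
#' \deqn{NES = 1 - U/(mn), \quad U = nm + m(m+1)/2 - T,}
#' where m is the number of pathway genes present in the profile, n the
#' number of genes outside the pathway and T the sum of the pathway genes'
#' ranks. NES lies in [0, 1] and equals the fraction of (in-set, out-set)
#' gene pairs in which the pathway gene outranks the other: values near 1
#' mean maximal activation, values near 0 minimal activation. The p-value is
#' a one-sided (greater) tie-corrected normal approximation.
#'
#' @param ranks named rank vector from [rank_cell] (ties as average ranks).
#' @param gs a [gene_set]; genes absent from the profile are dropped before
#'   computing m.
#' @return one-row data.frame: m, n, T, U, NES, p, scorable. When no pathway
#'   gene is present (or none is outside the set) the row is flagged
#'   `scorable = FALSE` with NA statistics rather than a silent NES of 0.
#' @export
mww_gst <- function(ranks, gs) {
  stopifnot(inherits(gs, "gene_set"))
  in_set <- names(ranks) %in% gs$genes
  m <- sum(in_set)
  n <- length(ranks) - m
  if (m == 0 || n == 0) {
    return(data.frame(m = m, n = n, T = NA_real_, U = NA_real_,
                      NES = NA_real_, p = NA_real_, scorable = FALSE))
  }
  st <- mww_stats(ranks, in_set)
  tie_term <- tie_correction_term(ranks)
  p <- mww_pvalue(st$T, st$m, st$n, tie_term)
  data.frame(m = st$m, n = st$n, T = st$T, U = st$U, NES = st$NES, p = p,
             scorable = TRUE)
}

# sum over tie groups of (t^3 - t), computed from the rank vector
tie_correction_term <- function(ranks) {
  t <- tabulate(match(ranks, unique(ranks)))
  sum(t^3 - t)
}

#' Active-call rule
#'
#' A cell is called pathway-active when its NES strictly exceeds `nes_min`
#' and its FDR-adjusted p-value is strictly below `fdr`. Boundary values
#' (NES exactly 0.3, q exactly 0.05) are NOT active.
#'
#' @param nes numeric NES values.
#' @param q FDR-adjusted p-values.
#' @param nes_min NES threshold, default 0.3.
#' @param fdr FDR threshold, default 0.05.
#' @return logical vector (NA-safe: unscorable cells give FALSE).
#' @export
call_active <- function(nes, q, nes_min = 0.3, fdr = 0.05) {
  act <- nes > nes_min & q < fdr
  act[is.na(act)] <- FALSE
  act
}

#' Score a pathway's activity in every cell
#'
#' The central fit of the package: standardizes expression within clusters,
#' ranks each cell's genes by Z-score, applies the Mann-Whitney-Wilcoxon
#' gene-set test per cell, adjusts p-values across cells (Benjamini-
#' Hochberg, one family per pathway) and calls active cells with
#' [call_active]. Returns a classed object with print / summary / plot /
#' as.data.frame methods.
#'
#' @param mat normalized [expr_matrix] (or an already standardized one, in
#'   which case `clusters` is ignored).
#' @param clusters per-cell cluster labels used for standardization.
#' @param gs a [gene_set].
#' @param nes_min,fdr active-call thresholds, see [call_active].
#' @return object of class `"scssa"`; `as.data.frame()` yields one row per
#'   cell with obs_id, pathway, m, n, T, U, NES, p, q, active.
#' @export
scssa <- function(mat, clusters = NULL, gs, nes_min = 0.3, fdr = 0.05) {
  stopifnot(inherits(mat, "expr_matrix"), inherits(gs, "gene_set"))
  std <- if (mat$layer == "standardized") mat
         else standardize_within_cluster(mat, clusters)
  z <- as.matrix(std$values)
  G <- nrow(z)
  in_set <- std$gene_ids %in% gs$genes
  m <- sum(in_set)
  n <- G - m
  nc <- ncol(z)
  if (m == 0)
    stop("no gene of set '", gs$name, "' is present in the matrix")
  if (n == 0) stop("gene set covers the whole matrix; n = 0")
  T_sum <- numeric(nc); tie <- numeric(nc)
  for (j in seq_len(nc)) {
    r <- rank(z[, j], ties.method = "average")
    T_sum[j] <- sum(r[in_set])
    tie[j] <- tie_correction_term(r)
  }
  U <- n * m + m * (m + 1) / 2 - T_sum
  nes <- 1 - U / (m * n)
  u1 <- T_sum - m * (m + 1) / 2
  sigma2 <- m * n / 12 * ((G + 1) - tie / (G * (G - 1)))
  p <- ifelse(sigma2 > 0,
              stats::pnorm((u1 - m * n / 2 - 0.5) / sqrt(pmax(sigma2, 1e-300)),
                           lower.tail = FALSE),
              1)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(obs_id = std$obs_ids, pathway = gs$name,
                    m = m, n = n, T = T_sum, U = U, NES = nes,
                    p = p, q = q,
                    active = call_active(nes, q, nes_min, fdr),
                    stringsAsFactors = FALSE)
  structure(list(results = res, pathway = gs$name, m = m, n = n,
                 nes_min = nes_min, fdr = fdr, n_cells = nc),
            class = "scssa")
}

#' Per-cell activity table for a pathway
#'
#' Convenience wrapper around [scssa] returning the per-cell result table
#' directly.
#'
#' @inheritParams scssa
#' @return data.frame, one row per cell.
#' @export
score_pathway <- function(mat, clusters = NULL, gs, nes_min = 0.3,
                          fdr = 0.05) {
  as.data.frame(scssa(mat, clusters, gs, nes_min = nes_min, fdr = fdr))
}

#' @export
as.data.frame.scssa <- function(x, ...) x$results

#' @export
print.scssa <- function(x, ...) {
  cat(sprintf("scssa fit: pathway '%s' (m = %d in-set, n = %d out-set genes)\n",
              x$pathway, x$m, x$n))
  cat(sprintf("  %d cells scored; %d active (NES > %g & q < %g)\n",
              x$n_cells, sum(x$results$active), x$nes_min, x$fdr))
  invisible(x)
}

#' @export
summary.scssa <- function(object, ...) {
  r <- object$results
  out <- list(pathway = object$pathway,
              n_cells = object$n_cells,
              n_active = sum(r$active),
              nes = summary(r$NES),
              q = summary(r$q))
  class(out) <- "summary.scssa"
  out
}

#' @export
print.summary.scssa <- function(x, ...) {
  cat(sprintf("Pathway activity summary: '%s'\n", x$pathway))
  cat(sprintf("  cells: %d, active: %d (%.1f%%)\n", x$n_cells, x$n_active,
              100 * x$n_active / x$n_cells))
  cat("  NES distribution:\n"); print(x$nes)
  cat("  FDR q distribution:\n"); print(x$q)
  invisible(x)
}

#' Dot plot of per-cell activity
#'
#' NES on the x-axis against -log10 FDR q on the y-axis, active cells
#' highlighted, with the two decision thresholds drawn.
#'
#' @param x an `"scssa"` object.
#' @param ... passed to [graphics::plot].
#' @export
plot.scssa <- function(x, ...) {
  r <- x$results
  graphics::plot(r$NES, -log10(pmax(r$q, 1e-300)),
                 col = ifelse(r$active, "firebrick", "grey50"),
                 pch = 16, cex = 0.5, xlab = "NES",
                 ylab = expression(-log[10] ~ q),
                 main = paste0("Pathway activity: ", x$pathway), ...)
  graphics::abline(v = x$nes_min, lty = 2)
  graphics::abline(h = -log10(x$fdr), lty = 2)
  invisible(x)
}
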