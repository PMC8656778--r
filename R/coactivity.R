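# One-sided enrichment p for a 2x2 table [[a,b],[c,d]] = P(X >= a) under the
# hypergeometric with the table's margins fixed. Identical to
# fisher.test(alternative = "greater")$p.value but cheap enough to run over
# thousands of pathways.
fisher_greater_p <- function(a, b, c, d) {
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Test co-activity between a reference pathway and another pathway
#'
#' Builds the 2x2 table of reference-pathway activity (e.g. ECM) against
#' another pathway's activity over the cells of one cell type and computes a
#' one-sided (enrichment) Fisher exact p-value, the sample odds ratio, and
#' the prevalence: the fraction of reference-active cells in which the other
#' pathway is also active.
#'
#' @param ref_active logical vector, reference-pathway activity per cell.
#' @param pw_active logical vector over the same cells.
#' @param pathway,cell_type labels carried into the record.
#' @return one-row data.frame: cell_type, pathway, a/b/c/d table counts,
#'   fisher_odds_ratio, fisher_p, prevalence, defined. With zero
#'   reference-active cells the record is flagged `defined = FALSE`.
#' @export
coactivity_test <- function(ref_active, pw_active, pathway = NA_character_,
                            cell_type = NA_character_) {
  if (length(ref_active) != length(pw_active))
    stop("flag vectors must cover the same cells")
  a <- sum(ref_active & pw_active)
  b <- sum(ref_active & !pw_active)
  c_ <- sum(!ref_active & pw_active)
  d <- sum(!ref_active & !pw_active)
  if (a + b == 0) {
    return(data.frame(cell_type = cell_type, pathway = pathway,
                      a = a, b = b, c = c_, d = d,
                      fisher_odds_ratio = NA_real_, fisher_p = NA_real_,
                      prevalence = NA_real_, defined = FALSE,
                      stringsAsFactors = FALSE))
  }
  or <- (a * d) / (b * c_)   # sample odds ratio; Inf/NaN on empty margins
  data.frame(cell_type = cell_type, pathway = pathway,
             a = a, b = b, c = c_, d = d,
             fisher_odds_ratio = or,
             fisher_p = fisher_greater_p(a, b, c_, d),
             prevalence = a / (a + b), defined = TRUE,
             stringsAsFactors = FALSE)
}

#' Co-activity records for a collection of pathways
#'
#' Applies [coactivity_test] to every pathway's per-cell activity flags and
#' adjusts the Fisher p-values across pathways (Benjamini-Hochberg) within
#' the cell type.
#'
#' @param ref_active logical vector of reference-pathway activity per cell.
#' @param pw_active_mat logical matrix, cells x pathways (named columns), or
#'   a named list of logical vectors.
#' @param cell_type label carried into the records.
#' @return data.frame of records with a `q` column.
#' @export
coactivity_records <- function(ref_active, pw_active_mat,
                               cell_type = NA_character_) {
  if (is.list(pw_active_mat))
    pw_active_mat <- do.call(cbind, pw_active_mat)
  recs <- do.call(rbind, lapply(colnames(pw_active_mat), function(pw)
    coactivity_test(ref_active, pw_active_mat[, pw], pathway = pw,
                    cell_type = cell_type)))
  recs$q <- NA_real_
  recs$q[recs$defined] <- stats::p.adjust(recs$fisher_p[recs$defined],
                                          method = "BH")
  recs
}

#' Build a cell-type co-active pathway network
#'
#' Keeps pathways significant at q < `q_max`, ranks them lexicographically
#' by (q ascending, prevalence descending), selects the top `top_frac`
#' (ceiling, so at least one survives whenever any is significant) capped at
#' `max_nodes`, and draws an edge between two selected pathways when the
#' fraction of reference-active cells active for both strictly exceeds
#' `share_min`; the edge weight is that shared fraction.
#'
#' @param records output of [coactivity_records].
#' @param active_sets named list mapping pathway name to the ids of cells
#'   active for that pathway.
#' @param ref_active_ids ids of the reference-active (e.g. ECM-active) cells.
#' @param q_max FDR threshold, default 0.05.
#' @param top_frac fraction of significant pathways kept, default 0.10.
#' @param max_nodes node cap, default 10.
#' @param share_min strict lower bound on the shared fraction for an edge,
#'   default 0.80.
#' @return object of class `"coactive_network"` with `nodes` (pathway, q,
#'   prevalence) and `edges` (p1, p2, weight) data.frames. An empty network
#'   (no significant pathway) is a valid result.
#' @export
build_network <- function(records, active_sets, ref_active_ids,
                          q_max = 0.05, top_frac = 0.10, max_nodes = 10,
                          share_min = 0.80) {
  sig <- records[records$defined & !is.na(records$q) & records$q < q_max, ,
                 drop = FALSE]
  sig <- sig[order(sig$q, -sig$prevalence), , drop = FALSE]
  n_keep <- min(ceiling(top_frac * nrow(sig)), max_nodes)
  nodes <- sig[seq_len(n_keep), c("pathway", "q", "prevalence"),
               drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(p1 = character(), p2 = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  n_ref <- length(ref_active_ids)
  if (nrow(nodes) >= 2 && n_ref > 0) {
    pws <- nodes$pathway
    for (i in seq_len(length(pws) - 1)) {
      for (j in seq(i + 1, length(pws))) {
        shared <- length(Reduce(intersect,
                                list(active_sets[[pws[i]]],
                                     active_sets[[pws[j]]],
                                     ref_active_ids))) / n_ref
        if (shared > share_min)
          edges <- rbind(edges, data.frame(p1 = pws[i], p2 = pws[j],
                                           weight = shared,
                                           stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 cell_type = records$cell_type[1]),
            class = "coactive_network")
}

#' @export
print.coactive_network <- function(x, ...) {
  cat(sprintf("coactive_network (%s): %d pathways, %d links\n",
              x$cell_type, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Circos-style plot of a co-active network
#'
#' Renders nodes on a circle with edge widths scaled to the shared-cell
#' fraction; a table/edge-list stand-in for a full Circos diagram.
#'
#' @param x a `"coactive_network"`.
#' @param ... passed to [igraph::plot.igraph].
#' @export
plot.coactive_network <- function(x, ...) {
  if (nrow(x$nodes) == 0) {
    graphics::plot.new(); graphics::title("empty co-active network")
    return(invisible(x))
  }
  g <- igraph::graph_from_data_frame(x$edges, directed = FALSE,
                                     vertices = x$nodes)
  igraph::plot.igraph(g, layout = igraph::layout_in_circle(g),
                      edge.width = 1 + 6 * (if (nrow(x$edges))
                        x$edges$weight else 0), ...)
  invisible(x)
}

#' Export a co-active network as node and edge TSVs
#'
#' @param net a `"coactive_network"`.
#' @param node_path,edge_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_coactive_network <- function(net, node_path, edge_path) {
  utils::write.table(net$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(node_path, edge_path))
}
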