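#' Simulation configuration for clustered single-cell counts
#'
#' Defaults describe a down-sampled but realistic droplet experiment: a
#' 2,000-gene panel over 3,000 cells in 5 clusters with negative-binomial
#' counts (dispersion 2), log-normally varying sequencing depth around
#' 2,000 UMIs/cell, a 100-gene pathway, and a planted subpopulation —
#' 30% of one cluster — whose pathway-gene means are multiplied by
#' exp(delta).
#'
#' @param n_genes,n_cells,n_clusters matrix and clustering dimensions.
#' @param m pathway size (genes).
#' @param planted_fraction fraction of cluster 1 made pathway-active.
#' @param delta natural-log mean up-shift of pathway genes in planted
#'   cells; 0 plants nothing.
#' @param nb_dispersion negative-binomial size parameter.
#' @param depth_mean expected UMIs per cell.
#' @param n_mito number of mitochondrial (`MT-`) genes included.
#' @param seed integer RNG seed.
#' @return a `"sim_config"` list.
#' @export
sim_config <- function(n_genes = 2000, n_cells = 3000, n_clusters = 5,
                       m = 100, planted_fraction = 0.3, delta = 2,
                       nb_dispersion = 2, depth_mean = 2000, n_mito = 5,
                       seed = 1L) {
  stopifnot(n_genes >= 10, n_cells >= 10, n_clusters >= 1,
            m >= 1, planted_fraction > 0, planted_fraction <= 1,
            delta >= 0, nb_dispersion > 0, depth_mean > 0)
  if (m > n_genes - n_mito)
    stop("pathway size m exceeds the number of non-mitochondrial genes")
  structure(list(n_genes = n_genes, n_cells = n_cells,
                 n_clusters = n_clusters, m = m,
                 planted_fraction = planted_fraction, delta = delta,
                 nb_dispersion = nb_dispersion, depth_mean = depth_mean,
                 n_mito = n_mito, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate clustered single-cell counts with a planted active population
#'
#' Draws negative-binomial UMI counts from per-cluster gene-mean profiles:
#' each cluster over-expresses its own marker block, per-cell depth varies
#' log-normally around `depth_mean`, and in cluster 1 a `planted_fraction`
#' of cells has the pathway genes' means multiplied by `exp(delta)` — the
#' planted "pathway-active" population that the scoring pipeline should
#' recover. Fully reproducible from the config seed.
#'
#' @param cfg a [sim_config].
#' @return list with `mat` (counts [expr_matrix]), `ann` (annotation
#'   data.frame with donor, tissue, cell_type, cluster and QC columns),
#'   `truth` (obs_id, cluster, planted), and `pathway` (a [gene_set] of the
#'   planted pathway's genes).
#' @export
simulate_sc <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes; C <- cfg$n_cells; K <- cfg$n_clusters
  n_mito <- cfg$n_mito
  genes <- c(sprintf("MT-G%d", seq_len(n_mito)),
             sprintf("GENE%05d", seq_len(G - n_mito)))
  cells <- sprintf("CELL%05d", seq_len(C))
  pathway_genes <- genes[n_mito + seq_len(cfg$m)]

  # base relative expression, heavy-tailed like real transcriptomes
  base <- exp(stats::rnorm(G, mean = 0, sd = 1.2))
  names(base) <- genes
  base[seq_len(n_mito)] <- mean(base) * 2  # modest mitochondrial content

  # per-cluster profiles: each cluster up-shifts its own marker block
  block <- max(20L, floor((G - n_mito - cfg$m) / (2 * K)))
  nonmarker_pool <- setdiff(seq_len(G), c(seq_len(n_mito),
                                          n_mito + seq_len(cfg$m)))
  profiles <- matrix(rep(base, K), nrow = G,
                     dimnames = list(genes, NULL))
  for (k in seq_len(K)) {
    mk <- nonmarker_pool[((k - 1) * block + 1):(k * block)]
    profiles[mk, k] <- profiles[mk, k] * exp(2)
  }

  cluster <- sort(rep_len(seq_len(K), C))
  planted <- rep(FALSE, C)
  in1 <- which(cluster == 1L)
  planted[in1[seq_len(round(cfg$planted_fraction * length(in1)))]] <- TRUE

  depth <- stats::rlnorm(C, meanlog = log(cfg$depth_mean) - 0.3^2 / 2,
                         sdlog = 0.3)
  counts <- matrix(0L, G, C, dimnames = list(genes, cells))
  pw_idx <- match(pathway_genes, genes)
  for (j in seq_len(C)) {
    prof <- profiles[, cluster[j]]
    if (planted[j]) prof[pw_idx] <- prof[pw_idx] * exp(cfg$delta)
    mu <- depth[j] * prof / sum(prof)
    counts[, j] <- stats::rnbinom(G, mu = mu, size = cfg$nb_dispersion)
  }
  mat <- expr_matrix(counts, layer = "counts")
  qm <- qc_metrics(mat)
  ann <- data.frame(obs_id = cells,
                    donor = paste0("D", 1 + seq_len(C) %% 2),
                    tissue = "organ1",
                    cell_type = paste0("CT", cluster),
                    cluster = cluster,
                    n_umi = qm$n_umi, n_genes = qm$n_genes,
                    pct_mito = qm$pct_mito, stringsAsFactors = FALSE)
  truth <- data.frame(obs_id = cells, cluster = cluster, planted = planted,
                      stringsAsFactors = FALSE)
  list(mat = mat, ann = ann, truth = truth,
       pathway = gene_set("SIM_PATHWAY", pathway_genes))
}

#' Simulate bulk samples as noisy mixtures of phenotype profiles
#'
#' Each sample is a Dirichlet-weighted convex combination of the marker
#' matrix's phenotype columns with multiplicative log-normal noise; the
#' true weights are returned for recovery checks.
#'
#' @param markers a `"marker_matrix"`.
#' @param n_samples number of bulk samples.
#' @param noise_sd standard deviation of the log-normal noise (0 = exact
#'   mixtures), default 0.05.
#' @param seed integer RNG seed.
#' @param alpha Dirichlet concentration, default 1 (uniform on the simplex).
#' @return list with `bulk` ([expr_matrix], genes x samples, linear scale)
#'   and `weights` (samples x phenotypes, rows summing to 1).
#' @export
simulate_bulk <- function(markers, n_samples, noise_sd = 0.05, seed = 1L,
                          alpha = 1) {
  stopifnot(inherits(markers, "marker_matrix"))
  set.seed(seed)
  A <- markers$values
  K <- ncol(A)
  w <- matrix(stats::rgamma(n_samples * K, shape = alpha), n_samples, K)
  w <- w / rowSums(w)
  colnames(w) <- colnames(A)
  rownames(w) <- sprintf("SAMPLE%04d", seq_len(n_samples))
  mix <- A %*% t(w)
  if (noise_sd > 0)
    mix <- mix * exp(matrix(stats::rnorm(length(mix), 0, noise_sd),
                            nrow(mix)))
  colnames(mix) <- rownames(w)
  list(bulk = expr_matrix(mix, layer = "counts"), weights = w)
}

#' Simulate survival records with a score-dependent hazard
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(beta * score)`; censoring times are independent
#' exponentials with rate `censor_rate` (0 = no censoring). The observed
#' time is the minimum of the two, the event indicator marks whether the
#' death was observed.
#'
#' @param scores named numeric vector of per-sample scores (names become
#'   sample ids; unnamed vectors get generated ids).
#' @param beta log-hazard slope per unit score.
#' @param baseline_hazard baseline event rate per day, default 0.01.
#' @param censor_rate censoring rate per day, default 0.002.
#' @param seed integer RNG seed.
#' @return data.frame: sample_id, time, event, score.
#' @export
simulate_survival <- function(scores, beta, baseline_hazard = 0.01,
                              censor_rate = 0.002, seed = 1L) {
  set.seed(seed)
  n <- length(scores)
  ids <- names(scores)
  if (is.null(ids)) ids <- sprintf("SAMPLE%04d", seq_len(n))
  t_event <- stats::rexp(n, rate = baseline_hazard * exp(beta * scores))
  t_cens <- if (censor_rate > 0) stats::rexp(n, rate = censor_rate)
            else rep(Inf, n)
  data.frame(sample_id = ids,
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             score = as.numeric(scores),
             stringsAsFactors = FALSE)
}
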