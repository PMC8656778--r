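# Small in-code fixtures and independent oracles shared across test files.

# genes x cells matrix with generated ids, wrapped at a given layer
make_mat <- function(values, layer = "counts") {
  rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  colnames(values) <- sprintf("C%03d", seq_len(ncol(values)))
  expr_matrix(values, layer = layer)
}

# standardized-layer matrix straight from a Z-score matrix
make_std <- function(z) make_mat(z, layer = "standardized")

# Exhaustive pair-counting oracle for the normalized enrichment score:
# the fraction of (in-set, out-set) gene pairs in which the in-set gene
# holds the strictly larger rank (ties count one half).
nes_pair_oracle <- function(ranks, in_set) {
  rin <- ranks[in_set]
  rout <- ranks[!in_set]
  wins <- 0
  for (ri in rin) wins <- wins + sum(ri > rout) + 0.5 * sum(ri == rout)
  wins / (length(rin) * length(rout))
}

# Independent one-sided Fisher p for [[a,b],[c,d]]: direct summation of
# hypergeometric point masses over x >= a at fixed margins.
hyper_p_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  r1 <- a + b            # reference-active cells
  k <- a + c             # pathway-active cells
  xs <- max(0, k - (N - r1)):min(r1, k)
  num <- sum(choose(r1, xs[xs >= a]) * choose(N - r1, k - xs[xs >= a]))
  num / choose(N, k)
}

# tiny normalized matrix with two planted groups differing on a gene block
make_two_group_norm <- function(n_genes = 60, n_per_group = 30,
                                shift_genes = 1:5, shift = log(4),
                                seed = 1L) {
  set.seed(seed)
  base <- matrix(rnorm(n_genes * 2 * n_per_group, mean = 1, sd = 0.3),
                 n_genes)
  base[shift_genes, seq_len(n_per_group)] <-
    base[shift_genes, seq_len(n_per_group)] + shift
  base[base < 0] <- 0
  make_mat(base, layer = "normalized")
}
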