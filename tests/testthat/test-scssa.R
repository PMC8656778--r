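test_that("within-cluster standardization yields zero mean and unit variance", {
  # two-point cluster, population sd: values 1,3 -> Z = -1, +1
  mat <- make_mat(matrix(c(1, 3, 2, 2), 1, 4), layer = "normalized")
  cl <- c(1, 1, 2, 2)
  std <- standardize_within_cluster(mat, cl)
  expect_equal(as.numeric(std$values[1, 1:2]), c(-1, 1))
  # constant gene within cluster 2 -> all zero
  expect_equal(as.numeric(std$values[1, 3:4]), c(0, 0))
  # sample-sd option
  std_s <- standardize_within_cluster(mat, cl, sd_type = "sample")
  expect_equal(as.numeric(std_s$values[1, 1:2]),
               c(-1, 1) / sqrt(2), tolerance = 1e-12)

  set.seed(5)
  big <- make_mat(matrix(rnorm(40 * 30, 2), 40, 30), layer = "normalized")
  cl2 <- rep(1:3, each = 10)
  stdb <- standardize_within_cluster(big, cl2)
  for (k in 1:3) {
    sub <- as.matrix(stdb$values[, cl2 == k])
    expect_lt(max(abs(rowMeans(sub))), 1e-10)
    expect_lt(max(abs(rowMeans(sub^2) - 1)), 1e-10)
  }

  one <- make_mat(matrix(rnorm(4), 2, 2), layer = "normalized")
  w <- capture_warnings(std1 <- standardize_within_cluster(one, c(1, 2)))
  expect_match(w, "single cell", all = TRUE)  # one warning per cluster
  expect_true(all(std1$values == 0))
})

test_that("per-cell ranking puts the largest Z at rank G with tie averaging", {
  std <- make_std(matrix(c(2, 0, -1), 3, 1))
  r <- rank_cell(std, "C001")
  expect_equal(unname(r), c(3, 2, 1))
  std_t <- make_std(matrix(c(1, 1, 0), 3, 1))
  expect_equal(unname(rank_cell(std_t, "C001")), c(2.5, 2.5, 1))
  # permutation identity: rank sum is G(G+1)/2 even under ties
  set.seed(9)
  for (i in 1:20) {
    z <- sample(round(rnorm(15), 1), 15, replace = TRUE)
    r <- rank_cell(make_std(matrix(z, 15, 1)), "C001")
    expect_equal(sum(r), 15 * 16 / 2)
  }
})

test_that("MWW-GST reproduces the T/U/NES arithmetic at the extremes", {
  gs <- gene_set("PW", c("G004", "G005"))
  # in-set genes at the two top ranks of G = 5: T = 9, U = 0, NES = 1
  top <- mww_gst(rank_cell(make_std(matrix(1:5, 5, 1)), "C001"), gs)
  expect_equal(top$T, 9)
  expect_equal(top$U, 0)
  expect_equal(top$NES, 1)
  # in-set genes at the two bottom ranks: T = 3, U = 6, NES = 0
  bottom <- mww_gst(rank_cell(make_std(matrix(5:1, 5, 1)), "C001"), gs)
  expect_equal(bottom$T, 3)
  expect_equal(bottom$U, 6)
  expect_equal(bottom$NES, 0)
  # in-set at ranks {2, 5}: NES = 2/3, matching exhaustive pair counting
  ranks <- rank_cell(make_std(matrix(c(1, 5, 6, 2, 9), 5, 1)), "C001")
  expect_equal(unname(ranks[c("G004", "G005")]), c(2, 5))
  mid <- mww_gst(ranks, gs)
  expect_equal(mid$T, 7)
  expect_equal(mid$U, 2)
  expect_equal(mid$NES, 2 / 3)
  expect_equal(mid$NES, nes_pair_oracle(ranks, names(ranks) %in% gs$genes))
})

test_that("a gene set absent from the profile is flagged unscorable", {
  ranks <- rank_cell(make_std(matrix(1:4, 4, 1)), "C001")
  res <- mww_gst(ranks, gene_set("NONE", c("ZZZ1", "ZZZ2")))
  expect_false(res$scorable)
  expect_true(is.na(res$NES))
  expect_error(scssa(make_std(matrix(1:4, 4, 2)),
                     gs = gene_set("NONE", "ZZZ1")),
               "no gene of set")
})

test_that("the U-formula NES equals exhaustive pair counting (G <= 12, all m)", {
  set.seed(11)
  for (G in 2:12) {
    for (m in 1:(G - 1)) {
      for (rep in 1:3) {
        z <- rnorm(G)
        in_set <- rep(FALSE, G)
        in_set[sample(G, m)] <- TRUE
        r <- rank(z, ties.method = "average")
        T_sum <- sum(r[in_set])
        U <- (G - m) * m + m * (m + 1) / 2 - T_sum
        nes <- 1 - U / (m * (G - m))
        expect_equal(nes, nes_pair_oracle(r, in_set), tolerance = 1e-12)
      }
    }
  }
})

test_that("NES symmetry, monotone invariance, and null mean 0.5 hold", {
  set.seed(13)
  gs <- gene_set("PW", sprintf("G%03d", 1:4))
  # reversal symmetry on tie-free profiles
  for (i in 1:10) {
    z <- sample(seq(-3, 3, length.out = 20))
    fwd <- mww_gst(rank_cell(make_std(matrix(z, 20, 1)), "C001"), gs)
    rev <- mww_gst(rank_cell(make_std(matrix(-z, 20, 1)), "C001"), gs)
    expect_equal(fwd$NES + rev$NES, 1, tolerance = 1e-12)
  }
  # invariance under monotone transforms of the Z profile
  z <- rnorm(30)
  base <- mww_gst(rank_cell(make_std(matrix(z, 30, 1)), "C001"),
                  gene_set("PW", sprintf("G%03d", 1:6)))
  for (f in list(function(x) x^3, exp, function(x) 2 * x + 7)) {
    tr <- mww_gst(rank_cell(make_std(matrix(f(z), 30, 1)), "C001"),
                  gene_set("PW", sprintf("G%03d", 1:6)))
    expect_equal(tr$NES, base$NES)
  }
  # expected NES under random gene-set draws is 0.5
  z <- rnorm(200)
  r <- rank(z)
  nes <- replicate(1000, {
    in_set <- rep(FALSE, 200); in_set[sample(200, 10)] <- TRUE
    nes_from <- sum(r[in_set]) - 10 * 11 / 2
    nes_from / (10 * 190)
  })
  expect_lt(abs(mean(nes) - 0.5), 0.02)
})

test_that("active calls honour the strict NES and FDR boundaries", {
  expect_false(call_active(0.30, 0.001))
  expect_true(call_active(0.31, 0.049))
  expect_true(call_active(0.5, 0.01))
  expect_false(call_active(0.5, 0.05))
  expect_false(call_active(NA, 0.01))
  expect_equal(call_active(c(0.4, 0.2), c(0.01, 0.01)), c(TRUE, FALSE))
})

test_that("score_pathway recovers a planted active subpopulation", {
  sim <- simulate_sc(sim_config(n_cells = 800, n_genes = 1000, m = 50,
                                delta = 2, seed = 21L))
  flt <- qc_filter(sim$mat, sim$ann)
  nrm <- normalize_library_size(flt$mat)
  res <- score_pathway(nrm, flt$ann$cluster, sim$pathway)
  truth <- sim$truth[match(res$obs_id, sim$truth$obs_id), ]
  expect_gte(mean(res$active[truth$planted]), 0.90)
  expect_lte(mean(res$active[!truth$planted]), 0.05)
  # planted cells sit well above background on the NES scale
  expect_gt(mean(res$NES[truth$planted]) - mean(res$NES[!truth$planted]),
            0.2)
  # q is a BH adjustment of p within the pathway family
  expect_equal(res$q, p.adjust(res$p, "BH"))
})

test_that("scssa methods expose the fit", {
  sim <- simulate_sc(sim_config(n_cells = 100, n_genes = 200, m = 20,
                                seed = 5L))
  fit <- scssa(normalize_library_size(sim$mat), sim$ann$cluster,
               sim$pathway)
  expect_s3_class(fit, "scssa")
  df <- as.data.frame(fit)
  expect_named(df, c("obs_id", "pathway", "m", "n", "T", "U", "NES", "p",
                     "q", "active"))
  expect_true(all(df$NES >= 0 & df$NES <= 1))
  expect_output(print(fit), "active")
  s <- summary(fit)
  expect_equal(s$n_cells, 100)
  expect_output(print(s), "NES distribution")
})
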