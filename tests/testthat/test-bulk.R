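# a small marker matrix with orthogonal-support phenotypes for exact
# mixture recovery
make_markers <- function() {
  values <- rbind(diag(4) * c(10, 8, 6, 4),
                  matrix(0, 2, 4))
  values[5, ] <- c(1, 0, 2, 0)
  values[6, ] <- c(0, 3, 0, 1)
  rownames(values) <- sprintf("G%03d", 1:6)
  colnames(values) <- c("fib_active", "fib_inactive",
                        "epi_active", "epi_inactive")
  structure(list(values = values,
                 phenotypes = data.frame(
                   column = colnames(values),
                   cell_type = rep(c("fib", "epi"), each = 2),
                   active = rep(c(TRUE, FALSE), 2),
                   stringsAsFactors = FALSE)),
            class = "marker_matrix")
}

test_that("the marker matrix has the phenotype-mean structure", {
  # 2 cell types x 2 phenotypes over 10 DEGs -> 10 x 4 matrix
  set.seed(41)
  n_cells <- 40
  vals <- matrix(rexp(10 * n_cells, 1), 10, n_cells)
  ct <- rep(c("fib", "epi"), each = 20)
  active <- rep(rep(c(TRUE, FALSE), each = 10), 2)
  # a gene expressed only in active fib cells
  vals[1, !(ct == "fib" & active)] <- 0
  mat <- make_mat(log1p(vals), layer = "normalized")
  ann <- data.frame(obs_id = mat$obs_ids, cell_type = ct,
                    stringsAsFactors = FALSE)
  act <- data.frame(obs_id = mat$obs_ids, active = active,
                    stringsAsFactors = FALSE)
  degs <- list(data.frame(cell_type = "fib", gene = sprintf("G%03d", 1:6)),
               data.frame(cell_type = "epi", gene = sprintf("G%03d", 5:10)))
  mm <- build_marker_matrix(mat, ann, act, degs)
  expect_equal(dim(mm$values), c(10, 4))
  expect_setequal(colnames(mm$values),
                  c("fib_active", "fib_inactive", "epi_active",
                    "epi_inactive"))
  # column values are phenotype means on the linear (expm1) scale
  expect_equal(mm$values["G001", "fib_active"],
               mean(vals[1, ct == "fib" & active]), tolerance = 1e-12)
  expect_equal(mm$values["G001", "fib_inactive"], 0)
  # a phenotype with zero cells is dropped with a warning
  act_all <- data.frame(obs_id = mat$obs_ids, active = TRUE)
  w <- capture_warnings(mm2 <- build_marker_matrix(mat, ann, act_all, degs))
  expect_match(w, "zero cells", all = TRUE)
  expect_length(w, 2)  # both inactive phenotypes dropped
  expect_equal(ncol(mm2$values), 2)
})

test_that("CIBERSORTx signature export round-trips bit-exactly", {
  mm <- make_markers()
  path <- withr::local_tempfile(fileext = ".txt")
  write_cibersortx_signature(mm, path)
  header <- readLines(path, n = 1)
  expect_identical(strsplit(header, "\t")[[1]][1], "GeneSymbol")
  back <- read_cibersortx_signature(path)
  expect_equal(back$values, mm$values)
  expect_equal(back$phenotypes, mm$phenotypes)
})

test_that("pure and noiseless mixed samples are recovered exactly", {
  mm <- make_markers()
  # a bulk sample copying one phenotype column scores 1 for it
  pure <- expr_matrix(mm$values[, "fib_active", drop = FALSE],
                      gene_ids = rownames(mm$values), obs_ids = "S1",
                      layer = "counts")
  sc <- score_bulk(pure, mm)
  expect_equal(unname(sc$coefficients[1, "fib_active"]), 1,
               tolerance = 1e-9)
  expect_equal(unname(sc$profibrotic[1, "fib"]), 1, tolerance = 1e-9)
  # 50/50 mixture of two orthogonal-support phenotypes
  mix <- 0.5 * mm$values[, "fib_active"] + 0.5 * mm$values[, "epi_active"]
  bulk <- expr_matrix(matrix(mix, ncol = 1),
                      gene_ids = rownames(mm$values), obs_ids = "S1",
                      layer = "counts")
  sc2 <- score_bulk(bulk, mm)
  expect_equal(unname(sc2$coefficients[1, c("fib_active", "epi_active")]),
               c(0.5, 0.5), tolerance = 1e-6)
})

test_that("relative-mode coefficients are simplex-valued and scale-free", {
  mm <- make_markers()
  sim <- simulate_bulk(mm, n_samples = 20, noise_sd = 0.05, seed = 5L)
  sc <- score_bulk(sim$bulk, mm)
  expect_true(all(sc$coefficients >= -1e-12))
  expect_equal(unname(rowSums(sc$coefficients)), rep(1, 20),
               tolerance = 1e-9)
  # scaling a sample leaves its normalized coefficients unchanged
  scaled <- sim$bulk
  scaled$values[, 1] <- scaled$values[, 1] * 37
  expect_equal(score_bulk(scaled, mm)$coefficients[1, ],
               sc$coefficients[1, ], tolerance = 1e-9)
  # no overlap -> error
  bad <- expr_matrix(matrix(1:4, 2, 2), gene_ids = c("X1", "X2"),
                     obs_ids = c("s1", "s2"), layer = "counts")
  expect_error(score_bulk(bad, mm), "no marker gene")
})

test_that("noisy mixture weights are recovered with small error", {
  mm <- make_markers()
  sim <- simulate_bulk(mm, n_samples = 50, noise_sd = 0.05, seed = 6L)
  expect_equal(unname(rowSums(sim$weights)), rep(1, 50), tolerance = 1e-12)
  sc <- score_bulk(sim$bulk, mm)
  mae <- mean(abs(sc$coefficients[, "fib_active"] -
                  sim$weights[, "fib_active"]))
  expect_lt(mae, 0.05)
  # noiseless mixtures are exact
  sim0 <- simulate_bulk(mm, n_samples = 10, noise_sd = 0, seed = 7L)
  sc0 <- score_bulk(sim0$bulk, mm)
  expect_equal(unname(sc0$coefficients), unname(sim0$weights),
               tolerance = 1e-6)
})
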