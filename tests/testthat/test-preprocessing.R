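test_that("QC filters apply all four thresholds with strict inequalities", {
  # c1 clean; each other cell violates exactly one rule -> 1 survivor
  m <- matrix(0L, 5, 5,
              dimnames = list(c("MT-X", "G1", "G2", "G3", "G4"),
                              paste0("c", 1:5)))
  m["G1", ] <- c(500L, 400L, 400L, 60000L, 400L)
  m["G2", ] <- c(300L, 300L, 300L, 300L, 300L)
  m["G3", ] <- c(0L, 0L, 0L, 0L, 200L)
  m["G4", ] <- c(0L, 0L, 0L, 0L, 100L)
  m["MT-X", ] <- c(10L, 500L, 0L, 10L, 10L)
  m <- Matrix::Matrix(m, sparse = TRUE)
  th <- qc_thresholds(min_genes = 2L, max_umis = 50000L, max_genes = 4L)
  kept <- qc_filter_cells(m, th)
  expect_false("c2" %in% colnames(kept))   # mito fraction 500/1200 over 0.15
  expect_false("c3" %in% colnames(kept))   # exactly min_genes detected: strict
  expect_false("c4" %in% colnames(kept))   # 60310 UMIs over the cap
  expect_false("c5" %in% colnames(kept))   # max_genes detected: strict
  expect_identical(colnames(kept), "c1")

  # boundary: exactly min_genes detected is removed, one more is kept
  m2 <- Matrix::Matrix(matrix(c(1, 1, 0, 1, 1, 1), 3, 2,
                              dimnames = list(c("A", "B", "C"), c("x", "y"))),
                       sparse = TRUE)
  th2 <- qc_thresholds(min_genes = 2L, max_genes = 10L)
  kept2 <- qc_filter_cells(m2, th2, mito_genes = rep(FALSE, 3))
  expect_identical(colnames(kept2), "y")

  expect_warning(qc_filter_cells(m2, qc_thresholds(min_genes = 5L, max_genes = 10L),
                                 mito_genes = rep(FALSE, 3)),
                 "no cells pass")
})

test_that("log-normalization follows e = ln(1e4 n / N + 1) with dominant-gene exclusion", {
  m <- Matrix::Matrix(matrix(c(10, 9990, 0, 500, 5000, 1000), 3, 2,
                             dimnames = list(c("A", "B", "C"), c("c1", "c2"))),
                      sparse = TRUE)
  e <- log_normalize(m, max_gene_share = 1)   # no exclusions
  expect_equal(e["A", "c1"], log(1e4 * 10 / 1e4 + 1))
  expect_equal(e["A", "c1"], log(11), tolerance = 1e-12)
  expect_equal(e["C", "c1"], 0)

  # B holds >20% of c1's UMIs -> excluded from every cell's denominator
  e2 <- log_normalize(m)
  expect_identical(attr(e2, "excluded_genes"), "B")
  # N_c1 = 10, N_c2 = 1500; B itself still normalized and reported
  expect_equal(e2["A", "c1"], log(1e4 * 10 / 10 + 1))
  expect_equal(e2["B", "c2"], log(1e4 * 5000 / 1500 + 1))
  expect_gt(e2["B", "c1"], 0)
})

test_that("log-normalization is monotone and invertible without exclusions", {
  set.seed(1)
  m <- Matrix::Matrix(matrix(rpois(200, 3), 20, 10,
                             dimnames = list(paste0("g", 1:20), paste0("c", 1:10))),
                      sparse = TRUE)
  e <- log_normalize(m, max_gene_share = 1)
  n_c <- attr(e, "cell_totals")
  back <- sweep(expm1(e), 2, n_c / 1e4, "*")
  expect_equal(back, as.matrix(m), tolerance = 1e-9, ignore_attr = TRUE)
  # monotone within a column
  ord_counts <- order(as.matrix(m)[, 1])
  expect_true(all(diff(e[ord_counts, 1]) >= 0))
})

test_that("analysis-gene selection removes IG genes always, sex genes only for NMF", {
  gm <- tibble::tibble(symbol = c("IGKC", "CD27", "XIST", "RPS4Y1", "IGHM"),
                       ig_locus = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_identical(gm$symbol[select_analysis_genes(gm, "nmf")], "CD27")
  expect_identical(gm$symbol[select_analysis_genes(gm, "de")],
                   c("CD27", "XIST", "RPS4Y1"))
  # prefix fallback without ig_locus column
  gm2 <- tibble::tibble(symbol = c("IGLV2-14", "TP53"))
  expect_identical(gm2$symbol[select_analysis_genes(gm2, "de")], "TP53")
})

test_that("pseudobulk excludes >5% genes from the denominator only", {
  # B holds 90% of counts, the ten others 1% each: denominator is 10
  m <- Matrix::Matrix(matrix(c(rep(1, 10), 90), 11, 1,
                             dimnames = list(c(paste0("g", 1:10), "B"), "c1")),
                      sparse = TRUE)
  pb <- pseudobulk(m)
  expect_equal(unname(pb["g1"]), 1 / 10 * 1e6)
  expect_equal(unname(pb["B"]), 90 / 10 * 1e6)   # reported, just not in the denominator

  # uniform genes at 1% each: plain CPM
  u <- Matrix::Matrix(matrix(rep(1, 20), 20, 1,
                             dimnames = list(paste0("g", 1:20), "c1")),
                      sparse = TRUE)
  expect_equal(unname(pseudobulk(u)), rep(1e6 / 20, 20))

  # single cell: equals that cell's scaled counts
  expect_equal(pseudobulk(m, "c1"), pb)
  expect_error(pseudobulk(m, character(0)), "empty")
})

test_that("pseudobulk of the union matches summed raw counts before scaling", {
  set.seed(2)
  m <- Matrix::Matrix(matrix(rpois(300, 5), 30, 10,
                             dimnames = list(paste0("g", 1:30), paste0("c", 1:10))),
                      sparse = TRUE)
  sums_a <- Matrix::rowSums(m[, 1:4])
  sums_b <- Matrix::rowSums(m[, 5:10])
  expect_equal(sums_a + sums_b, Matrix::rowSums(m))
})

test_that("CPM gene filter combines the three rules", {
  cpm <- rbind(g1 = c(4.9, 4.9), g2 = c(0, 6), g3 = c(100, 100),
               g4 = c(50, 50), g5 = c(10, 10), g6 = c(5, 4))
  fa <- c(0.5, 0.5, 0.01, 0.5, 0.02, 0.5)
  fn <- c(0.5, 0.5, 0.02, 0.5, 0.06, 0.5)
  ig <- c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  keep <- cpm_filter_genes(cpm, fa, fn, ig)
  # g1 below CPM everywhere; g3 under-expressed in both; g4 is IG; g6 boundary 5 kept
  expect_identical(rownames(cpm)[keep], c("g2", "g5", "g6"))
})
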