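test_that("group fold change follows the offset-regularised ratio", {
  spec <- fold_change_spec(0.126)
  # identical groups
  expect_equal(group_fold_change(c(1, 2, 3), c(1, 2, 3), spec), 1)
  # all-zero reference with mean_A = ln 2: (2 - 1 + .126) / (0 + .126)
  fc <- group_fold_change(rep(log(2), 4), rep(0, 4), spec)
  expect_equal(fc, 1.126 / 0.126, tolerance = 1e-12)
  expect_equal(fc, 8.937, tolerance = 1e-3)
  # reciprocal identity, exactly
  set.seed(3)
  a <- matrix(rexp(40), 4); b <- matrix(rexp(40), 4)
  expect_equal(group_fold_change(a, b, spec) * group_fold_change(b, a, spec),
               rep(1, 4), tolerance = 1e-14)
  expect_error(group_fold_change(numeric(0), 1, spec), "empty")
})

test_that("the default offset is half the minimum nonzero log-normalized value", {
  e <- matrix(c(0, 0.4, 1.2, 0), 2)
  expect_equal(default_fc_offset(e), 0.2)
  expect_error(default_fc_offset(matrix(0, 2, 2)), "nonzero")
})

test_that("row-wise Wilcoxon p agrees with wilcox.test and the exact oracle", {
  set.seed(11)
  for (rep in 1:10) {
    x <- rpois(6, 4); y <- rpois(8, 6)
    expr <- matrix(c(x, y), nrow = 1)
    p_pkg <- plasmasig:::wilcoxon_rows(expr, c(rep(TRUE, 6), rep(FALSE, 8)))
    p_ref <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
    expect_equal(unname(p_pkg), p_ref, tolerance = 1e-10)
    p_exact <- oracle_wilcoxon_exact(x, y)
    expect_lt(abs(p_pkg - p_exact), 0.02 + 0.03 * (p_exact > 0.5))
  }
})

test_that("within-patient DE is calibrated on null data and flags nothing", {
  set.seed(5)
  e <- matrix(rpois(100 * 400, 2), 100, 400,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("c%03d", 1:400)))
  e <- log1p(e)
  res <- within_patient_de(e, colnames(e)[1:200], fold_change_spec(0.126))
  expect_lte(mean(res$p < 0.05), 0.07)
  expect_lte(sum(res$deg), 1)
})

test_that("constant genes give p = 1 and are never flagged", {
  e <- rbind(flat = rep(1, 40), var = c(rnorm(20, 0), rnorm(20, 3)))
  colnames(e) <- paste0("c", 1:40)
  e <- pmax(e, 0)
  res <- within_patient_de(e, paste0("c", 1:20), fold_change_spec(0.126))
  expect_equal(res$p[res$gene == "flat"], 1)
  expect_false(res$deg[res$gene == "flat"])
})

test_that("planted fold changes are recovered by the Eq-style estimator", {
  cfg <- simulation_config(
    n_samples_per_stage = c(SMM = 1), cells_per_sample = c(600L, 600L),
    n_genes = 300L, purity_per_sample = c("SMM-1" = 0.5),
    planted_deg_spec = list(list(n_genes = 20, fc = 2, direction = "up")),
    seed = 31)
  co <- generate_cohort(cfg)
  e <- log_normalize(co$counts)
  ab <- intersect(co$cell_meta$cell_id[co$cell_meta$is_abnormal], colnames(e))
  nm <- intersect(co$cell_meta$cell_id[!co$cell_meta$is_abnormal], colnames(e))
  spec <- fold_change_spec(default_fc_offset(e))
  fc <- group_fold_change(e[co$truth$planted_degs$gene, ab],
                          e[co$truth$planted_degs$gene, nm], spec)
  expect_gte(median(fc), 1.7)
  expect_lte(median(fc), 2.3)
})

test_that("BH-adjusted flags are order-invariant and q is monotone in p", {
  set.seed(7)
  e <- log1p(matrix(rpois(50 * 60, 3), 50, 60,
                    dimnames = list(paste0("g", 1:50), paste0("c", 1:60))))
  res <- within_patient_de(e, paste0("c", 1:30), fold_change_spec(0.126))
  perm <- sample(nrow(e))
  res2 <- within_patient_de(e[perm, ], paste0("c", 1:30), fold_change_spec(0.126))
  m <- dplyr::left_join(res, res2, by = "gene")
  expect_equal(m$q.x, m$q.y)
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
})

test_that("pseudosample preparation splits populations and imputes NBM age", {
  cfg <- simulation_config(n_samples_per_stage = c(NBM = 1, MM = 1),
                           cells_per_sample = c(100L, 120L), n_genes = 80L,
                           purity_per_sample = c("NBM-1" = 0, "MM-1" = 0.5),
                           seed = 13)
  co <- generate_cohort(cfg)
  labels <- co$cell_meta |>
    dplyr::mutate(label = ifelse(.data$is_abnormal, "abnormal", "normal")) |>
    dplyr::select("cell_id", "sample_id", "label")
  smeta <- unique(co$cell_meta[, c("sample_id", "stage", "sex", "age",
                                   "batch", "preservation")])
  smeta$age[smeta$sample_id == "NBM-1"] <- NA
  smeta <- rbind(smeta,
                 tibble::tibble(sample_id = "NBM-2", stage = "NBM", sex = "F",
                                age = 50, batch = "B1", preservation = "fresh"))
  pt <- prepare_pseudosample_tables(co$counts, labels, smeta,
                                    co$gene_meta$ig_locus)
  # one pure-normal and one mixed sample -> 3 pseudosamples
  expect_equal(ncol(pt$counts), 3)
  expect_false(anyNA(pt$design$age))
  expect_equal(pt$design$age[pt$design$sample_id == "NBM-1"][1], 50)
  # summed counts equal brute-force sums
  ab_cells <- labels$cell_id[labels$sample_id == "MM-1" & labels$label == "abnormal"]
  expect_equal(pt$counts[, "MM-1.abnormal"],
               Matrix::rowSums(co$counts[pt$kept_genes, ab_cells]))
  # immunoglobulin genes never pass the filter
  expect_length(intersect(pt$kept_genes,
                          co$gene_meta$symbol[co$gene_meta$ig_locus]), 0)
})

test_that("cross-patient roll-up multiplies the max q and caps at 1", {
  degs <- tibble::tibble(
    gene = c("A", "A", "B", "C"),
    comparison = c("p1", "p2", "p1", "p1"),
    log_fc = c(1, 2, -1, 0.9),
    p = c(0.001, 0.0001, 0.01, 0.02),
    q = c(0.01, 0.002, 0.2, 0.05),
    deg = c(TRUE, TRUE, TRUE, TRUE))
  out <- cross_patient_max_q(degs, 10)
  a <- out[out$gene == "A", ]
  expect_equal(a$max_q, 0.1)                  # max(0.01, 0.002) * 10
  expect_equal(a$max_abs_log2_fc, 2 / log(2))
  expect_equal(a$n_samples_detected, 2L)
  expect_equal(out$max_q[out$gene == "B"], 1) # 0.2 * 10 capped
  expect_identical(out$direction[out$gene == "B"], "down")
  # single patient: q unchanged
  out1 <- cross_patient_max_q(degs[4, ], 1)
  expect_equal(out1$max_q, 0.05)
})
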