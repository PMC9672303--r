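test_that("compute_b follows the hyperparameter convention", {
  expect_equal(compute_b(3, matrix(2, 2, 2), 1), 2)
  expect_error(compute_b(2, matrix(1, 2, 2), 5), "exceed 2")
  expect_error(compute_b(10, matrix(0, 2, 2), 5), "degenerate")
  v1 <- matrix(1, 3, 3); v4 <- matrix(4, 3, 3)
  expect_equal(compute_b(10, v4, 5) / compute_b(10, v1, 5), 2)  # sqrt scaling
})

test_that("the MAP objective is non-increasing across seeds and shapes", {
  set.seed(100)
  shapes <- list(c(30, 50), c(60, 20), c(25, 120))
  for (shape in shapes) {
    for (s in 1:6) {
      V <- matrix(rpois(prod(shape), 3), shape[1], shape[2])
      cfg <- ardnmf_config(K_init = 6L, max_iter = 120L, tol = 1e-12, seed = s)
      f <- fit_ardnmf(V, cfg, trace_every = 1L)
      tr <- f$objective_trace
      expect_true(all(diff(tr) <= abs(tr[-length(tr)]) * 1e-9 + 1e-12))
    }
  }
})

test_that("a noiseless rank-1 matrix collapses to one component", {
  set.seed(3)
  w <- rexp(40) + 0.1
  h <- rexp(60) + 0.1
  V <- outer(w, h) * 5
  cfg <- ardnmf_config(K_init = 6L, max_iter = 2000L, tol = 1e-7, seed = 1)
  f <- fit_ardnmf(V, cfg, trace_every = 0L)
  expect_equal(f$K_final, 1)
  rel_err <- norm(V - f$W %*% f$H, "F") / norm(V, "F")
  expect_lt(rel_err, 0.01)
})

test_that("latent signatures are recovered from a small synthetic cohort", {
  cfg <- simulation_config(n_samples_per_stage = c(SMM = 2),
                           cells_per_sample = c(200L, 200L), n_genes = 120L,
                           k_true = 3L, seed = 42)
  co <- generate_cohort(cfg)
  mask <- select_analysis_genes(co$gene_meta, "nmf")
  V <- as.matrix(co$counts[co$gene_meta$symbol[mask], ])
  f <- fit_ardnmf(V, ardnmf_config(K_init = 6L, max_iter = 2000L, tol = 1e-5,
                                   seed = 7), trace_every = 0L)
  expect_true(f$K_final >= 2 && f$K_final <= 5)
  shared <- intersect(rownames(co$truth$true_W), rownames(f$W))
  cos <- oracle_matched_cosine(co$truth$true_W[shared, ], f$W[shared, ])
  expect_gte(cos, 0.8)
})

test_that("holdout projection recovers known activities and ranks W correctly", {
  set.seed(5)
  W <- matrix(rexp(50 * 3), 50, 3)
  h <- matrix(rexp(3 * 10) + 0.5, 3, 10)
  V_h <- W %*% h
  pr <- project_holdout(W, V_h, max_iter = 5000L, tol = 1e-10)
  expect_lt(max(abs(pr$H - h) / h), 0.01)
  expect_lt(pr$divergence / sum(V_h), 1e-4)

  # a mismatched random W explains the data strictly worse
  W_bad <- matrix(rexp(50 * 3), 50, 3)
  pr_bad <- project_holdout(W_bad, V_h, max_iter = 2000L)
  expect_gt(pr_bad$divergence, pr$divergence)
  expect_error(project_holdout(W, V_h[1:10, ]), "dimensions")
})

test_that("training and identical held-out cells give matching divergence", {
  set.seed(6)
  V <- matrix(rpois(40 * 80, 4), 40, 80)
  cfg <- ardnmf_config(K_init = 5L, max_iter = 600L, tol = 1e-6, seed = 2)
  f <- fit_ardnmf(V, cfg, trace_every = 0L)
  train_div <- plasmasig:::kl_divergence(V, f$W %*% f$H)
  pr <- project_holdout(f, V, max_iter = 2000L)
  expect_lt(abs(pr$divergence - train_div) / train_div, 0.05)
})

test_that("solution selection restricts to the modal K and minimal divergence", {
  mk <- function(K, div) {
    structure(list(K_final = K, heldout_divergence = div), class = "ardnmf_fit")
  }
  picked <- select_solution(list(mk(5, 10), mk(5, 8), mk(6, 1)))
  expect_equal(picked$K_final, 5)
  expect_equal(picked$heldout_divergence, 8)
  # single restart: returned unchanged
  one <- mk(4, 2)
  expect_identical(select_solution(list(one)), one)
  # bimodal K: smaller K wins
  picked2 <- select_solution(list(mk(4, 9), mk(4, 7), mk(6, 1), mk(6, 0.5)))
  expect_equal(picked2$K_final, 4)
})

test_that("factor normalization shifts weight into H leaving WH unchanged", {
  fit <- structure(list(
    W = matrix(c(2, 2, 1, 3), 2, 2), H = matrix(c(1, 2, 3, 2), 2, 2),
    lambda = c(1, 1), K_final = 2L, gene_ids = NULL, cell_ids = NULL
  ), class = "ardnmf_fit")
  before <- fit$W %*% fit$H
  nf <- normalize_factors(fit)
  expect_equal(colSums(nf$W), c(1, 1), tolerance = 1e-12)
  expect_equal(nf$W[, 1], c(0.5, 0.5))
  expect_equal(nf$H[1, ], c(4, 12))     # row scaled by the old column sum 4
  expect_equal(nf$W %*% nf$H, before, tolerance = 1e-10)

  fit$W[, 2] <- 0
  expect_warning(nf2 <- normalize_factors(fit), "pruned")
  expect_equal(nf2$K_final, 1L)
})

test_that("per-cell activity normalization divides by totals and drops zeros", {
  H <- matrix(c(10, 30, 2, 4), 2, 2)
  out <- normalize_activities_per_cell(H, c(100, 2))
  expect_equal(out[, 1], c(0.1, 0.3))
  expect_equal(out[, 2], c(1, 2))
  expect_warning(out2 <- normalize_activities_per_cell(H, c(100, 0)), "zero totals")
  expect_equal(ncol(out2), 1)
  # equal totals preserve activity ordering
  H2 <- matrix(runif(12), 3)
  out3 <- normalize_activities_per_cell(H2, rep(50, 4))
  expect_equal(apply(out3, 2, order), apply(H2, 2, order))
})

test_that("signature classification applies the patient and gene gap rules", {
  # 5 patients, 20 cells each; sig1 blows up in patient p1
  pats <- rep(paste0("p", 1:5), each = 20)
  H <- rbind(sig1 = rep(c(10, 1.0, 1.1, 0.9, 1.0), each = 20),
             sig2 = rep(1, 100), sig3 = rep(1, 100))
  W <- cbind(sig1 = c(0.4, 0.3, 0.2, 0.1),
             sig2 = c(0.8, 0.1, 0.05, 0.05),
             sig3 = c(0.25, 0.25, 0.25, 0.25))
  rownames(W) <- paste0("g", 1:4)
  cls <- classify_signatures(H, W, pats)
  expect_equal(cls$class, c("patient_specific", "single_gene", "interpretable"))
  expect_equal(cls$max_patient[1], "p1")
  expect_gte(cls$weight_gap[2], 0.5)
  expect_warning(classify_signatures(H[, 1:20], W, pats[1:20]), ">= 2 patients")
})

test_that("specificity follows the activity-weighted share and rows sum to 1", {
  # single signature: s = 1 for expressed genes
  W1 <- matrix(c(0.2, 0.8, 0), 3, 1, dimnames = list(paste0("g", 1:3), "sig1"))
  H1 <- matrix(rexp(10), 1, 10)
  s1 <- specificity_scores(W1, H1)
  expect_equal(unname(s1[1:2, 1]), c(1, 1))
  expect_equal(unname(s1[3, 1]), 0)      # all-zero weight: specificity 0

  W <- matrix(c(0.5, 0.5), 1, 2, dimnames = list("g1", c("a", "b")))
  H <- rbind(rep(10, 10), rep(30, 10))   # row sums 100 and 300
  s <- specificity_scores(W, H)
  expect_equal(unname(s[1, ]), c(0.25, 0.75))
  expect_equal(sum(s[1, ]), 1)

  rk <- rank_genes(W1, s1, n_top = 3)
  expect_equal(rk$gene[rk$rank == 1], "g2")
  expect_equal(rk$importance, rk$weight * rk$specificity)
})
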