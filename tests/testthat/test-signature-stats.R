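test_that("population means and bootstrap SEM behave like the analytic SEM", {
  labels <- tibble::tibble(cell_id = paste0("c", 1:100),
                           sample_id = "s1", label = "abnormal")
  # constant activity: SEM exactly 0
  H <- matrix(2, 1, 100, dimnames = list("sig1", labels$cell_id))
  pm <- population_means(H, labels, n_boot = 500, seed = 1)
  expect_equal(pm$mean, 2)
  expect_equal(pm$sem, 0)
  expect_equal(pm$n_cells, 100)

  # balanced 0/1 activities: SEM ~ sd/sqrt(n) = 0.05
  H2 <- matrix(rep(c(0, 1), 50), 1, 100, dimnames = list("sig1", labels$cell_id))
  pm2 <- population_means(H2, labels, n_boot = 5000, seed = 2)
  expect_equal(pm2$sem, 0.05, tolerance = 0.1)

  # determinism under a fixed seed
  pm3 <- population_means(H2, labels, n_boot = 5000, seed = 2)
  expect_identical(pm2$sem, pm3$sem)
})

test_that("Kruskal-Wallis group test matches the exact permutation oracle", {
  # table with a clear shift in group c, where the chi-square approximation
  # of the omnibus p is accurate
  vals <- c(1.2, 3.4, 2.2, 0.3, 2.8, 1.9, 3.3, 2.0, 6.0, 7.1, 5.9, 6.4)
  grp <- rep(c("a", "b", "c"), each = 4)
  act <- tibble::tibble(signature = "sig1", group = grp, value = vals)
  res <- group_activity_test(act)
  p_exact <- oracle_kw_exact(vals, grp)
  expect_lt(abs(res$omnibus$kw_p - p_exact), 0.02)
  expect_equal(nrow(res$pairwise), 3)   # all pairs, Bonferroni over 3
  expect_true(all(res$pairwise$p_bonferroni >= res$pairwise$p))
})

test_that("group test finds a strongly shifted group and respects the null", {
  set.seed(9)
  hits <- 0; power_hits <- 0; n_sim <- 60
  for (i in 1:n_sim) {
    null_act <- tibble::tibble(signature = "s", group = rep(c("a", "b", "c"), each = 8),
                               value = rnorm(24))
    r0 <- group_activity_test(null_act)
    if (any(r0$pairwise$significant)) hits <- hits + 1
    shift_act <- null_act
    shift_act$value[shift_act$group == "c"] <- rnorm(8, mean = 3)
    r1 <- group_activity_test(shift_act)
    if (any(r1$pairwise$significant[r1$pairwise$group1 == "c" |
                                      r1$pairwise$group2 == "c"])) {
      power_hits <- power_hits + 1
    }
  }
  expect_lte(hits / n_sim, 0.18)        # FWER controlled near 0.1
  expect_gte(power_hits / n_sim, 0.9)   # 3-SD shift detected
})

test_that("two groups fall back to a rank-sum test", {
  act <- tibble::tibble(signature = "s", group = rep(c("a", "b"), each = 6),
                        value = c(rnorm(6), rnorm(6, 5)))
  res <- group_activity_test(act)
  expect_equal(res$omnibus$n_groups, 2L)
  expect_lt(res$pairwise$p, 0.05)
})

test_that("Jonckheere-Terpstra matches enumeration and is extreme for perfect trends", {
  # perfectly increasing singleton groups: statistic at max, minimal p
  r <- trend_test(c(1, 2, 3), c("g1", "g2", "g3"),
                  levels = c("g1", "g2", "g3"))
  expect_equal(r$statistic, 3)          # all 3 ordered pairs concordant
  expect_equal(r$method, "exact permutation")
  expect_equal(r$p, 2 / 6)              # only the two extreme orderings

  set.seed(10)
  vals <- rnorm(9)
  grp <- rep(c("lo", "mid", "hi"), each = 3)
  r2 <- trend_test(vals, grp, levels = c("lo", "mid", "hi"))
  # independent check against the large-sample approximation
  r3 <- trend_test(vals, grp, levels = c("lo", "mid", "hi"), exact_max = 0L)
  expect_lt(abs(r2$p - r3$p), 0.15)
  expect_error(trend_test(1:4, rep(c("a", "b"), 2)), "3 ordered groups")
})

test_that("Jonckheere-Terpstra null p-values are roughly uniform", {
  set.seed(11)
  ps <- replicate(300, {
    trend_test(rnorm(30), rep(c("a", "b", "c"), each = 10),
               levels = c("a", "b", "c"), exact_max = 0L)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(ps >= 0 & ps <= 1))
})

test_that("intratumor heterogeneity flags CV > 1 with population SD", {
  H <- matrix(0, 2, 9, dimnames = list(c("sig1", "sig2"), paste0("c", 1:9)))
  cl <- rep(c("k1", "k2", "k3"), each = 3)
  H[1, ] <- rep(c(0, 0, 9), each = 3)    # cluster means 0, 0, 9
  H[2, ] <- 5                            # constant
  res <- intratumor_heterogeneity(H, cl)
  expect_equal(res$cv[res$signature == "sig1"], sqrt(18) / 3, tolerance = 1e-12)
  expect_equal(res$cv[res$signature == "sig1"], 1.414, tolerance = 1e-3)
  expect_true(res$heterogeneous[res$signature == "sig1"])
  expect_equal(res$cv[res$signature == "sig2"], 0)
  expect_false(res$heterogeneous[res$signature == "sig2"])

  # single cluster: CV undefined, not flagged
  res1 <- intratumor_heterogeneity(H, rep("k1", 9))
  expect_true(all(is.na(res1$cv)))
  expect_false(any(res1$heterogeneous))

  # invariance to cluster relabeling
  res2 <- intratumor_heterogeneity(H, rep(c("z9", "a1", "m5"), each = 3))
  expect_equal(res2$cv, res$cv)
})

test_that("batch screen reports perfect age correlation and skips constants", {
  cm <- tibble::tibble(cell_id = paste0("c", 1:40),
                       sample_id = rep(paste0("s", 1:8), each = 5))
  covs <- tibble::tibble(sample_id = paste0("s", 1:8),
                         sex = rep(c("F", "M"), 4),
                         preservation = rep("fresh", 8),
                         batch = rep(c("B1", "B2", "B3", "B1"), 2),
                         age = seq(40, 75, length.out = 8))
  ages <- setNames(covs$age, covs$sample_id)
  H <- matrix(rep(ages[cm$sample_id], each = 1), 1, 40,
              dimnames = list("sig1", cm$cell_id))
  res <- batch_association_checks(H, cm, covs)
  pear <- res[res$test == "pearson", ]
  expect_equal(pear$estimate, 1, tolerance = 1e-9)
  expect_lt(pear$p, 1e-6)
  # constant preservation covariate skipped entirely
  expect_false("preservation" %in% res$covariate)
  expect_true(all(c("sex", "batch", "age") %in% res$covariate))
})

test_that("size factors and bulk projection behave on proportional samples", {
  set.seed(12)
  base <- rpois(50, 40) + 1
  bulk <- cbind(s1 = base, s2 = 2 * base, s3 = rpois(50, 35) + 1)
  rownames(bulk) <- paste0("g", 1:50)
  sf <- size_factors(bulk)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2, tolerance = 1e-12)

  act <- bulk_signature_activity(bulk, paste0("g", 1:7))
  expect_equal(mean(act$activity), 0, tolerance = 1e-10)
  expect_error(size_factors(bulk[, 1, drop = FALSE]), ">= 2 bulk samples")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(13)
  bulk <- matrix(rpois(200, 30) + 1, 40, 5,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:5)))
  sf <- size_factors(bulk)
  ref <- DESeq2::estimateSizeFactorsForMatrix(bulk)
  expect_equal(unname(sf), unname(ref), tolerance = 1e-8)
})

test_that("bulk activity of the normal-PC gene set tracks the normal fraction", {
  # synthetic bulk mixtures of a normal and an abnormal expression profile
  set.seed(14)
  n_genes <- 60
  sig_genes <- paste0("g", 1:7)
  normal_prof <- rgamma(n_genes, 2, 1) + 0.5
  abnormal_prof <- normal_prof
  abnormal_prof[1:7] <- abnormal_prof[1:7] * 0.1   # signature genes lost in tumor
  fracs <- seq(0.05, 0.95, length.out = 10)        # normal fraction per sample
  bulk <- sapply(fracs, function(f) {
    rpois(n_genes, 3000 * (f * normal_prof + (1 - f) * abnormal_prof) /
            sum(f * normal_prof + (1 - f) * abnormal_prof))
  })
  dimnames(bulk) <- list(paste0("g", 1:n_genes), paste0("s", 1:10))
  act <- bulk_signature_activity(bulk, sig_genes)
  purity <- 1 - fracs
  expect_lt(cor(act$activity, purity), 0)
  expect_gt(cor(act$activity, fracs), 0.9)
})
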