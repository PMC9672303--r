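#' Mean signature activity per sample population with bootstrap SEM
#'
#' For every (sample, population, signature) combination, the mean activity
#' over cells and its standard error computed as the SD of the means of
#' `n_boot` bootstrap resamples of the cells (resample counts drawn
#' multinomially, which is the bootstrap's exact resampling distribution).
#'
#' @param H_norm Signatures x cells activity matrix.
#' @param labels Tibble with `cell_id`, `sample_id`, `label`
#'   (normal/abnormal).
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed Seed for the resampling.
#' @return Tibble with `sample_id`, `population`, `signature`, `mean`,
#'   `sem`, `n_cells`.
#' @export
population_means <- function(H_norm, labels, n_boot = 10000L, seed = 1L) {
  set.seed(substream_seed(seed, "bootstrap_sem"))
  k_names <- rownames(H_norm) %||% paste0("sig", seq_len(nrow(H_norm)))
  groups <- labels |>
    dplyr::filter(.data$label %in% c("normal", "abnormal"),
                  .data$cell_id %in% colnames(H_norm))
  keys <- unique(groups[, c("sample_id", "label")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    cells <- groups$cell_id[groups$sample_id == keys$sample_id[i] &
                              groups$label == keys$label[i]]
    n <- length(cells)
    if (n == 0) return(NULL)
    A <- Matrix::t(H_norm[, cells, drop = FALSE])      # n x K
    m <- colMeans(A)
    sem <- if (n == 1) rep(0, length(m)) else {
      cnt <- rmultinom(n_boot, n, rep(1 / n, n))        # n x n_boot
      boots <- crossprod(cnt, as.matrix(A)) / n         # n_boot x K
      apply(boots, 2, sd)
    }
    const <- apply(as.matrix(A), 2, function(v) all(v == v[1]))
    sem[const] <- 0
    tibble(sample_id = keys$sample_id[i], population = keys$label[i],
           signature = k_names, mean = unname(m), sem = unname(sem),
           n_cells = n)
  })
  dplyr::bind_rows(out)
}

#' Kruskal-Wallis omnibus and Dunn pairwise tests on population activities
#'
#' Per signature: a Kruskal-Wallis test (with tie correction) across the
#' groups, followed by Dunn's z-tests on the pooled ranks for each pairwise
#' comparison, Bonferroni-corrected over the comparisons performed.
#' Significance is declared at family-wise error rate `fwer`. With exactly
#' two groups the omnibus falls back to a Wilcoxon rank-sum test.
#'
#' @param activity Tibble with `signature`, `group`, `value` (typically one
#'   value per sample population from [population_means()]).
#' @param comparisons Optional list of length-2 character vectors naming the
#'   pairs to test; default all pairs.
#' @param fwer Family-wise error rate (default 0.1).
#' @param min_per_group Groups with fewer values are dropped with a warning.
#' @return List of tibbles: `omnibus` (`signature`, `kw_p`, `n_groups`) and
#'   `pairwise` (`signature`, `group1`, `group2`, `z`, `p`, `p_bonferroni`,
#'   `significant`).
#' @export
group_activity_test <- function(activity, comparisons = NULL, fwer = 0.1,
                                min_per_group = 2L) {
  omni <- list(); pairs_out <- list()
  for (sig in unique(activity$signature)) {
    d <- activity[activity$signature == sig, ]
    sizes <- table(d$group)
    small <- names(sizes)[sizes < min_per_group]
    if (length(small) > 0) {
      warning("dropping group(s) with < ", min_per_group, " values: ",
              paste(small, collapse = ", "))
      d <- d[!d$group %in% small, ]
    }
    groups <- unique(d$group)
    if (length(groups) < 2) next
    if (length(groups) == 2) {
      p <- wilcox.test(value ~ group, data = d, exact = FALSE)$p.value
      omni[[sig]] <- tibble(signature = sig, kw_p = p, n_groups = 2L)
      pr <- tibble(signature = sig, group1 = groups[1], group2 = groups[2],
                   z = NA_real_, p = p, p_bonferroni = p,
                   significant = p < fwer)
      pairs_out[[sig]] <- pr
      next
    }
    kw <- kruskal.test(d$value, factor(d$group))
    omni[[sig]] <- tibble(signature = sig, kw_p = kw$p.value,
                          n_groups = length(groups))
    pr <- dunn_test(d$value, d$group, comparisons)
    pr$signature <- sig
    pr$significant <- pr$p_bonferroni < fwer
    pairs_out[[sig]] <- pr[, c("signature", "group1", "group2", "z", "p",
                               "p_bonferroni", "significant")]
  }
  list(omnibus = dplyr::bind_rows(omni), pairwise = dplyr::bind_rows(pairs_out))
}

# Dunn's post-hoc z tests on pooled ranks with tie correction and
# Bonferroni over the performed comparisons.
dunn_test <- function(values, groups, comparisons = NULL) {
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  gmeans <- tapply(r, groups, mean)
  gn <- table(groups)
  if (is.null(comparisons)) {
    comparisons <- combn(names(gmeans), 2, simplify = FALSE)
  }
  comparisons <- Filter(function(p) all(p %in% names(gmeans)), comparisons)
  m <- length(comparisons)
  out <- lapply(comparisons, function(pair) {
    g1 <- pair[1]; g2 <- pair[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / gn[[g1]] + 1 / gn[[g2]]))
    z <- (gmeans[[g1]] - gmeans[[g2]]) / se
    p <- 2 * pnorm(-abs(z))
    tibble(group1 = g1, group2 = g2, z = unname(z), p = unname(p),
           p_bonferroni = min(unname(p) * m, 1))
  })
  dplyr::bind_rows(out)
}

#' Jonckheere-Terpstra trend test for ordered groups
#'
#' The statistic is the sum of pairwise Mann-Whitney counts over all ordered
#' group pairs. For total `n <= exact_max` a full permutation enumeration
#' of group assignments gives the exact two-sided p; otherwise a normal
#' approximation with continuity correction (ties handled by counting 0.5)
#' is used.
#'
#' @param values Numeric responses.
#' @param groups Ordered factor (or vector coerced with the order of
#'   `levels`) of group membership; at least 3 groups.
#' @param levels Optional explicit group order.
#' @param exact_max Enumeration cutoff on total n (default 12).
#' @return Tibble with `statistic`, `p`, `method`.
#' @export
trend_test <- function(values, groups, levels = NULL, exact_max = 12L) {
  if (is.null(levels)) {
    levels <- if (is.factor(groups)) base::levels(groups) else unique(groups)
  }
  groups <- factor(as.character(groups), levels = levels)
  if (nlevels(groups) < 3) stop("trend test needs >= 3 ordered groups")
  n <- length(values)
  if (n <= exact_max) {
    stat <- jt_statistic(values, as.integer(groups))
    sizes <- tabulate(groups)
    perms <- multiset_permutations(sizes)
    stats <- apply(perms, 1, function(g) jt_statistic(values, g))
    dev <- abs(stats - mean(stats))
    p <- mean(dev >= abs(stat - mean(stats)) - 1e-12)
    return(tibble(statistic = stat, p = p, method = "exact permutation"))
  }
  stat <- jt_statistic(values, as.integer(groups))
  sizes <- tabulate(groups)
  mu <- (n^2 - sum(sizes^2)) / 4
  sig2 <- (n^2 * (2 * n + 3) - sum(sizes^2 * (2 * sizes + 3))) / 72
  z <- (abs(stat - mu) - 0.5) / sqrt(sig2)
  tibble(statistic = stat, p = min(2 * pnorm(-max(z, 0)), 1),
         method = "normal approximation")
}

# sum over ordered group pairs of #(x_i < x_j) + 0.5 #(x_i == x_j)
jt_statistic <- function(values, group_idx) {
  ng <- max(group_idx)
  total <- 0
  for (i in seq_len(ng - 1)) {
    vi <- values[group_idx == i]
    for (j in (i + 1):ng) {
      vj <- values[group_idx == j]
      if (length(vi) == 0 || length(vj) == 0) next
      cmp <- outer(vi, vj, "<")
      eq <- outer(vi, vj, "==")
      total <- total + sum(cmp) + 0.5 * sum(eq)
    }
  }
  total
}

# all distinct assignments of n items into groups of the given sizes,
# one assignment per row (values are group indices)
multiset_permutations <- function(sizes) {
  n <- sum(sizes)
  acc <- vector("list", 0)
  recurse <- function(prefix, remaining) {
    if (length(prefix) == n) {
      acc[[length(acc) + 1]] <<- prefix
      return(invisible())
    }
    for (g in seq_along(remaining)) {
      if (remaining[g] > 0) {
        rem <- remaining
        rem[g] <- rem[g] - 1L
        recurse(c(prefix, g), rem)
      }
    }
  }
  recurse(integer(0), as.integer(sizes))
  do.call(rbind, acc)
}

#' Intratumor heterogeneity of signature activities
#'
#' For one sample's abnormal cells grouped into clusters, computes per
#' signature the vector of cluster mean activities and its coefficient of
#' variation (population SD over mean); a sample-signature pair is flagged
#' heterogeneous when CV > 1. A single cluster leaves the CV undefined and
#' the flag `FALSE`.
#'
#' @param H_norm Signatures x cells activity matrix (abnormal cells).
#' @param cluster_of_cell Cluster label per column of `H_norm`.
#' @param cv_threshold Flag threshold (default 1).
#' @return Tibble with `signature`, `n_clusters`, `cv`, `heterogeneous`,
#'   and a list-column `cluster_means`.
#' @export
intratumor_heterogeneity <- function(H_norm, cluster_of_cell, cv_threshold = 1) {
  stopifnot(ncol(H_norm) == length(cluster_of_cell))
  k_names <- rownames(H_norm) %||% paste0("sig", seq_len(nrow(H_norm)))
  cl <- factor(cluster_of_cell)
  out <- lapply(seq_len(nrow(H_norm)), function(k) {
    mu <- tapply(H_norm[k, ], cl, mean)
    nclust <- length(mu)
    if (nclust < 2 || mean(mu) == 0) {
      return(tibble(signature = k_names[k], n_clusters = nclust,
                    cv = NA_real_, heterogeneous = FALSE,
                    cluster_means = list(as.numeric(mu))))
    }
    pop_sd <- sqrt(mean((mu - mean(mu))^2))
    cv <- pop_sd / mean(mu)
    tibble(signature = k_names[k], n_clusters = nclust, cv = cv,
           heterogeneous = cv > cv_threshold,
           cluster_means = list(as.numeric(mu)))
  })
  dplyr::bind_rows(out)
}

#' Screen signature activities for batch-variable associations
#'
#' On normal cells only (where no biological activity differences are
#' expected), tests each signature's per-sample mean activity against each
#' covariate: rank-sum for binary covariates (sex, fresh/frozen),
#' Kruskal-Wallis for multi-level batch, and Pearson plus Spearman
#' correlation for age. Constant covariates are skipped.
#'
#' @param H_norm Signatures x normal-cells activity matrix.
#' @param cell_meta Tibble with `cell_id`, `sample_id` covering the columns.
#' @param sample_covariates Tibble with `sample_id` and covariate columns.
#' @param covariates Covariate column names to screen.
#' @param alpha Screening threshold recorded in the output (default 0.05).
#' @return Tibble with `signature`, `covariate`, `test`, `estimate`, `p`,
#'   `flagged`.
#' @export
batch_association_checks <- function(H_norm, cell_meta, sample_covariates,
                                     covariates = c("sex", "preservation",
                                                    "batch", "age"),
                                     alpha = 0.05) {
  k_names <- rownames(H_norm) %||% paste0("sig", seq_len(nrow(H_norm)))
  sample_of <- setNames(cell_meta$sample_id, cell_meta$cell_id)
  sid <- unname(sample_of[colnames(H_norm)])
  idx_by_sample <- split(seq_len(ncol(H_norm)), sid)
  per_sample <- vapply(idx_by_sample, function(ix) {
    rowMeans(H_norm[, ix, drop = FALSE])
  }, numeric(nrow(H_norm)))
  if (is.null(dim(per_sample))) {
    per_sample <- matrix(per_sample, nrow = 1,
                         dimnames = list(NULL, names(idx_by_sample)))
  }
  samp_ids <- colnames(per_sample)
  cov_df <- sample_covariates[match(samp_ids, sample_covariates$sample_id), ]

  out <- list()
  for (k in seq_len(nrow(per_sample))) {
    act <- per_sample[k, ]
    for (cv in covariates) {
      x <- cov_df[[cv]]
      if (is.null(x) || length(unique(x[!is.na(x)])) < 2) next
      if (is.numeric(x)) {
        for (meth in c("pearson", "spearman")) {
          ct <- suppressWarnings(cor.test(act, x, method = meth, exact = FALSE))
          out[[length(out) + 1]] <- tibble(
            signature = k_names[k], covariate = cv, test = meth,
            estimate = unname(ct$estimate), p = ct$p.value,
            flagged = ct$p.value < alpha)
        }
      } else if (length(unique(x)) == 2) {
        p <- suppressWarnings(wilcox.test(act ~ factor(x), exact = FALSE)$p.value)
        out[[length(out) + 1]] <- tibble(
          signature = k_names[k], covariate = cv, test = "rank_sum",
          estimate = NA_real_, p = p, flagged = p < alpha)
      } else {
        p <- kruskal.test(act, factor(x))$p.value
        out[[length(out) + 1]] <- tibble(
          signature = k_names[k], covariate = cv, test = "kruskal_wallis",
          estimate = NA_real_, p = p, flagged = p < alpha)
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Median-of-ratios size factors for bulk samples
#'
#' Each sample's factor is the median over genes (with positive geometric
#' mean) of the ratio of the gene's count to its geometric mean across
#' samples.
#'
#' @param bulk_counts Genes x samples count matrix (>= 2 samples).
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(bulk_counts) {
  bulk_counts <- as.matrix(bulk_counts)
  if (ncol(bulk_counts) < 2) stop("need >= 2 bulk samples")
  log_gm <- rowMeans(log(bulk_counts))
  use <- is.finite(log_gm)                      # drops genes with any zero
  if (!any(use)) stop("no genes with positive counts in all samples")
  sf <- apply(bulk_counts[use, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_gm[use]))
  })
  setNames(sf, colnames(bulk_counts))
}

#' Project a signature onto bulk samples via z-scored log expression
#'
#' Normalizes counts by size factors, scales to per-million, takes
#' `log1p`, z-scores each signature gene across samples, and averages the
#' z-scores. Zero-variance genes contribute 0 with a warning.
#'
#' @param bulk_counts Genes x samples count matrix.
#' @param signature_genes Gene symbols of the signature's top genes (the
#'   normal plasma cell signature uses CD27, CD79A, RNU12, JSRP1, SAT1,
#'   CTSH, HCST).
#' @param sf Optional precomputed [size_factors()].
#' @return Tibble with `sample_id` and `activity` (mean z-score; column
#'   means are ~0 by construction).
#' @export
bulk_signature_activity <- function(bulk_counts, signature_genes, sf = NULL) {
  stopifnot(length(signature_genes) > 0)
  bulk_counts <- as.matrix(bulk_counts)
  if (is.null(sf)) sf <- size_factors(bulk_counts)
  norm <- sweep(bulk_counts, 2, sf, "/")
  cpm <- sweep(norm, 2, colSums(norm), "/") * 1e6
  logtpm <- log1p(cpm)
  genes <- intersect(signature_genes, rownames(logtpm))
  if (length(genes) == 0) stop("none of the signature genes found")
  z <- t(apply(logtpm[genes, , drop = FALSE], 1, function(v) {
    if (sd(v) == 0) {
      warning("zero-variance gene; z set to 0")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / sd(v)
  }))
  tibble(sample_id = colnames(bulk_counts) %||% as.character(seq_len(ncol(bulk_counts))),
         activity = colMeans(z))
}
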