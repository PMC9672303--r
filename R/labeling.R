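#' Cluster cells of one sample with a graph community-detection backend
#'
#' A pluggable stand-in for the per-sample clustering step: PCA on scaled
#' log-normalized expression of the supplied genes, a shared-nearest-neighbor
#' style kNN graph, and igraph Louvain communities. Immunoglobulin genes
#' should be excluded from `genes` by the caller (see
#' [select_analysis_genes()]) so clonal chains cannot drive the clustering.
#'
#' @param norm_expr Genes x cells matrix of log-normalized expression.
#' @param genes Genes to cluster on (default: all rows).
#' @param n_pcs Number of principal components (default 10).
#' @param k_neighbors kNN graph degree (default 15).
#' @param resolution Louvain resolution (default 0.6).
#' @param seed Integer seed for the community detection.
#' @return Named integer vector of cluster labels per cell.
#' @export
cluster_cells <- function(norm_expr, genes = NULL, n_pcs = 10L,
                          k_neighbors = 15L, resolution = 0.6, seed = 1L) {
  if (!is.null(genes)) norm_expr <- norm_expr[genes, , drop = FALSE]
  x <- t(as.matrix(norm_expr))
  nc <- nrow(x)
  if (nc < 3) return(setNames(rep(1L, nc), rownames(x)))
  keep <- apply(x, 2, sd) > 0
  x <- scale(x[, keep, drop = FALSE])
  x[x > 10] <- 10                                    # clip like the field does
  n_pcs <- min(n_pcs, ncol(x) - 1, nc - 1)
  pcs <- prcomp(x, rank. = n_pcs)$x
  k <- min(k_neighbors, nc - 1)
  d <- as.matrix(dist(pcs))
  edges <- do.call(rbind, lapply(seq_len(nc), function(i) {
    nn <- order(d[i, ])[2:(k + 1)]
    cbind(i, nn)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  setNames(as.integer(igraph::membership(comm)), rownames(x))
}

#' Automated normal/abnormal labeling of one sample's cells
#'
#' An automated surrogate for manual cluster curation: every cluster whose
#' dominant light-chain fraction exceeds `chain_purity_threshold` *and*
#' whose kappa fraction departs from the normal-cell prior expectation by
#' more than `prior_margin`, or whose mean driver-gene expression exceeds
#' the other clusters by `driver_z_margin` pooled SDs, is called abnormal;
#' all other clusters are normal. The per-sample purity is the abnormal
#' fraction with its conjugate Beta 95% CI.
#'
#' @param chains Tibble from [assign_light_chain()] for this sample's cells.
#' @param clusters Named cluster labels per cell (e.g. [cluster_cells()]).
#' @param prior A [kappa_prior()] for the normal kappa fraction.
#' @param norm_expr Optional genes x cells matrix, needed only when
#'   `driver_genes` is non-empty.
#' @param driver_genes Optional oncogene symbols (e.g. CCND1) whose
#'   overexpression marks an abnormal cluster.
#' @param chain_purity_threshold Dominant-chain fraction above which a
#'   cluster looks clonal (default 0.9).
#' @param prior_margin Minimum |kappa fraction - mu| for the clonal call
#'   (default 0.2).
#' @param driver_z_margin z-score margin for the driver-gene rule (default 2).
#' @return A `cell_labels` list: `labels` tibble (`cell_id`, `cluster`,
#'   `label`), `clusters` tibble with per-cluster evidence, and `purity`
#'   tibble (`estimate`, `ci_lo`, `ci_hi`).
#' @export
label_cells <- function(chains, clusters, prior, norm_expr = NULL,
                        driver_genes = character(),
                        chain_purity_threshold = 0.9, prior_margin = 0.2,
                        driver_z_margin = 2) {
  if (is.null(clusters) || length(clusters) == 0) stop("cluster labels required")
  stopifnot(inherits(prior, "kappa_prior"))
  df <- chains |> dplyr::mutate(cluster = unname(clusters[.data$cell_id]))
  if (anyNA(df$cluster)) stop("every cell needs a cluster label")

  ev <- df |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_assigned = sum(.data$chain != "unassigned"),
      frac_kappa = ifelse(n_assigned > 0,
                          sum(.data$chain == "kappa") / n_assigned, NA_real_),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      dominant_frac = pmax(.data$frac_kappa, 1 - .data$frac_kappa),
      chain_call = !is.na(.data$dominant_frac) &
        .data$dominant_frac > chain_purity_threshold &
        abs(.data$frac_kappa - prior$mu) > prior_margin
    )

  driver_call <- rep(FALSE, nrow(ev))
  if (length(driver_genes) > 0) {
    if (is.null(norm_expr)) stop("norm_expr required for driver-gene rule")
    dg <- intersect(driver_genes, rownames(norm_expr))
    if (length(dg) > 0) {
      score <- colMeans(norm_expr[dg, df$cell_id, drop = FALSE])
      by_cl <- tapply(score, df$cluster, mean)
      by_cl <- by_cl[as.character(ev$cluster)]
      for (i in seq_along(by_cl)) {
        others <- by_cl[-i]
        if (length(others) >= 2 && sd(others) > 0) {
          driver_call[i] <- by_cl[i] > mean(others) + driver_z_margin * sd(others)
        }
      }
    }
  }
  ev$driver_call <- driver_call
  ev$label <- ifelse(ev$chain_call | ev$driver_call, "abnormal", "normal")

  labels <- df |>
    dplyr::left_join(ev |> dplyr::select("cluster", "label"), by = "cluster") |>
    dplyr::select("cell_id", "cluster", "label")
  n_ab <- sum(labels$label == "abnormal")
  structure(list(labels = labels, clusters = ev,
                 purity = binomial_purity_ci(n_ab, nrow(labels))),
            class = "cell_labels")
}

#' @export
print.cell_labels <- function(x, ...) {
  cat(sprintf("<cell_labels> %d cells, %d clusters, purity %.3f [%.3f, %.3f]\n",
              nrow(x$labels), nrow(x$clusters), x$purity$estimate,
              x$purity$ci_lo, x$purity$ci_hi))
  invisible(x)
}

#' Label every sample of a cohort and compare the two purity estimators
#'
#' Runs light-chain assignment, per-sample clustering, [label_cells()], and
#' [purity_posterior()] for each sample, returning the per-sample comparison
#' of the two estimators: label-derived purity (with Beta CI) next to the Bayesian
#' posterior mode (with posterior CI).
#'
#' @param norm_expr Genes x cells log-normalized expression for the cohort.
#' @param cell_meta Tibble with `cell_id` and `sample_id` (and `stage` to
#'   identify NBM samples when `prior` is `NULL`).
#' @param gene_meta Gene metadata for [select_analysis_genes()].
#' @param prior Optional [kappa_prior()]; when `NULL`, estimated from the
#'   samples whose `stage == "NBM"`.
#' @param seed Seed for the clustering backend.
#' @param ... Passed to [label_cells()].
#' @return List with `purity` (per-sample tibble with both estimators) and
#'   `labels` (per-cell tibble).
#' @export
label_cohort <- function(norm_expr, cell_meta, gene_meta, prior = NULL,
                         seed = 1L, ...) {
  chains <- assign_light_chain(norm_expr)
  sample_of <- setNames(cell_meta$sample_id, cell_meta$cell_id)
  summ <- light_chain_summary(chains, sample_of)
  if (is.null(prior)) {
    nbm <- cell_meta$sample_id[cell_meta$stage == "NBM"]
    prior <- estimate_normal_kappa_prior(summ[summ$sample_id %in% unique(nbm), ])
  }
  keep_genes <- gene_meta$symbol[select_analysis_genes(gene_meta, "nmf")]
  samples <- unique(cell_meta$sample_id)
  res <- lapply(samples, function(sid) {
    cells <- cell_meta$cell_id[cell_meta$sample_id == sid]
    expr_s <- norm_expr[, cells, drop = FALSE]
    cl <- cluster_cells(expr_s, genes = intersect(keep_genes, rownames(expr_s)),
                        seed = substream_seed(seed, sid))
    lab <- label_cells(chains[chains$cell_id %in% cells, ], cl, prior,
                       norm_expr = expr_s, ...)
    s <- summ[summ$sample_id == sid, ]
    post <- if (nrow(s) == 1 && s$N >= 1) {
      purity_posterior(s$N, s$n_kappa, prior)
    } else NULL
    list(sid = sid, lab = lab, post = post)
  })
  purity <- dplyr::bind_rows(lapply(res, function(r) {
    g <- if (!is.null(r$post)) glance(r$post) else
      tibble(mode = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
             N = NA_integer_, n_kappa = NA_integer_)
    tibble(sample_id = r$sid,
           purity_label = r$lab$purity$estimate,
           label_ci_lo = r$lab$purity$ci_lo, label_ci_hi = r$lab$purity$ci_hi,
           purity_bayes = g$mode, bayes_ci_lo = g$ci_lo, bayes_ci_hi = g$ci_hi)
  }))
  labels <- dplyr::bind_rows(lapply(res, function(r) {
    r$lab$labels |> dplyr::mutate(sample_id = r$sid)
  }))
  list(purity = purity, labels = labels, prior = prior)
}

#' Plot the two purity estimators against each other
#'
#' @param purity Tibble from [label_cohort()]`$purity`.
#' @return A ggplot.
#' @export
plot_purity_comparison <- function(purity) {
  ggplot2::ggplot(purity, ggplot2::aes(x = .data$purity_label,
                                       y = .data$purity_bayes)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$bayes_ci_lo,
                                        ymax = .data$bayes_ci_hi),
                           width = 0, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "purity (cluster labels)", y = "purity (Bayesian mode)") +
    ggplot2::theme_minimal()
}
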