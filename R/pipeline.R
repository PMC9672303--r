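#' Resolved configuration for the end-to-end pipeline
#'
#' Collects every stage's parameters with the analysis defaults, at the
#' desk-scale fixture sizes: 12 samples (3 per stage), a few hundred cells
#' each, 500 genes, and 10 NMF restarts from a compact `K_init`. A single
#' global seed is fanned out to the stages through named substreams, so each
#' stage is reproducible independently of execution order. The returned
#' object is fully resolved: every parameter is present, nothing is
#' defaulted silently downstream.
#'
#' @param seed Global integer seed.
#' @param simulation A [simulation_config()]; defaults to the desk-scale
#'   fixture cohort.
#' @param qc A [qc_thresholds()].
#' @param fc_offset Fold-change offset, or `NULL` to derive from the data.
#' @param nmf An [ardnmf_config()]; the pipeline default trades the full-scale
#'   `K_init = 50` for a compact rank ceiling suited to the fixture.
#' @param driver_genes Oncogene symbols for the labeling heuristic.
#' @param signature_genes Gene list for the bulk projection stage (unused by
#'   the default stages; kept so the config echo is complete).
#' @param n_boot Bootstrap replicates for population SEMs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            simulation = NULL,
                            qc = qc_thresholds(),
                            fc_offset = NULL,
                            nmf = NULL,
                            driver_genes = character(),
                            signature_genes = character(),
                            n_boot = 1000L) {
  if (is.null(simulation)) {
    simulation <- simulation_config(
      n_samples_per_stage = c(NBM = 3, MGUS = 3, SMM = 3, MM = 3),
      cells_per_sample = c(80L, 160L), n_genes = 500L, k_true = 5L,
      planted_deg_spec = list(list(n_genes = 25, fc = 2.5, direction = "up")),
      seed = substream_seed(seed, "simulate"))
  }
  if (is.null(nmf)) {
    nmf <- ardnmf_config(K_init = 12L, max_iter = 1200L, tol = 1e-5,
                         n_restarts = 10L,
                         seed = substream_seed(seed, "nmf"))
  }
  structure(list(seed = as.integer(seed), simulation = simulation, qc = qc,
                 fc_offset = fc_offset, nmf = nmf,
                 driver_genes = driver_genes,
                 signature_genes = signature_genes,
                 n_boot = as.integer(n_boot)),
            class = "pipeline_config")
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in canonical order
#' (`simulate, qc, normalize, purity, label, de, nmf, sigstats, report`),
#' carrying state in memory and writing each stage's tables under
#' `out_dir/<stage>/`. Stages whose upstream results are missing raise an
#' error naming the stage to run first. Reruns with the same config are
#' byte-identical.
#'
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @param stages Stages to run (default all).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         stages = c("simulate", "qc", "normalize", "purity",
                                    "label", "de", "nmf", "sigstats", "report")) {
  order_all <- c("simulate", "qc", "normalize", "purity", "label", "de",
                 "nmf", "sigstats", "report")
  stages <- order_all[order_all %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  # full resolved configuration echo: no silent defaults downstream
  jsonlite::write_json(rapply(unclass(config), unclass, how = "replace"),
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  st <- new.env(parent = emptyenv())
  log_lines <- c(sprintf("seed\t%d", config$seed))
  need <- function(what, from) {
    if (!exists(what, envir = st)) {
      stop("stage requires '", from, "' to run first (missing ", what, ")")
    }
    get(what, envir = st)
  }

  for (stage in stages) {
    sdir <- file.path(out_dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    switch(stage,
      simulate = {
        cohort <- generate_cohort(config$simulation)
        st$cohort <- cohort
        write_cohort(cohort, file.path(sdir, "cohort"))
        write_tsv_plain(cohort$truth$samples, file.path(sdir, "truth_samples.tsv"))
        write_tsv_plain(cohort$truth$planted_degs, file.path(sdir, "planted_degs.tsv"))
        log_lines <- c(log_lines, sprintf("simulate\tcells\t%d\tgenes\t%d",
                                          ncol(cohort$counts), nrow(cohort$counts)))
      },
      qc = {
        cohort <- if (exists("cohort", envir = st)) st$cohort else {
          p <- file.path(out_dir, "simulate", "cohort")
          if (!dir.exists(p)) stop("stage requires 'simulate' to run first (missing cohort)")
          read_cohort(p)
        }
        st$cohort <- cohort
        filtered <- qc_filter_cells(cohort$counts, config$qc,
                                    mito_genes = cohort$gene_meta$mito)
        st$counts <- filtered
        st$cell_meta <- cohort$cell_meta[cohort$cell_meta$cell_id %in%
                                           colnames(filtered), ]
        writeLines(as.character(colnames(filtered) %||% character()),
                   file.path(sdir, "kept_barcodes.tsv"))
        log_lines <- c(log_lines, sprintf("qc\tcells_in\t%d\tcells_kept\t%d",
                                          ncol(cohort$counts), ncol(filtered)))
      },
      normalize = {
        counts <- need("counts", "qc")
        st$norm_expr <- log_normalize(counts)
        writeLines(attr(st$norm_expr, "excluded_genes"),
                   file.path(sdir, "excluded_genes.tsv"))
        log_lines <- c(log_lines, sprintf("normalize\texcluded_genes\t%d",
                                          length(attr(st$norm_expr, "excluded_genes"))))
      },
      purity = {
        norm_expr <- need("norm_expr", "normalize")
        cell_meta <- need("cell_meta", "qc")
        chains <- assign_light_chain(norm_expr)
        summ <- light_chain_summary(chains, setNames(cell_meta$sample_id,
                                                    cell_meta$cell_id))
        nbm <- unique(cell_meta$sample_id[cell_meta$stage == "NBM"])
        prior <- estimate_normal_kappa_prior(summ[summ$sample_id %in% nbm, ])
        st$chains <- chains; st$prior <- prior
        bayes <- dplyr::bind_rows(lapply(seq_len(nrow(summ)), function(i) {
          g <- glance(purity_posterior(summ$N[i], summ$n_kappa[i], prior))
          dplyr::mutate(g, sample_id = summ$sample_id[i], .before = 1)
        }))
        st$bayes_purity <- bayes
        write_tsv_plain(bayes, file.path(sdir, "bayes_purity.tsv"))
        log_lines <- c(log_lines, sprintf("purity\tprior_mu\t%.6f\tprior_sigma\t%.6f",
                                          prior$mu, prior$sigma))
      },
      label = {
        norm_expr <- need("norm_expr", "normalize")
        cell_meta <- need("cell_meta", "qc")
        cohort <- need("cohort", "qc")
        lc <- label_cohort(norm_expr, cell_meta, cohort$gene_meta,
                           prior = st$prior,
                           seed = substream_seed(config$seed, "label"),
                           driver_genes = config$driver_genes)
        st$labels <- lc$labels |>
          dplyr::left_join(cell_meta[, c("cell_id", "sample_id")],
                           by = c("cell_id", "sample_id"))
        st$purity_comparison <- lc$purity
        write_tsv_plain(lc$purity, file.path(sdir, "purity_comparison.tsv"))
        write_tsv_plain(lc$labels, file.path(sdir, "cell_labels.tsv"))
        log_lines <- c(log_lines, sprintf("label\tsamples\t%d", nrow(lc$purity)))
      },
      de = {
        norm_expr <- need("norm_expr", "normalize")
        labels <- need("labels", "label")
        cohort <- need("cohort", "qc")
        de_mask <- select_analysis_genes(cohort$gene_meta, "de")
        de_genes <- intersect(cohort$gene_meta$symbol[de_mask], rownames(norm_expr))
        spec <- fold_change_spec(config$fc_offset %||%
                                   default_fc_offset(norm_expr))
        degs <- cohort_within_patient_de(norm_expr[de_genes, , drop = FALSE],
                                         labels, spec)
        st$degs <- degs
        n_pat <- length(unique(degs$comparison[degs$deg]))
        st$cross <- if (nrow(degs) > 0 && n_pat > 0) {
          cross_patient_max_q(degs, n_pat)
        } else {
          tibble(gene = character(), direction = character(), max_q = numeric(),
                 max_abs_log2_fc = numeric(), n_samples_detected = integer())
        }
        write_tsv_plain(degs, file.path(sdir, "within_patient_degs.tsv"))
        write_tsv_plain(st$cross, file.path(sdir, "cross_patient_summary.tsv"))
        log_lines <- c(log_lines, sprintf("de\toffset\t%.6f\tdegs\t%d",
                                          spec$offset, sum(degs$deg)))
      },
      nmf = {
        counts <- need("counts", "qc")
        cohort <- need("cohort", "qc")
        cell_meta <- need("cell_meta", "qc")
        mask <- select_analysis_genes(cohort$gene_meta, "nmf")
        genes <- intersect(cohort$gene_meta$symbol[mask], rownames(counts))
        V <- as.matrix(counts[genes, , drop = FALSE])
        res <- fit_ardnmf_restarts(V, config$nmf)
        fit <- select_cells_catalog(res, V)
        train_cells <- fit$cell_ids
        cat_res <- signature_catalog(
          fit, cell_totals = colSums(V)[train_cells],
          patient_of_cell = cell_meta$sample_id[match(train_cells,
                                                      cell_meta$cell_id)])
        st$nmf <- res; st$catalog <- cat_res
        write_tsv_plain(res$restart_log, file.path(sdir, "restart_log.tsv"))
        write_tsv_plain(cat_res$classes, file.path(sdir, "signature_classes.tsv"))
        write_tsv_plain(cat_res$top_genes, file.path(sdir, "top_genes.tsv"))
        utils::write.table(cat_res$fit$W, file.path(sdir, "W.tsv"),
                           sep = "\t", quote = FALSE)
        utils::write.table(t(cat_res$H_norm), file.path(sdir, "H_norm.tsv"),
                           sep = "\t", quote = FALSE)
        write_tsv_plain(tidy(cat_res$fit, "lambda"), file.path(sdir, "lambda.tsv"))
        log_lines <- c(log_lines, sprintf("nmf\tK_final\t%d", cat_res$fit$K_final))
      },
      sigstats = {
        cat_res <- need("catalog", "nmf")
        labels <- need("labels", "label")
        cell_meta <- need("cell_meta", "qc")
        H_norm <- cat_res$H_norm
        pm <- population_means(H_norm, labels, n_boot = config$n_boot,
                               seed = substream_seed(config$seed, "sigstats"))
        stage_of <- setNames(cell_meta$stage, cell_meta$sample_id)
        act <- pm |>
          dplyr::mutate(stage = unname(stage_of[.data$sample_id]),
                        group = ifelse(.data$stage == "NBM", "NBM",
                                       paste(.data$population, .data$stage)),
                        value = .data$mean)
        gt <- group_activity_test(act[, c("signature", "group", "value")])
        st$population_means <- pm; st$group_tests <- gt
        het <- list()
        for (sid in unique(labels$sample_id)) {
          ab <- labels$cell_id[labels$sample_id == sid & labels$label == "abnormal"]
          ab <- intersect(ab, colnames(H_norm))
          if (length(ab) < 20) next
          cl <- labels$cluster[match(ab, labels$cell_id)]
          h <- intratumor_heterogeneity(H_norm[, ab, drop = FALSE], cl)
          h$sample_id <- sid
          het[[sid]] <- h
        }
        st$heterogeneity <- dplyr::bind_rows(het)
        normal_cells <- intersect(labels$cell_id[labels$label == "normal"],
                                  colnames(H_norm))
        covs <- unique(cell_meta[, c("sample_id", "sex", "age", "batch",
                                     "preservation")])
        st$batch_screen <- batch_association_checks(
          H_norm[, normal_cells, drop = FALSE], cell_meta, covs)
        write_tsv_plain(pm, file.path(sdir, "population_means.tsv"))
        write_tsv_plain(gt$omnibus, file.path(sdir, "group_tests_omnibus.tsv"))
        write_tsv_plain(gt$pairwise, file.path(sdir, "group_tests_pairwise.tsv"))
        if (nrow(st$heterogeneity) > 0) {
          write_tsv_plain(dplyr::select(st$heterogeneity, -"cluster_means"),
                          file.path(sdir, "heterogeneity.tsv"))
        } else {
          write_tsv_plain(tibble(signature = character()),
                          file.path(sdir, "heterogeneity.tsv"))
        }
        write_tsv_plain(st$batch_screen, file.path(sdir, "batch_screen.tsv"))
        log_lines <- c(log_lines, sprintf("sigstats\tsignatures\t%d", nrow(H_norm)))
      },
      report = {
        report <- list(
          config = list(seed = config$seed,
                        n_genes = config$simulation$n_genes,
                        k_true = config$simulation$k_true,
                        nmf_K_init = config$nmf$K_init,
                        nmf_restarts = config$nmf$n_restarts),
          purity = if (exists("purity_comparison", envir = st))
            st$purity_comparison else NULL,
          n_degs = if (exists("degs", envir = st)) sum(st$degs$deg) else NULL,
          deg_summary = if (exists("cross", envir = st)) st$cross else NULL,
          signature_classes = if (exists("catalog", envir = st))
            st$catalog$classes else NULL,
          heterogeneity_flags = if (exists("heterogeneity", envir = st) &&
                                      nrow(st$heterogeneity) > 0)
            dplyr::select(st$heterogeneity, -"cluster_means") else NULL
        )
        jsonlite::write_json(report[!vapply(report, is.null, logical(1))],
                             file.path(sdir, "report.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
      }
    )
  }
  writeLines(log_lines, file.path(out_dir, "pipeline_log.tsv"))
  invisible(as.list(st))
}

# the selected fit was trained on the non-holdout cells; attach their IDs
select_cells_catalog <- function(res, V) {
  fit <- res$selected
  train_cells <- setdiff(colnames(V), res$holdout_cells)
  fit$cell_ids <- train_cells
  colnames(fit$H) <- train_cells
  rownames(fit$W) <- rownames(V)
  fit$gene_ids <- rownames(V)
  fit
}
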