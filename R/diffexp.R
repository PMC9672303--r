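#' Fold-change specification for within-patient differential expression
#'
#' The fold change between two cell groups is the ratio of
#' `exp(mean(log-normalized expression)) - 1 + offset` in each group. The
#' offset regularises genes with near-zero expression; by default it is half
#' the minimum nonzero log-normalized value in the dataset at hand (the
#' reference cohort value is 0.126, available via `offset = 0.126`).
#'
#' @param offset Positive offset, or `NULL` to compute from data.
#' @return A `fold_change_spec` list.
#' @export
fold_change_spec <- function(offset = NULL) {
  if (!is.null(offset)) stopifnot(offset > 0)
  structure(list(offset = offset), class = "fold_change_spec")
}

#' Default fold-change offset: half the minimum nonzero log-normalized value
#'
#' @param norm_expr Matrix of log-normalized expression.
#' @return A positive scalar.
#' @export
default_fc_offset <- function(norm_expr) {
  v <- norm_expr[norm_expr > 0]
  if (length(v) == 0) stop("no nonzero expression values")
  min(v) / 2
}

#' Offset-regularised fold change between two expression groups
#'
#' `FC = (exp(mean_A) - 1 + offset) / (exp(mean_B) - 1 + offset)`, with
#' means taken over log-normalized expression per group. Satisfies
#' `FC(A, B) * FC(B, A) = 1` exactly.
#'
#' @param expr_a,expr_b Numeric vectors (one gene) or matrices (genes x
#'   cells) of log-normalized expression.
#' @param spec A [fold_change_spec()] with a resolved offset.
#' @return Fold change(s), one per gene.
#' @export
group_fold_change <- function(expr_a, expr_b, spec = fold_change_spec(0.126)) {
  if (is.null(spec$offset)) stop("offset must be resolved (see default_fc_offset)")
  if (is.matrix(expr_a)) {
    if (ncol(expr_a) == 0 || ncol(expr_b) == 0) stop("empty group")
    ma <- rowMeans(expr_a); mb <- rowMeans(expr_b)
  } else {
    if (length(expr_a) == 0 || length(expr_b) == 0) stop("empty group")
    ma <- mean(expr_a); mb <- mean(expr_b)
  }
  (expm1(ma) + spec$offset) / (expm1(mb) + spec$offset)
}

# Vectorised two-sided Wilcoxon rank-sum p-values (normal approximation with
# tie and continuity correction), one gene per row.
wilcoxon_rows <- function(expr, in_a) {
  n1 <- sum(in_a); n2 <- sum(!in_a); n <- n1 + n2
  stopifnot(n1 > 0, n2 > 0)
  p <- apply(expr, 1, function(v) {
    r <- rank(v)
    w <- sum(r[in_a]) - n1 * (n1 + 1) / 2       # Mann-Whitney U for group A
    ties <- table(v)
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sig2 <- n1 * n2 / 12 * (n + 1 - tie_corr)
    if (sig2 <= 0) return(1)
    z <- w - n1 * n2 / 2
    z <- sign(z) * max(abs(z) - 0.5, 0)          # continuity correction
    2 * pnorm(-abs(z) / sqrt(sig2))
  })
  pmin(p, 1)
}

#' Within-patient differential expression between abnormal and normal cells
#'
#' For one sample with both populations, tests each gene with a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction),
#' adjusts across genes with Benjamini-Hochberg, and computes the
#' offset-regularised fold change (abnormal over normal). A gene is flagged
#' as a DEG when `q < fdr` and `|log FC| > log(lfc_threshold)`.
#'
#' @param norm_expr Genes x cells log-normalized expression for the sample
#'   (already restricted to analysis genes; sex genes are kept for DE).
#' @param abnormal_cells Character vector of abnormal cell IDs; remaining
#'   columns are treated as normal.
#' @param spec A [fold_change_spec()]; a `NULL` offset is resolved from
#'   `norm_expr`.
#' @param comparison Label stored in the output (e.g. the sample ID).
#' @param fdr,lfc_threshold DEG thresholds (defaults 0.1 and 1.5).
#' @return Tibble with `gene`, `comparison`, `log_fc` (natural log), `p`,
#'   `q`, `deg`.
#' @export
within_patient_de <- function(norm_expr, abnormal_cells,
                              spec = fold_change_spec(),
                              comparison = "abnormal_vs_normal",
                              fdr = 0.1, lfc_threshold = 1.5) {
  in_a <- colnames(norm_expr) %in% abnormal_cells
  if (!any(in_a) || all(in_a)) {
    stop("sample needs both abnormal and normal cells for within-patient DE")
  }
  if (is.null(spec$offset)) spec <- fold_change_spec(default_fc_offset(norm_expr))
  expressed <- rowSums(norm_expr > 0) > 0
  expr <- norm_expr[expressed, , drop = FALSE]
  p <- wilcoxon_rows(expr, in_a)
  q <- p.adjust(p, "BH")
  fc <- group_fold_change(expr[, in_a, drop = FALSE],
                          expr[, !in_a, drop = FALSE], spec)
  tibble(gene = rownames(expr), comparison = comparison,
         log_fc = unname(log(fc)), p = unname(p), q = unname(q),
         deg = unname(q < fdr & abs(log(fc)) > log(lfc_threshold)))
}

#' Run within-patient DE across a labeled cohort
#'
#' Samples without both populations (or with fewer than `min_cells` cells in
#' either) are skipped with a message.
#'
#' @param norm_expr Genes x cells log-normalized expression (DE genes).
#' @param labels Per-cell tibble with `cell_id`, `sample_id`, `label`.
#' @param spec A [fold_change_spec()]; a `NULL` offset is resolved once from
#'   the full matrix so all samples share it.
#' @param min_cells Minimum cells per population (default 10).
#' @inheritParams within_patient_de
#' @return Tibble of per-gene results across samples.
#' @export
cohort_within_patient_de <- function(norm_expr, labels,
                                     spec = fold_change_spec(),
                                     min_cells = 10L, fdr = 0.1,
                                     lfc_threshold = 1.5) {
  if (is.null(spec$offset)) spec <- fold_change_spec(default_fc_offset(norm_expr))
  out <- list()
  for (sid in unique(labels$sample_id)) {
    lab_s <- labels[labels$sample_id == sid, ]
    ab <- lab_s$cell_id[lab_s$label == "abnormal"]
    nm <- lab_s$cell_id[lab_s$label == "normal"]
    if (length(ab) < min_cells || length(nm) < min_cells) {
      message("skipping ", sid, ": needs >= ", min_cells,
              " cells in both populations")
      next
    }
    out[[sid]] <- within_patient_de(
      norm_expr[, c(ab, nm), drop = FALSE], ab, spec,
      comparison = sid, fdr = fdr, lfc_threshold = lfc_threshold)
  }
  dplyr::bind_rows(out)
}

#' Pseudosample count tables and covariates for cross-patient model fitting
#'
#' Splits each sample into abnormal and normal populations, sums counts per
#' pseudosample, filters genes with [cpm_filter_genes()], and emits the
#' design covariates (age with mean imputation of missing NBM ages, sex,
#' batch, fresh/frozen) expected by an external model-fitting step such as
#' limma-voom.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param labels Per-cell tibble with `cell_id`, `sample_id`, `label`.
#' @param sample_meta Tibble with `sample_id`, `stage`, `sex`, `age`,
#'   `batch`, `preservation`.
#' @param ig_genes Logical per gene of `counts`.
#' @return List with `counts` (genes x pseudosamples, filtered), `design`
#'   (tibble), and `kept_genes`.
#' @export
prepare_pseudosample_tables <- function(counts, labels, sample_meta, ig_genes) {
  assert_count_matrix(counts)
  groups <- labels |>
    dplyr::filter(.data$label %in% c("abnormal", "normal")) |>
    dplyr::mutate(pseudosample = paste(.data$sample_id, .data$label, sep = "."))
  ids <- unique(groups$pseudosample)
  sums <- vapply(ids, function(ps) {
    Matrix::rowSums(counts[, groups$cell_id[groups$pseudosample == ps], drop = FALSE])
  }, numeric(nrow(counts)))
  cpm <- vapply(ids, function(ps) {
    pseudobulk(counts, groups$cell_id[groups$pseudosample == ps])
  }, numeric(nrow(counts)))

  frac_expr <- function(pop) {
    cells <- groups$cell_id[groups$label == pop]
    if (length(cells) == 0) return(rep(0, nrow(counts)))
    Matrix::rowSums(counts[, cells, drop = FALSE] > 0) / length(cells)
  }
  keep <- cpm_filter_genes(cpm, frac_expr("abnormal"), frac_expr("normal"), ig_genes)

  design <- tibble(pseudosample = ids) |>
    tidyr::separate_wider_delim("pseudosample", ".", names = c("sample_id", "population"),
                                cols_remove = FALSE) |>
    dplyr::left_join(sample_meta, by = "sample_id")
  if (anyNA(design$age)) {
    nbm_ages <- sample_meta$age[sample_meta$stage == "NBM" &
                                  !is.na(sample_meta$age)]
    design$age[is.na(design$age)] <- mean(nbm_ages)
  }
  list(counts = sums[keep, , drop = FALSE], design = design,
       kept_genes = rownames(counts)[keep])
}

#' Cross-patient roll-up of within-patient DEGs
#'
#' For each gene and direction, reports the maximum BH q across patients
#' multiplied by the number of patients with any DEGs (capped at 1) as a
#' cross-patient multiplicity correction, together with the maximum |log2
#' fold change| and the number of patients in which the gene was flagged.
#'
#' @param degs Tibble from [cohort_within_patient_de()], DEG rows only or
#'   full table (only `deg == TRUE` rows are summarised).
#' @param n_patients_with_degs Number of patients contributing DEGs.
#' @return Tibble with `gene`, `direction`, `max_q`, `max_abs_log2_fc`,
#'   `n_samples_detected`.
#' @export
cross_patient_max_q <- function(degs, n_patients_with_degs) {
  stopifnot(n_patients_with_degs >= 1)
  degs |>
    dplyr::filter(.data$deg) |>
    dplyr::mutate(direction = ifelse(.data$log_fc > 0, "up", "down")) |>
    dplyr::group_by(.data$gene, .data$direction) |>
    dplyr::summarise(
      max_q = min(max(.data$q) * n_patients_with_degs, 1),
      max_abs_log2_fc = max(abs(.data$log_fc)) / log(2),
      n_samples_detected = dplyr::n(),
      .groups = "drop"
    )
}
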