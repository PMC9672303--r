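#' Cell quality-control thresholds
#'
#' Default filters: cells with <15% mitochondrial expression, >200 genes
#' covered, <50,000 total UMIs, and <4000 total genes detected. All
#' inequalities are strict.
#'
#' @param max_mito_fraction Mitochondrial UMI fraction upper bound.
#' @param min_genes Lower bound on genes detected.
#' @param max_umis Upper bound on total UMIs.
#' @param max_genes Upper bound on genes detected.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.15, min_genes = 200L,
                          max_umis = 50000L, max_genes = 4000L) {
  stopifnot(max_mito_fraction > 0, min_genes > 0, max_umis > 0,
            min_genes < max_genes)
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_genes = as.integer(min_genes),
                 max_umis = as.integer(max_umis),
                 max_genes = as.integer(max_genes)),
            class = "qc_thresholds")
}

#' Filter cells on mitochondrial fraction, genes detected, and total UMIs
#'
#' Retains exactly the cells with mito fraction < `max_mito_fraction`, genes
#' detected > `min_genes`, total UMIs < `max_umis`, and genes detected <
#' `max_genes` (all strict), preserving cell order.
#'
#' @param counts Sparse genes x cells count matrix with dimnames.
#' @param thresholds A [qc_thresholds()].
#' @param mito_genes Logical vector per gene, or `NULL` to flag genes whose
#'   symbol starts with `"MT-"`.
#' @return The filtered count matrix.
#' @export
qc_filter_cells <- function(counts, thresholds = qc_thresholds(),
                            mito_genes = NULL) {
  assert_count_matrix(counts)
  if (is.null(mito_genes)) mito_genes <- startsWith(rownames(counts), "MT-")
  stopifnot(length(mito_genes) == nrow(counts))
  tot <- Matrix::colSums(counts)
  mito_frac <- ifelse(tot > 0, Matrix::colSums(counts[mito_genes, , drop = FALSE]) / tot, 0)
  n_genes <- Matrix::colSums(counts > 0)
  keep <- mito_frac < thresholds$max_mito_fraction &
    n_genes > thresholds$min_genes &
    tot < thresholds$max_umis &
    n_genes < thresholds$max_genes
  if (!any(keep)) warning("no cells pass QC; returning empty matrix")
  counts[, keep, drop = FALSE]
}

#' Log-normalize UMI counts
#'
#' Computes `e_gc = log(1e4 * n_gc / N_c + 1)` (natural log), where the cell
#' total `N_c` excludes any gene that accounts for more than
#' `max_gene_share` of UMIs in *any* cell. Excluded genes are still
#' normalized and reported; they are only removed from the denominators.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param scale_factor Scale inside the log (default 1e4).
#' @param max_gene_share Per-cell UMI-share threshold for excluding a gene
#'   from the totals (default 0.2).
#' @return A genes x cells matrix of log-normalized expression, with
#'   attributes `excluded_genes` (character) and `cell_totals` (the adjusted
#'   `N_c`). Cells whose adjusted total is 0 are dropped with a warning.
#' @export
log_normalize <- function(counts, scale_factor = 1e4, max_gene_share = 0.2) {
  assert_count_matrix(counts)
  if (ncol(counts) == 0) stop("empty count matrix")
  tot_all <- Matrix::colSums(counts)
  pos <- tot_all > 0
  share_max <- apply(sweep(as.matrix(counts[, pos, drop = FALSE]), 2,
                           tot_all[pos], "/"), 1, max)
  excluded <- rownames(counts)[share_max > max_gene_share]
  n_c <- Matrix::colSums(counts[!rownames(counts) %in% excluded, , drop = FALSE])
  drop <- n_c == 0
  if (any(drop)) {
    warning(sum(drop), " cell(s) with zero adjusted total dropped")
    counts <- counts[, !drop, drop = FALSE]
    n_c <- n_c[!drop]
  }
  e <- log1p(sweep(as.matrix(counts), 2, scale_factor / n_c, "*"))
  attr(e, "excluded_genes") <- excluded
  attr(e, "cell_totals") <- n_c
  e
}

#' Select analysis genes by removing immunoglobulin-locus and sex genes
#'
#' Immunoglobulin (IGH/IGK/IGL locus) genes are removed for every analysis
#' mode, since they are clonally expressed in abnormal cells and would
#' dominate disease signatures. The sex genes XIST and RPS4Y1 are removed
#' only for dimensionality-reduction uses (PCA/UMAP/clustering/NMF), not for
#' differential expression.
#'
#' @param gene_meta Data frame with a `symbol` column and optionally an
#'   `ig_locus` logical column; when absent, IG membership falls back to the
#'   symbol-prefix rule (IGH/IGK/IGL).
#' @param mode `"nmf"` (also covers PCA/UMAP/clustering) or `"de"`.
#' @param sex_genes Symbols removed in dimension-reduction mode.
#' @return Logical keep-mask over the rows of `gene_meta`.
#' @export
select_analysis_genes <- function(gene_meta, mode = c("nmf", "de"),
                                  sex_genes = c("XIST", "RPS4Y1")) {
  mode <- match.arg(mode)
  sym <- gene_meta$symbol
  ig <- if ("ig_locus" %in% names(gene_meta)) {
    gene_meta$ig_locus
  } else {
    startsWith(sym, "IGH") | startsWith(sym, "IGK") | startsWith(sym, "IGL")
  }
  keep <- !ig
  if (mode == "nmf") keep <- keep & !(sym %in% sex_genes)
  keep
}

#' Pseudobulk a set of cells into one CPM-scaled profile
#'
#' Sums counts across the cells, computes the total ignoring genes that
#' account for more than `max_gene_share` (default 5%) of the summed counts,
#' divides by that total and scales to one million. Dominant genes are still
#' reported; they are only excluded from the denominator.
#'
#' @param counts Sparse genes x cells count matrix.
#' @param cells Cell IDs or logical/integer index; default all cells.
#' @param max_gene_share Denominator-exclusion threshold (default 0.05).
#' @return Named numeric vector of CPM-like values per gene.
#' @export
pseudobulk <- function(counts, cells = NULL, max_gene_share = 0.05) {
  assert_count_matrix(counts)
  if (!is.null(cells)) counts <- counts[, cells, drop = FALSE]
  if (ncol(counts) == 0) stop("empty cell subset")
  sums <- Matrix::rowSums(counts)
  total_all <- sum(sums)
  if (total_all == 0) stop("no counts in subset")
  dominant <- sums / total_all > max_gene_share
  denom <- sum(sums[!dominant])
  if (denom == 0) stop("all counts in dominant genes; cannot scale")
  sums / denom * 1e6
}

#' Filter genes for the pseudosample comparison
#'
#' Keeps genes with CPM >= `min_cpm` in at least one pseudosample, expressed
#' in at least `min_cell_fraction` of abnormal *or* normal cells, and not
#' immunoglobulin genes.
#'
#' @param pseudo_cpm Genes x pseudosamples CPM matrix.
#' @param frac_abnormal,frac_normal Per-gene fraction of abnormal/normal
#'   cells expressing the gene.
#' @param ig_genes Logical per gene.
#' @param min_cpm,min_cell_fraction Thresholds (defaults 5 and 0.05).
#' @return Logical keep-mask per gene.
#' @export
cpm_filter_genes <- function(pseudo_cpm, frac_abnormal, frac_normal,
                             ig_genes, min_cpm = 5, min_cell_fraction = 0.05) {
  stopifnot(nrow(pseudo_cpm) == length(frac_abnormal),
            length(frac_abnormal) == length(frac_normal),
            length(ig_genes) == nrow(pseudo_cpm))
  cpm_ok <- apply(pseudo_cpm, 1, max) >= min_cpm
  frac_ok <- frac_abnormal >= min_cell_fraction | frac_normal >= min_cell_fraction
  cpm_ok & frac_ok & !ig_genes
}
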