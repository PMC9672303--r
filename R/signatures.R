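#' Classify signatures as patient-specific, single-gene, or interpretable
#'
#' A signature is *patient-specific* when its mean (per-cell-normalized)
#' activity in some patient exceeds the mean of the other patients' means by
#' more than 4 standard deviations of those other means. Otherwise it is
#' *single-gene* when, in the sum-1-normalized W column, the top gene weight
#' exceeds the second weight by at least 0.5. Everything else is
#' *interpretable* and is described by its top genes.
#'
#' @param H_norm Signatures x cells activity matrix (cell-total normalized).
#' @param W Genes x signatures weight matrix with columns summing to 1.
#' @param patient_of_cell Patient ID per column of `H_norm`.
#' @param sd_margin Patient-specific margin in SDs (default 4).
#' @param gap_threshold Single-gene weight gap (default 0.5).
#' @return Tibble with `signature`, `class`, and the supporting evidence
#'   (`max_patient`, `patient_z`, `top_gene`, `weight_gap`).
#' @export
classify_signatures <- function(H_norm, W, patient_of_cell, sd_margin = 4,
                                gap_threshold = 0.5) {
  stopifnot(ncol(H_norm) == length(patient_of_cell), nrow(H_norm) == ncol(W))
  patients <- unique(patient_of_cell)
  if (length(patients) < 2) {
    warning("patient-specific rule skipped: need >= 2 patients")
  }
  k_names <- colnames(W) %||% paste0("sig", seq_len(ncol(W)))
  out <- lapply(seq_len(ncol(W)), function(k) {
    pat_means <- tapply(H_norm[k, ], patient_of_cell, mean)
    ps <- FALSE; z <- NA_real_; top_pat <- NA_character_
    if (length(pat_means) >= 3) {
      zs <- vapply(seq_along(pat_means), function(i) {
        others <- pat_means[-i]
        s <- sd(others)
        if (is.na(s) || s == 0) return(NA_real_)
        (pat_means[i] - mean(others)) / s
      }, numeric(1))
      if (any(!is.na(zs))) {
        z <- max(zs, na.rm = TRUE)
        top_pat <- names(pat_means)[which.max(zs)]
        ps <- z > sd_margin
      }
    }
    w <- sort(W[, k], decreasing = TRUE)
    gap <- if (length(w) >= 2) w[1] - w[2] else w[1]
    cls <- if (ps) "patient_specific" else
      if (gap >= gap_threshold) "single_gene" else "interpretable"
    tibble(signature = k_names[k], class = cls, max_patient = top_pat,
           patient_z = z, top_gene = names(w)[1], weight_gap = gap)
  })
  dplyr::bind_rows(out)
}

#' Per-gene signature specificity
#'
#' `s_gk = [H 1]_k w_gk / sum_k' [H 1]_k' w_gk'`: the fraction of a gene's
#' activity-weighted factor weight attributable to signature k. Rows sum to
#' 1 for every gene with any nonzero weight; all-zero genes get 0 across
#' signatures.
#'
#' @param W Genes x signatures matrix (normalized columns).
#' @param H Signatures x cells activity matrix.
#' @return Genes x signatures specificity matrix.
#' @export
specificity_scores <- function(W, H) {
  stopifnot(ncol(W) == nrow(H))
  hr <- rowSums(H)
  num <- sweep(W, 2, hr, "*")
  denom <- rowSums(num)
  s <- num / ifelse(denom > 0, denom, 1)
  s[denom == 0, ] <- 0
  dimnames(s) <- dimnames(W)
  s
}

#' Rank signature genes by weight times specificity
#'
#' @param W Genes x signatures matrix with rownames.
#' @param s Specificity matrix from [specificity_scores()].
#' @param n_top Genes returned per signature (default 10).
#' @return Tibble with `signature`, `rank`, `gene`, `weight`, `specificity`,
#'   `importance`.
#' @export
rank_genes <- function(W, s, n_top = 10L) {
  stopifnot(identical(dim(W), dim(s)))
  k_names <- colnames(W) %||% paste0("sig", seq_len(ncol(W)))
  genes <- rownames(W) %||% as.character(seq_len(nrow(W)))
  imp <- W * s
  dplyr::bind_rows(lapply(seq_len(ncol(W)), function(k) {
    ord <- order(imp[, k], decreasing = TRUE)[seq_len(min(n_top, nrow(W)))]
    tibble(signature = k_names[k], rank = seq_along(ord), gene = genes[ord],
           weight = W[ord, k], specificity = s[ord, k],
           importance = imp[ord, k])
  }))
}

#' Build the full signature catalog from a normalized fit
#'
#' Convenience wrapper: normalizes factors (Eqs. of the W/H weight shift),
#' normalizes activities by cell totals, classifies signatures, and ranks
#' top genes.
#'
#' @param fit An `ardnmf_fit`.
#' @param cell_totals Total counts per cell (aligned to `fit$H` columns).
#' @param patient_of_cell Patient ID per cell.
#' @param n_top Top genes per signature.
#' @return List with `fit` (normalized), `H_norm`, `classes`, `top_genes`,
#'   `specificity`.
#' @export
signature_catalog <- function(fit, cell_totals, patient_of_cell, n_top = 10L) {
  fit <- normalize_factors(fit)
  rownames(fit$W) <- fit$gene_ids %||% rownames(fit$W)
  colnames(fit$W) <- paste0("sig", seq_len(fit$K_final))
  H_norm <- normalize_activities_per_cell(fit$H, cell_totals)
  classes <- classify_signatures(H_norm, fit$W, patient_of_cell)
  s <- specificity_scores(fit$W, fit$H)
  list(fit = fit, H_norm = H_norm, classes = classes,
       top_genes = rank_genes(fit$W, s, n_top), specificity = s)
}
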