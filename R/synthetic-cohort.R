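#' Configuration for the synthetic plasma-cell cohort generator
#'
#' Defaults reproduce the package's reference cohort design: 9 normal bone
#' marrow donors (NBM) and 26 patient samples
#' (6 MGUS, 12 SMM, 8 MM); several hundred cells per sample; per-stage tumor
#' purity drawn from the ranges reported for each stage (NBM 0, MGUS 0-0.81,
#' SMM 0.58-1, MM 0.98-1); normal-cell kappa fractions drawn from a
#' TruncNormal(mu, sigma^2) on \[0, 1\]; the clonal light chain of each patient
#' sample drawn Bernoulli(0.5). Expression is a low-rank mixture: expected
#' counts are Poisson around library-size-scaled `W %*% h` shares, with
#' dedicated high-mean components for the light-chain genes and optional
#' planted fold changes in the abnormal population.
#'
#' @param n_samples_per_stage Named integer vector, samples per disease stage.
#' @param cells_per_sample Length-2 integer range; cells drawn uniformly.
#' @param n_genes Total genes including immunoglobulin/mito/sex genes.
#' @param k_true Number of latent expression signatures.
#' @param kappa_prior_mu,kappa_prior_sigma TruncNormal parameters for the
#'   kappa fraction among normal cells.
#' @param purity_per_sample Optional named numeric vector of purities; when
#'   `NULL`, purities are drawn from `purity_rules` by stage.
#' @param purity_rules Named list of length-2 ranges per stage.
#' @param planted_deg_spec List of specs, each a list with `n_genes`, `fc`
#'   (> 1), `direction` ("up"/"down"), and `population` (default "abnormal").
#' @param library_size Named vector `c(meanlog=, sdlog=)` of the log-normal
#'   per-cell total-UMI distribution.
#' @param clonal_chain Optional named character vector ("kappa"/"lambda") per
#'   sample, overriding the Bernoulli(0.5) draw.
#' @param n_clusters_range Length-2 range of abnormal subclones per sample.
#' @param chain_share Expected UMI share of the clonal light-chain gene.
#' @param abnormal_profile `"distinct"` (default): abnormal cells draw their
#'   signature mix from tumor-dominated subclone profiles; `"shared"`:
#'   abnormal cells use the normal-cell program, so the only expression
#'   differences are the clonal light chain and any planted fold changes
#'   (useful for null calibration of differential expression).
#' @param seed Integer seed; fully determines the cohort.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples_per_stage = c(NBM = 9, MGUS = 6, SMM = 12, MM = 8),
                              cells_per_sample = c(300L, 1500L),
                              n_genes = 500L,
                              k_true = 5L,
                              kappa_prior_mu = 0.6,
                              kappa_prior_sigma = 0.05,
                              purity_per_sample = NULL,
                              purity_rules = list(NBM = c(0, 0), MGUS = c(0, 0.81),
                                                  SMM = c(0.58, 1), MM = c(0.98, 1)),
                              planted_deg_spec = list(),
                              library_size = c(meanlog = log(5000), sdlog = 0.4),
                              clonal_chain = NULL,
                              n_clusters_range = c(1L, 3L),
                              chain_share = 0.05,
                              abnormal_profile = c("distinct", "shared"),
                              seed = 1L) {
  abnormal_profile <- match.arg(abnormal_profile)
  stopifnot(all(n_samples_per_stage >= 0), !is.null(names(n_samples_per_stage)))
  stopifnot(length(cells_per_sample) == 2, all(cells_per_sample >= 1),
            cells_per_sample[1] <= cells_per_sample[2])
  stopifnot(n_genes >= 30, k_true >= 1, k_true <= n_genes)
  stopifnot(kappa_prior_mu > 0, kappa_prior_mu < 1, kappa_prior_sigma > 0)
  if (!is.null(purity_per_sample)) {
    stopifnot(all(purity_per_sample >= 0), all(purity_per_sample <= 1))
  }
  stopifnot(chain_share > 0, chain_share < 0.2)
  for (spec in planted_deg_spec) {
    stopifnot(is.list(spec), spec$n_genes >= 1, spec$fc > 1)
  }
  structure(
    list(n_samples_per_stage = n_samples_per_stage,
         cells_per_sample = as.integer(cells_per_sample),
         n_genes = as.integer(n_genes), k_true = as.integer(k_true),
         kappa_prior_mu = kappa_prior_mu, kappa_prior_sigma = kappa_prior_sigma,
         purity_per_sample = purity_per_sample, purity_rules = purity_rules,
         planted_deg_spec = planted_deg_spec, library_size = library_size,
         clonal_chain = clonal_chain,
         n_clusters_range = as.integer(n_clusters_range),
         chain_share = chain_share, abnormal_profile = abnormal_profile,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# Fixed non-signature genes present in every synthetic cohort.
special_gene_table <- function() {
  tibble(
    symbol = c("IGKC", "IGLC2", "IGHG1", "IGHM", "IGKV1-5", "IGLV2-14",
               paste0("MT-", c("CO1", "ND1", "CYB", "ATP6", "ND4")),
               "XIST", "RPS4Y1"),
    ig_locus = c(rep(TRUE, 6), rep(FALSE, 7)),
    mito = c(rep(FALSE, 6), rep(TRUE, 5), FALSE, FALSE),
    light_chain_role = c("IGKC", "IGLC2", rep("none", 11))
  )
}

#' Generate a synthetic plasma-cell cohort with full ground truth
#'
#' @param config A [simulation_config()].
#' @return A `plasmasig_cohort` list with elements `counts` (sparse genes x
#'   cells UMI matrix), `cell_meta`, `gene_meta` (tibbles), and `truth`
#'   (per-sample purities, clonal chains, drawn kappa_n, planted DEGs,
#'   `true_W`, `true_H`, and the generating cluster of every cell).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(substream_seed(config$seed, "cohort"))
  k <- config$k_true

  special <- special_gene_table()
  n_base <- config$n_genes - nrow(special)
  stopifnot(n_base >= k)
  base_genes <- sprintf("GENE%04d", seq_len(n_base))
  gene_meta <- dplyr::bind_rows(
    special,
    tibble(symbol = base_genes, ig_locus = FALSE, mito = FALSE,
           light_chain_role = "none")
  )

  # latent signatures over the base genes: sparse background + exclusive
  # high-weight marker blocks so signatures have distinct top genes
  true_W <- matrix(rgamma(n_base * k, shape = 0.3, rate = 1), n_base, k,
                   dimnames = list(base_genes, paste0("sig", seq_len(k))))
  n_mark <- max(3L, floor(n_base / (k * 5)))
  for (j in seq_len(k)) {
    idx <- ((j - 1) * n_mark + 1):(j * n_mark)
    true_W[idx, j] <- true_W[idx, j] + rgamma(n_mark, shape = 8, rate = 1)
  }
  true_W <- sweep(true_W, 2, colSums(true_W), "/")

  # cohort-level expression profiles
  p_normal <- rdirichlet1(c(30, rep(0.5, k - 1)))   # normal PC program

  # planted DEGs drawn from mid/high-expression base genes
  # plant in the moderate-expression band: enough counts for power, small
  # enough total share that the compositional renormalisation barely
  # perturbs the remaining genes
  base_mass <- rowSums(true_W)
  ord <- base_genes[order(base_mass, decreasing = TRUE)]
  eligible <- ord[seq(floor(n_base * 0.3), floor(n_base * 0.8))]
  eligible <- setdiff(eligible, base_genes[seq_len(k * n_mark)])  # keep markers clean
  planted <- tibble(gene = character(), fc = numeric(),
                    direction = character(), population = character())
  for (spec in config$planted_deg_spec) {
    pick <- sample(eligible, spec$n_genes)
    eligible <- setdiff(eligible, pick)
    planted <- dplyr::bind_rows(planted, tibble(
      gene = pick, fc = spec$fc,
      direction = spec$direction %||% "up",
      population = spec$population %||% "abnormal"
    ))
  }
  if (nrow(planted) > 0) {
    # flatten planted genes across signatures so their baseline expression
    # is the same in normal and abnormal cells, then solve for the applied
    # multiplier whose post-renormalisation ratio equals the requested fold
    # change (per-cell share renormalisation dilutes all genes by d)
    true_W[planted$gene, ] <- rowMeans(true_W[planted$gene, , drop = FALSE])
    true_W <- sweep(true_W, 2, colSums(true_W), "/")
    r <- rowMeans(true_W[planted$gene, , drop = FALSE])
    fcs <- ifelse(planted$direction == "up", planted$fc, 1 / planted$fc)
    if (sum(r * fcs) >= 0.9) stop("planted DEG mass too large for the requested fold changes")
    d <- (1 - sum(r)) / (1 - sum(r * fcs))
    planted$multiplier <- fcs * d
  }

  stages <- rep(names(config$n_samples_per_stage), config$n_samples_per_stage)
  sample_ids <- unlist(lapply(names(config$n_samples_per_stage), function(s) {
    n <- config$n_samples_per_stage[[s]]
    if (n > 0) paste0(s, "-", seq_len(n)) else character()
  }))

  # per-sample latent draws
  n_s <- length(sample_ids)
  kappa_n <- rtruncnorm01(n_s, config$kappa_prior_mu, config$kappa_prior_sigma)
  if (is.null(config$clonal_chain)) {
    chain <- ifelse(runif(n_s) < 0.5, "kappa", "lambda")
  } else {
    chain <- unname(config$clonal_chain[sample_ids])
  }
  if (is.null(config$purity_per_sample)) {
    purity <- vapply(stages, function(s) {
      r <- config$purity_rules[[s]]
      if (is.null(r)) stop("no purity rule for stage ", s)
      runif(1, r[1], r[2])
    }, numeric(1))
  } else {
    purity <- unname(config$purity_per_sample[sample_ids])
    if (anyNA(purity)) stop("purity_per_sample must name every sample")
  }
  cell_range <- config$cells_per_sample[1]:config$cells_per_sample[2]
  n_cells <- cell_range[sample.int(length(cell_range), n_s, replace = TRUE)]
  sexes <- sample(c("F", "M"), n_s, replace = TRUE)
  ages <- round(runif(n_s, 40, 80))
  batches <- sample(paste0("B", 1:3), n_s, replace = TRUE)
  preservation <- sample(c("fresh", "frozen"), n_s, replace = TRUE)

  # fixed UMI shares of the non-signature genes
  shares <- c(chain = config$chain_share, cross_chain = 5e-4,
              ig_other = 0.004, mito_each = 0.01, sex = 1e-3)
  special_share <- shares[["cross_chain"]] + 2 * shares[["ig_other"]] +
    5 * shares[["mito_each"]] + shares[["sex"]]
  base_share <- 1 - shares[["chain"]] - special_share

  counts_list <- vector("list", n_s)
  meta_list <- vector("list", n_s)
  H_list <- vector("list", n_s)
  sym <- gene_meta$symbol

  for (i in seq_len(n_s)) {
    nc <- n_cells[i]
    n_ab <- round(purity[i] * nc)
    is_ab <- c(rep(TRUE, n_ab), rep(FALSE, nc - n_ab))

    # abnormal subclones: each concentrates on one tumor signature
    n_cl <- if (n_ab > 0 && k > 1) {
      cl_range <- config$n_clusters_range[1]:config$n_clusters_range[2]
      cl_range[sample.int(length(cl_range), 1)]
    } else 0L
    cl_assign <- rep(NA_character_, nc)
    H <- matrix(0, k, nc)
    if (n_ab > 0) {
      # all subclones of one tumor share a moderate core program (they
      # descend from one clone); each additionally concentrates on its own
      # dominant signature
      # each subclone concentrates on its own dominant signature on top of a
      # fixed 30% core program common to the whole tumor (subclones descend
      # from one clone and share its program)
      shared_sig <- if (k >= 3) sample(2:k, 1) else NA_integer_
      cand <- setdiff(seq(2, length.out = max(k - 1, 0)), shared_sig)
      n_prof <- max(n_cl, 1)
      dominants <- if (length(cand) > 0) {
        cand[sample.int(length(cand), n_prof, replace = length(cand) < n_prof)]
      } else rep(NA_integer_, n_prof)
      cl_profiles <- lapply(seq_len(n_prof), function(j) {
        if (config$abnormal_profile == "shared") return(p_normal)
        alpha <- rep(0.25, k)
        if (!is.na(dominants[j])) alpha[dominants[j]] <- 6
        base <- rdirichlet1(alpha)
        if (!is.na(shared_sig)) {
          core <- numeric(k); core[shared_sig] <- 1
          0.3 * core + 0.7 * base
        } else base
      })
      cl_of <- sample(seq_len(max(n_cl, 1)), n_ab,
                      replace = TRUE, prob = rdirichlet1(rep(2, max(n_cl, 1))))
      for (c0 in seq_len(n_ab)) {
        H[, c0] <- rdirichlet1(cl_profiles[[cl_of[c0]]] * 50 + 0.05)
      }
      cl_assign[seq_len(n_ab)] <- paste0("clone", cl_of)
    }
    if (n_ab < nc) {
      for (c0 in (n_ab + 1):nc) H[, c0] <- rdirichlet1(p_normal * 50 + 0.05)
      cl_assign[(n_ab + 1):nc] <- "normal"
    }

    # per-cell light chain
    cell_chain <- character(nc)
    if (n_ab > 0) cell_chain[seq_len(n_ab)] <- chain[i]
    if (n_ab < nc) {
      cell_chain[(n_ab + 1):nc] <-
        ifelse(runif(nc - n_ab) < kappa_n[i], "kappa", "lambda")
    }

    # expected UMI shares per gene x cell
    share <- matrix(0, config$n_genes, nc, dimnames = list(sym, NULL))
    base_p <- true_W %*% H                       # n_base x nc, columns sum to 1
    # planted fold changes on the target population
    if (nrow(planted) > 0) {
      target <- if (n_ab > 0) which(is_ab) else integer()
      if (length(target) > 0 && stages[i] != "NBM") {
        mult <- rep(1, n_base)
        names(mult) <- base_genes
        mult[planted$gene] <- planted$multiplier
        base_p[, target] <- base_p[, target] * mult
        base_p[, target] <- sweep(base_p[, target, drop = FALSE], 2,
                                  colSums(base_p[, target, drop = FALSE]), "/")
      }
    }
    share[base_genes, ] <- base_p * base_share
    is_kappa <- cell_chain == "kappa"
    share["IGKC", ] <- ifelse(is_kappa, shares[["chain"]], shares[["cross_chain"]])
    share["IGLC2", ] <- ifelse(is_kappa, shares[["cross_chain"]], shares[["chain"]])
    share["IGHG1", ] <- shares[["ig_other"]]
    share["IGHM", ] <- shares[["ig_other"]]
    share[paste0("MT-", c("CO1", "ND1", "CYB", "ATP6", "ND4")), ] <- shares[["mito_each"]]
    share["XIST", ] <- if (sexes[i] == "F") shares[["sex"]] else 0
    share["RPS4Y1", ] <- if (sexes[i] == "M") shares[["sex"]] else 0

    lib <- rlnorm(nc, config$library_size[["meanlog"]], config$library_size[["sdlog"]])
    lam <- sweep(share, 2, lib, "*")
    cnt <- matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))
    rownames(cnt) <- sym

    barcodes <- sprintf("%s_cell%04d", sample_ids[i], seq_len(nc))
    colnames(cnt) <- barcodes
    colnames(H) <- barcodes
    counts_list[[i]] <- cnt
    H_list[[i]] <- H
    meta_list[[i]] <- tibble(
      cell_id = barcodes, sample_id = sample_ids[i], stage = stages[i],
      sex = sexes[i], age = ages[i], batch = batches[i],
      preservation = preservation[i], is_abnormal = is_ab,
      true_chain = cell_chain, true_cluster = cl_assign
    )
  }

  counts <- methods::as(do.call(cbind, counts_list), "CsparseMatrix")
  cell_meta <- dplyr::bind_rows(meta_list)
  true_H <- do.call(cbind, H_list)
  rownames(true_H) <- paste0("sig", seq_len(k))

  truth <- list(
    samples = tibble(sample_id = sample_ids, stage = stages,
                     true_purity = round(purity * n_cells) / n_cells,
                     clonal_chain = chain, kappa_n = kappa_n,
                     n_cells = n_cells),
    planted_degs = planted,
    true_W = true_W,
    true_H = true_H,
    cluster_of_cell = setNames(cell_meta$true_cluster, cell_meta$cell_id)
  )

  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta, truth = truth),
            class = "plasmasig_cohort")
}

#' @export
print.plasmasig_cohort <- function(x, ...) {
  cat("<plasmasig_cohort> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " cells, ", nrow(x$truth$samples), " samples\n", sep = "")
  invisible(x)
}

#' Write a cohort to 10x-style MTX + TSV files
#'
#' Writes `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, and `cell_metadata.tsv`
#' under `path`. Round-trips losslessly through [read_cohort()].
#'
#' @param cohort A `plasmasig_cohort` (or any list with `counts`, `gene_meta`,
#'   `cell_meta`).
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  Matrix::writeMM(cohort$counts, file.path(path, "matrix.mtx"))
  write.table(cohort$gene_meta, file.path(path, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(as.character(colnames(cohort$counts) %||% character()),
             file.path(path, "barcodes.tsv"))
  write.table(cohort$cell_meta, file.path(path, "cell_metadata.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path Directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, and optionally `cell_metadata.tsv`.
#' @return A `plasmasig_cohort` (without ground truth).
#' @export
read_cohort <- function(path) {
  counts <- methods::as(Matrix::readMM(file.path(path, "matrix.mtx")), "CsparseMatrix")
  gene_meta <- as_tibble(read.table(file.path(path, "genes.tsv"),
                                    sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE))
  barcodes <- readLines(file.path(path, "barcodes.tsv"))
  rownames(counts) <- gene_meta$symbol
  if (length(barcodes) > 0) colnames(counts) <- barcodes
  meta_path <- file.path(path, "cell_metadata.tsv")
  cell_meta <- if (file.exists(meta_path) && ncol(counts) > 0) {
    as_tibble(read.table(meta_path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE))
  } else NULL
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta, truth = NULL),
            class = "plasmasig_cohort")
}
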