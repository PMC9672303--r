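#' Configuration for automatic-relevance-determination NMF
#'
#' MAP estimation of `V ~ Poisson(WH)` with an exponential (L1) prior on W,
#' a half-normal (L2) prior on H, and per-signature relevance weights
#' `lambda` with an inverse-gamma-style hyperprior controlled by `a` and
#' `b`. Components whose relevance collapses to the floor are pruned after
#' convergence, discovering the rank automatically.
#'
#' @param K_init Initial number of components (default 50).
#' @param max_iter Iteration cap (default 7000).
#' @param tol Convergence tolerance on the relative L2 change of the lambda
#'   vector (default 1e-5).
#' @param a Relevance hyperparameter (default 10; must exceed 2).
#' @param b Optional override; by default computed from `a` and the data as
#'   [compute_b()].
#' @param n_restarts Random restarts for [fit_ardnmf_restarts()] (default
#'   100, the full-scale setting; scale down for desk-size runs).
#' @param holdout_fraction Fraction of cells held out for model selection
#'   (default 0.2).
#' @param seed Integer seed.
#' @return An `ardnmf_config` list.
#' @export
ardnmf_config <- function(K_init = 50L, max_iter = 7000L, tol = 1e-5,
                          a = 10, b = NULL, n_restarts = 100L,
                          holdout_fraction = 0.2, seed = 1L) {
  stopifnot(K_init >= 1, max_iter >= 1, tol > 0, a > 2,
            holdout_fraction >= 0, holdout_fraction < 1, n_restarts >= 1)
  structure(list(K_init = as.integer(K_init), max_iter = as.integer(max_iter),
                 tol = tol, a = a, b = b, n_restarts = as.integer(n_restarts),
                 holdout_fraction = holdout_fraction, seed = as.integer(seed)),
            class = "ardnmf_config")
}

#' Relevance-floor hyperparameter b as a function of a and the data
#'
#' `b = sqrt((a - 1) * (a - 2) * mean(V) / K_init)`, the convention of the
#' GPU signature-analysis implementation this model family comes from.
#'
#' @param a Hyperparameter, `a > 2`.
#' @param V Nonnegative data matrix.
#' @param K_init Initial component count.
#' @return Positive scalar `b`.
#' @export
compute_b <- function(a, V, K_init) {
  if (a <= 2) stop("a must exceed 2")
  mv <- mean(V)
  if (mv <= 0) stop("degenerate all-zero matrix: mean(V) must be positive")
  sqrt((a - 1) * (a - 2) * mv / K_init)
}

# KL divergence D(V || Vhat) with the 0 log 0 = 0 convention
kl_divergence <- function(V, Vhat, eps = 1e-10) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / (Vhat[pos] + eps))) - sum(V) + sum(Vhat)
}

# Eq-style MAP objective: KL + sum_k [ (S_k + b)/lambda_k + M log lambda_k ],
# S_k = sum_g w_gk + sum_c h_kc^2 / 2, M = G + C/2 + a + 1. The additive
# constant cst(a, b) is omitted (invariant under optimisation).
ardnmf_objective <- function(V, W, H, lambda, a, b, eps = 1e-10) {
  Vhat <- W %*% H
  S <- colSums(W) + rowSums(H^2) / 2
  M <- nrow(W) + ncol(H) / 2 + a + 1
  kl_divergence(V, Vhat, eps) + sum((S + b) / lambda + M * log(lambda))
}

#' Fit ARD-NMF by multiplicative MAP updates
#'
#' Block-coordinate MAP estimation: H is updated by the exact minimiser of
#' the KL majoriser under the half-normal prior (a quadratic root), W by the
#' standard multiplicative rule under the exponential prior, and each
#' `lambda_k` by its closed-form stationary point
#' `(sum_g w_gk + sum_c h_kc^2/2 + b) / (G + C/2 + a + 1)`. Every block
#' update decreases the objective, so the recorded trace is non-increasing.
#' Convergence is declared when the relative L2 change of the lambda vector
#' falls below `tol`. After convergence, prior-dominated components -- those
#' whose data mass `S_k = sum_g w_gk + sum_c h_kc^2/2` has fallen below the
#' prior pseudo-mass `b` (equivalently `lambda_k < 2b / (G + C/2 + a + 1)`,
#' twice the relevance floor all dying components approach) -- and
#' components with negligible W column mass are pruned; `K_final` counts
#' the survivors.
#'
#' @param V Nonnegative genes x cells matrix (dense or sparse counts,
#'   typically restricted to analysis genes).
#' @param config An [ardnmf_config()].
#' @param seed Optional seed overriding `config$seed` (used by the restart
#'   driver).
#' @param trace_every Record the objective every this many iterations
#'   (default 1).
#' @return An `ardnmf_fit` with `W`, `H`, `lambda` (pruned to the surviving
#'   components), `K_final`, `objective_trace`, `converged`, `iterations`,
#'   and the hyperparameters used.
#' @export
fit_ardnmf <- function(V, config = ardnmf_config(), seed = NULL,
                       trace_every = 1L) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be nonnegative")
  G <- nrow(V); C <- ncol(V); K <- config$K_init
  b <- config$b %||% compute_b(config$a, V, K)
  M <- G + C / 2 + config$a + 1
  eps <- 1e-10
  set.seed(seed %||% config$seed)

  scale0 <- sqrt(mean(V) / K)
  W <- matrix(runif(G * K, 0.5, 1.5) * scale0, G, K)
  H <- matrix(runif(K * C, 0.5, 1.5) * scale0, K, C)
  lambda <- (colSums(W) + rowSums(H^2) / 2 + b) / M

  res <- .ardnmf_iterate(V, W, H, lambda, b, config$a,
                         config$max_iter, config$tol, as.integer(trace_every),
                         TRUE, TRUE)
  W <- res$W; H <- res$H; lambda <- drop(res$lambda)
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)

  S <- colSums(W) + rowSums(H^2) / 2
  col_mass <- colSums(W)
  dead <- S < b | col_mass < 1e-8 * sum(col_mass)
  active <- which(!dead)
  if (length(active) == 0) active <- which.max(lambda)

  structure(list(
    W = W[, active, drop = FALSE], H = H[active, , drop = FALSE],
    lambda = lambda[active], K_final = length(active),
    objective_trace = drop(res$objective_trace), converged = res$converged,
    iterations = res$iterations,
    a = config$a, b = b, G = G, C = C,
    gene_ids = rownames(V), cell_ids = colnames(V)
  ), class = "ardnmf_fit")
}

#' @export
print.ardnmf_fit <- function(x, ...) {
  cat(sprintf("<ardnmf_fit> K_final=%d (%d genes x %d cells), %d iterations%s\n",
              x$K_final, x$G, x$C, x$iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.ardnmf_fit <- function(x, ...) {
  tibble(K_final = x$K_final, iterations = x$iterations,
         converged = x$converged,
         objective = x$objective_trace[length(x$objective_trace)],
         heldout_divergence = x$heldout_divergence %||% NA_real_)
}

#' @exportS3Method generics::tidy
tidy.ardnmf_fit <- function(x, matrix = c("W", "H", "lambda"), ...) {
  matrix <- match.arg(matrix)
  k_names <- paste0("sig", seq_len(x$K_final))
  if (matrix == "lambda") {
    return(tibble(signature = k_names, lambda = x$lambda))
  }
  m <- x[[matrix]]
  if (matrix == "W") {
    dimnames(m) <- list(x$gene_ids %||% seq_len(nrow(m)), k_names)
    as_tibble(m, rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "signature", values_to = "weight")
  } else {
    dimnames(m) <- list(k_names, x$cell_ids %||% seq_len(ncol(m)))
    as_tibble(Matrix::t(m), rownames = "cell_id") |>
      tidyr::pivot_longer(-"cell_id", names_to = "signature", values_to = "activity")
  }
}

#' Project held-out cells onto a fitted W
#'
#' Runs the H-block multiplicative updates with W fixed (same half-normal
#' prior and relevance weights as the fit) and returns the plain KL (beta =
#' 1) divergence of the held-out data from its reconstruction.
#'
#' @param fit An `ardnmf_fit` (or a nonnegative W matrix).
#' @param V_heldout Genes x held-out-cells matrix aligned to W's rows.
#' @param lambda Relevance weights; taken from `fit` when available.
#' @param max_iter,tol Inner-loop controls (defaults 2000 and 1e-6).
#' @param seed Seed for the H initialisation.
#' @return List with `H` and `divergence`.
#' @export
project_holdout <- function(fit, V_heldout, lambda = NULL, max_iter = 2000L,
                            tol = 1e-6, seed = 1L) {
  W <- if (inherits(fit, "ardnmf_fit")) fit$W else fit
  if (is.null(lambda)) {
    # without a fitted lambda the projection is effectively unpenalised
    lambda <- if (inherits(fit, "ardnmf_fit")) fit$lambda else
      rep(1e8, ncol(W))
  }
  V_heldout <- as.matrix(V_heldout)
  if (nrow(V_heldout) != nrow(W)) stop("gene dimensions of W and V_heldout differ")
  K <- ncol(W); C <- ncol(V_heldout)
  set.seed(seed)
  H <- matrix(runif(K * C, 0.5, 1.5) * sqrt(mean(V_heldout) / max(K, 1)), K, C)
  a_eff <- if (inherits(fit, "ardnmf_fit")) fit$a else 10
  res <- .ardnmf_iterate(V_heldout, W, H, lambda, 0, a_eff,
                         as.integer(max_iter), tol, 0L, FALSE, FALSE)
  list(H = res$H, divergence = kl_divergence(V_heldout, W %*% res$H))
}

#' Run restarts with a shared holdout split and select the modal-K solution
#'
#' Cells are split once into training and validation sets; each restart fits
#' the training cells from a different seed and is scored by the KL
#' divergence of the projected validation cells. [select_solution()] then
#' restricts to restarts whose `K_final` equals the modal `K_final` and
#' returns the one with the lowest validation divergence.
#'
#' @param V Genes x cells matrix.
#' @param config An [ardnmf_config()].
#' @return List with `fits` (all restarts), `selected` (an `ardnmf_fit`
#'   carrying `heldout_divergence`), `holdout_cells`, and `restart_log`
#'   tibble (seed, K_final, heldout divergence per restart).
#' @export
fit_ardnmf_restarts <- function(V, config = ardnmf_config()) {
  V <- as.matrix(V)
  C <- ncol(V)
  set.seed(substream_seed(config$seed, "holdout"))
  n_hold <- floor(config$holdout_fraction * C)
  hold <- sort(sample(C, n_hold))
  train <- if (n_hold > 0) V[, -hold, drop = FALSE] else V
  valid <- V[, hold, drop = FALSE]
  b <- config$b %||% compute_b(config$a, V, config$K_init)
  cfg <- config; cfg$b <- b

  fits <- vector("list", config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    s <- substream_seed(config$seed, paste0("restart", r))
    fit <- fit_ardnmf(train, cfg, seed = s, trace_every = 50L)
    fit$heldout_divergence <- if (n_hold > 0) {
      project_holdout(fit, valid, seed = s)$divergence
    } else {
      kl_divergence(train, fit$W %*% fit$H)
    }
    fit$seed <- s
    fits[[r]] <- fit
  }
  log <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble(seed = f$seed, K_final = f$K_final,
           heldout_divergence = f$heldout_divergence,
           converged = f$converged, iterations = f$iterations)
  }))
  list(fits = fits, selected = select_solution(fits),
       holdout_cells = if (n_hold > 0) colnames(V)[hold] else character(),
       restart_log = log)
}

#' Select the best restart: modal K, then lowest validation divergence
#'
#' Ties in the modal `K_final` break toward the smaller K.
#'
#' @param fits List of `ardnmf_fit` objects with `heldout_divergence`.
#' @return The selected `ardnmf_fit`.
#' @export
select_solution <- function(fits) {
  stopifnot(length(fits) >= 1)
  ks <- vapply(fits, function(f) as.integer(f$K_final), integer(1))
  tab <- table(ks)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  cand <- fits[ks == modal]
  divs <- vapply(cand, function(f) f$heldout_divergence %||% Inf, numeric(1))
  cand[[which.min(divs)]]
}

#' Normalize W columns to sum 1, shifting the weight into H
#'
#' `w_gk <- w_gk / sum_g w_gk` and `h_kc <- sum_g(w_gk) * h_kc`, leaving the
#' reconstruction `W %*% H` unchanged. Zero columns are pruned with a
#' warning.
#'
#' @param fit An `ardnmf_fit` (modified copy returned).
#' @return The fit with normalized factors.
#' @export
normalize_factors <- function(fit) {
  cs <- colSums(fit$W)
  if (any(cs == 0)) {
    warning(sum(cs == 0), " zero-weight signature(s) pruned")
    keep <- cs > 0
    fit$W <- fit$W[, keep, drop = FALSE]
    fit$H <- fit$H[keep, , drop = FALSE]
    fit$lambda <- fit$lambda[keep]
    fit$K_final <- sum(keep)
    cs <- cs[keep]
  }
  fit$W <- sweep(fit$W, 2, cs, "/")
  fit$H <- sweep(fit$H, 1, cs, "*")
  fit
}

#' Normalize per-cell signature activities by cell totals
#'
#' Divides each column of H by that cell's total counts, making activities
#' comparable across sequencing depths. Cells with zero totals are dropped.
#'
#' @param H Signatures x cells activity matrix.
#' @param cell_totals Named (or aligned) totals per cell.
#' @return The normalized activity matrix.
#' @export
normalize_activities_per_cell <- function(H, cell_totals) {
  stopifnot(ncol(H) == length(cell_totals))
  zero <- cell_totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero totals excluded")
    H <- H[, !zero, drop = FALSE]
    cell_totals <- cell_totals[!zero]
  }
  sweep(H, 2, cell_totals, "/")
}
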