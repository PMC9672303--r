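#' Assign each cell a light chain from IGKC vs IGLC2 expression
#'
#' A cell is kappa if its IGKC expression exceeds IGLC2, lambda if IGLC2
#' exceeds IGKC; ties (including 0-0) are unassigned and excluded from the
#' light-chain counts, since the purity model assumes every counted cell is
#' informative.
#'
#' @param norm_expr Genes x cells matrix of (log-)normalized expression.
#' @param kappa_gene,lambda_gene Gene symbols (defaults IGKC, IGLC2).
#' @return Tibble with `cell_id` and `chain` in `{"kappa","lambda","unassigned"}`.
#' @export
assign_light_chain <- function(norm_expr, kappa_gene = "IGKC",
                               lambda_gene = "IGLC2") {
  if (!kappa_gene %in% rownames(norm_expr) || !lambda_gene %in% rownames(norm_expr)) {
    stop("light-chain genes ", kappa_gene, "/", lambda_gene, " not found")
  }
  kap <- norm_expr[kappa_gene, ]
  lam <- norm_expr[lambda_gene, ]
  tibble(
    cell_id = colnames(norm_expr),
    chain = dplyr::case_when(kap > lam ~ "kappa",
                             kap < lam ~ "lambda",
                             TRUE ~ "unassigned")
  )
}

#' Summarise light-chain assignments per sample
#'
#' @param chains Tibble from [assign_light_chain()].
#' @param sample_of_cell Named character vector mapping cell_id to sample.
#' @return Tibble with `sample_id`, `N` (assigned cells), `n_kappa`.
#' @export
light_chain_summary <- function(chains, sample_of_cell) {
  chains |>
    dplyr::filter(.data$chain != "unassigned") |>
    dplyr::mutate(sample_id = unname(sample_of_cell[.data$cell_id])) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(N = dplyr::n(),
                     n_kappa = sum(.data$chain == "kappa"),
                     .groups = "drop")
}

#' Estimate the normal-cell kappa-fraction prior from NBM samples
#'
#' `mu` is the mean of the per-sample kappa fractions; `sigma` the sample SD
#' (n-1 denominator), floored at `sigma_min` so the likelihood cannot become
#' singular when the donor samples happen to agree closely.
#'
#' @param summaries Tibble with columns `N` and `n_kappa` (one row per
#'   normal sample), as from [light_chain_summary()].
#' @param sigma_min Floor on sigma (default 0.01).
#' @return A `kappa_prior` list with `mu` and `sigma`.
#' @export
estimate_normal_kappa_prior <- function(summaries, sigma_min = 0.01) {
  if (nrow(summaries) < 2) {
    stop("need >= 2 normal samples to estimate the kappa prior; ",
         "supply an explicit kappa_prior(mu, sigma) instead")
  }
  frac <- summaries$n_kappa / summaries$N
  kappa_prior(mean(frac), max(sd(frac), sigma_min))
}

#' Construct a normal-cell kappa prior
#'
#' @param mu Mean kappa fraction in (0, 1).
#' @param sigma Positive SD.
#' @return A `kappa_prior` list.
#' @export
kappa_prior <- function(mu, sigma) {
  stopifnot(mu > 0, mu < 1, sigma > 0)
  structure(list(mu = mu, sigma = sigma), class = "kappa_prior")
}

#' Posterior distribution of tumor purity from light-chain counts
#'
#' Implements the hierarchical model: kappa_n ~ TruncNormal(mu, sigma^2, 0, 1)
#' for the kappa fraction among normal cells, kappa_t ~ Bernoulli(0.5) for
#' the clonal chain (0 or 1), rho ~ Beta(1, 1) for purity, and
#' n_kappa ~ Binomial(N, p) with p = rho * kappa_t + (1 - rho) * kappa_n.
#' The posterior over rho is evaluated on 100 equally spaced grid points in
#' \[0, 1\], marginalising kappa_t by summation and kappa_n by trapezoid
#' quadrature, then normalised across the grid. The mode is reported as the
#' purity estimate; the 95% CI comes from the 2.5% and 97.5% points of the
#' cumulative distribution (linearly interpolated, clamped to contain the
#' mode).
#'
#' @param N Total light-chain-assigned cells in the sample.
#' @param n_kappa Number of kappa cells, `0 <= n_kappa <= N`.
#' @param prior A [kappa_prior()].
#' @param grid_size Number of rho grid points (default 100).
#' @param integration_points Number of kappa_n quadrature points (default 1001).
#' @return A `purity_posterior` object with `grid`, `probs`, `mode`, `ci95`.
#' @export
purity_posterior <- function(N, n_kappa, prior, grid_size = 100L,
                             integration_points = 1001L) {
  stopifnot(N >= 1, n_kappa >= 0)
  if (n_kappa > N) stop("n_kappa cannot exceed N")
  stopifnot(inherits(prior, "kappa_prior"))
  rho <- seq(0, 1, length.out = grid_size)
  kn <- seq(0, 1, length.out = integration_points)
  h <- kn[2] - kn[1]
  dens <- dtruncnorm01(kn, prior$mu, prior$sigma)
  unnorm <- vapply(rho, function(r) {
    p0 <- pmin(pmax((1 - r) * kn, 0), 1)       # kappa_t = 0
    p1 <- pmin(pmax(r + (1 - r) * kn, 0), 1)   # kappa_t = 1
    i0 <- trapz(dbinom(n_kappa, N, p0) * dens, h)
    i1 <- trapz(dbinom(n_kappa, N, p1) * dens, h)
    0.5 * (i0 + i1)                             # times the flat Beta(1,1) prior
  }, numeric(1))
  probs <- unnorm / sum(unnorm)
  mode <- rho[which.max(probs)]
  ci <- cumulative_ci(rho, probs, c(0.025, 0.975))
  structure(list(grid = rho, probs = probs, mode = mode,
                 ci95 = c(lo = min(ci[1], mode), hi = max(ci[2], mode)),
                 N = N, n_kappa = n_kappa, prior = prior),
            class = "purity_posterior")
}

# interpolated quantiles of a discrete distribution on an ordered grid
cumulative_ci <- function(grid, probs, q) {
  cum <- cumsum(probs)
  vapply(q, function(qq) {
    i <- which(cum >= qq)[1]
    if (i == 1) return(grid[1])
    f0 <- cum[i - 1]
    grid[i - 1] + (qq - f0) / (cum[i] - f0) * (grid[i] - grid[i - 1])
  }, numeric(1))
}

#' @export
print.purity_posterior <- function(x, ...) {
  cat(sprintf("<purity_posterior> N=%d, n_kappa=%d: mode=%.3f, 95%% CI [%.3f, %.3f]\n",
              x$N, x$n_kappa, x$mode, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.purity_posterior <- function(x, ...) {
  tibble(rho = x$grid, posterior = x$probs)
}

#' @exportS3Method generics::glance
glance.purity_posterior <- function(x, ...) {
  tibble(mode = x$mode, ci_lo = unname(x$ci95[1]), ci_hi = unname(x$ci95[2]),
         N = x$N, n_kappa = x$n_kappa)
}

#' @exportS3Method ggplot2::autoplot
autoplot.purity_posterior <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$rho, y = .data$posterior)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$mode, linetype = "dashed") +
    ggplot2::labs(x = expression(rho~(tumor~purity)), y = "posterior mass") +
    ggplot2::theme_minimal()
}

#' Conjugate Beta interval for a label-derived purity estimate
#'
#' With n of N sequenced cells labeled abnormal and a uniform prior on the
#' abnormal fraction, the posterior is Beta(n + 1, N - n + 1); the 95% CI is
#' its 2.5% and 97.5% quantiles.
#'
#' @param n_abnormal Cells labeled abnormal.
#' @param N Total labeled cells (>= 1).
#' @return Tibble with `estimate`, `ci_lo`, `ci_hi`.
#' @export
binomial_purity_ci <- function(n_abnormal, N) {
  if (any(N < 1)) stop("N must be >= 1")
  stopifnot(all(n_abnormal >= 0), all(n_abnormal <= N))
  tibble(
    estimate = n_abnormal / N,
    ci_lo = qbeta(0.025, n_abnormal + 1, N - n_abnormal + 1),
    ci_hi = qbeta(0.975, n_abnormal + 1, N - n_abnormal + 1)
  )
}
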