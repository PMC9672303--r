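#' Derive a reproducible sub-seed from a base seed and a stream name
#'
#' All stochastic stages draw their seed from one global seed through this
#' helper, so each stage is reproducible independently of execution order.
#'
#' @param seed Integer base seed.
#' @param name Character stream name.
#' @return An integer seed below 2^31.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(name))
  codes <- utf8ToInt(name)
  h <- as.double(seed) %% 2147483629
  for (ch in codes) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

#' Sample from a normal distribution truncated to [0, 1]
#'
#' Inverse-CDF sampling: exact, with no rejection loop.
#'
#' @param n Number of draws.
#' @param mu,sigma Mean and SD of the untruncated normal.
#' @return Numeric vector of draws in \[0, 1\].
#' @export
rtruncnorm01 <- function(n, mu, sigma) {
  stopifnot(sigma > 0)
  lo <- pnorm(0, mu, sigma)
  hi <- pnorm(1, mu, sigma)
  qnorm(runif(n, lo, hi), mu, sigma)
}

#' Density of a normal distribution truncated to [0, 1]
#'
#' @param x Evaluation points.
#' @param mu,sigma Mean and SD of the untruncated normal.
#' @return Density values (0 outside \[0, 1\]).
#' @export
dtruncnorm01 <- function(x, mu, sigma) {
  z <- pnorm(1, mu, sigma) - pnorm(0, mu, sigma)
  out <- dnorm(x, mu, sigma) / z
  out[x < 0 | x > 1] <- 0
  out
}

# trapezoid rule on a uniform grid
trapz <- function(y, h) {
  n <- length(y)
  h * (sum(y) - (y[1] + y[n]) / 2)
}

# Dirichlet draw via gamma normalisation
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

assert_count_matrix <- function(counts) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate gene IDs in count matrix")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell IDs in count matrix")
  invisible(counts)
}
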