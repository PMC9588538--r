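# Small numerical helpers shared across the sampler modules.

#' Draw from an inverse-gamma distribution
#'
#' Parameterised so that `x ~ IG(shape, scale)` means `1/x ~ Gamma(shape,
#' rate = scale)`, the convention used for all variance-component priors in
#' this package.
#'
#' @param n number of draws.
#' @param shape,scale positive parameters.
#' @return numeric vector of positive draws.
#' @export
rinvgamma <- function(n, shape, scale) {
  stopifnot(shape > 0, scale > 0)
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

#' Inverse-gamma cumulative distribution function
#'
#' @param q quantiles.
#' @inheritParams rinvgamma
#' @return `P(X <= q)` for `X ~ IG(shape, scale)`.
#' @export
pinvgamma <- function(q, shape, scale) {
  stats::pgamma(1 / q, shape = shape, rate = scale, lower.tail = FALSE)
}

#' Sample from a lower-truncated normal distribution
#'
#' Inverse-CDF sampling in the body of the distribution; for truncation
#' points more than 5 standard deviations above the mean the exponential
#' rejection sampler of Robert (1995) is used for numerical stability.
#'
#' @param n number of draws (recycled against `mean`, `sd`, `lower`).
#' @param mean,sd location and scale of the untruncated normal.
#' @param lower lower truncation bound; draws satisfy `x > lower`.
#' @return numeric vector of length `n`.
#' @export
rtruncnorm_lower <- function(n, mean = 0, sd = 1, lower = -Inf) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  lower <- rep_len(lower, n)
  a <- (lower - mean) / sd
  out <- numeric(n)
  body <- which(a < 5)
  if (length(body)) {
    pa <- stats::pnorm(a[body])
    u <- pa + stats::runif(length(body)) * (1 - pa)
    # guard against u == 1 in double precision
    u <- pmin(u, 1 - 1e-16)
    out[body] <- mean[body] + sd[body] * stats::qnorm(u)
  }
  tail_idx <- which(a >= 5)
  for (i in tail_idx) {
    ai <- a[i]
    lam <- (ai + sqrt(ai^2 + 4)) / 2
    repeat {
      x <- ai + stats::rexp(1, rate = lam)
      if (stats::runif(1) <= exp(-(x - lam)^2 / 2)) break
    }
    out[i] <- mean[i] + sd[i] * x
  }
  # numerical floor: enforce the support constraint exactly
  pmax(out, lower + 0 * out + .Machine$double.eps * pmax(1, abs(lower)))
}

#' Effective sample size of an MCMC trace
#'
#' Initial-positive-sequence estimator based on the sample autocorrelation
#' function.
#'
#' @param x numeric vector of draws.
#' @return estimated effective sample size (capped at `length(x)`).
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4 || stats::sd(x) == 0) return(NA_real_)
  lag_max <- min(n - 2, max(10, floor(10 * log10(n))) * 3)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)[-1]
  s <- 0
  for (k in seq_along(rho)) {
    if (rho[k] < 0) break
    s <- s + rho[k]
  }
  min(n, n / (1 + 2 * s))
}

#' Split-chain potential scale reduction factor
#'
#' The split-\eqn{\widehat{R}} of Gelman et al.: the chain is split in half
#' and between/within variances compared.
#'
#' @param x numeric vector of draws from a single chain.
#' @return the split-chain \eqn{\widehat{R}} statistic.
#' @export
rhat_split <- function(x) {
  n <- length(x)
  if (n < 8) return(NA_real_)
  m <- floor(n / 2)
  halves <- list(x[seq_len(m)], x[(n - m + 1):n])
  w <- mean(vapply(halves, stats::var, 0))
  if (w == 0) return(1)
  b <- m * stats::var(vapply(halves, mean, 0))
  sqrt(((m - 1) / m * w + b / m) / w)
}

# deterministic child seed for nested stochastic loops (kept below 2^31)
child_seed <- function(seed, i, j = 0L) {
  as.integer((as.double(seed) + 1000003 * i + 997 * j) %% 2147483647)
}
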