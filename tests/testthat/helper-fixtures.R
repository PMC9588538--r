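# Small in-code fixtures shared across the test files.

# lognormal clustered data with known structure:
# log T = mu0 + x %*% beta + arm_eff[a] + b_k + sigma * eps
make_toy_data <- function(n = 60, K = 3, J = 3, p = 2, mu0 = 3,
                          beta = rep(0.5, p), arm_eff = c(0, 0.4, -0.3),
                          tau = 0.5, sigma = 0.4, cens_rate = 0,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cluster <- rep_len(seq_len(K), n)
  a <- factor(rep_len(seq_len(J), n))
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  b <- rnorm(K, 0, tau)
  logt <- mu0 + as.numeric(x %*% beta) + arm_eff[as.integer(a)] +
    b[cluster] + sigma * rnorm(n)
  t <- exp(logt)
  if (cens_rate > 0) {
    cns <- rexp(n, cens_rate / mean(t))
    y <- pmin(t, cns)
    delta <- as.integer(t < cns)
  } else {
    y <- t
    delta <- rep(1L, n)
  }
  list(data = clustered_survival_data(y, delta, a, cluster, x),
       b = b, logt = logt, beta = beta, arm_eff = arm_eff,
       mu0 = mu0, tau = tau, sigma = sigma)
}

# brute-force Kaplan-Meier product over risk sets
km_brute <- function(y, delta) {
  times <- sort(unique(y))
  s <- 1
  out <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    d <- sum(y == t & delta == 1)
    r <- sum(y >= t)
    s <- s * (1 - d / r)
    out[i] <- s
  }
  list(times = times, surv = out)
}

# recursive-descent routing oracle over the compact tree representation
predict_trees_oracle <- function(trees, X) {
  route_one <- function(M, xrow) {
    id <- 1
    while (M[id, "var"] > 0) {
      id <- if (xrow[M[id, "var"]] <= M[id, "cut"]) M[id, "left"]
            else M[id, "right"]
    }
    M[id, "mu"]
  }
  rowSums(vapply(trees, function(M)
    apply(X, 1, function(xr) route_one(M, xr)), numeric(nrow(X))))
}
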