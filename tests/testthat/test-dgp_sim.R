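test_that("covariate generator matches its marginal distributions", {
  set.seed(51)
  X <- simulate_covariates(1e5)
  expect_true(all(abs(colMeans(X[paste0("x", 1:5)])) < 0.015))
  expect_equal(as.numeric(prop.table(table(X$x6))), c(0.3, 0.3, 0.4),
               tolerance = 0.04)
  expect_equal(as.numeric(prop.table(table(X$x7))), c(0.3, 0.3, 0.4),
               tolerance = 0.04)
  expect_equal(colMeans(X[paste0("x", 8:10)]),
               c(x8 = 0.6, x9 = 0.4, x10 = 0.5), tolerance = 0.02)
})

test_that("treatment assignment follows the softmax model", {
  cfg <- dgp_config(K = 4, n_k = 50)
  # all coefficients zero, zero intercepts: each arm probability 1/3
  cfg0 <- cfg
  cfg0$xi0 <- c(0, 0)
  cfg0$xi1L <- cfg0$xi2L <- rep(0, 12)
  cfg0$xi1NL <- cfg0$xi2NL <- rep(0, 4)
  cfg0$tau_sd <- 0
  set.seed(52)
  X <- simulate_covariates(3000)
  tr <- simulate_treatment(X, nonlinear_basis(X), rep(1:4, each = 750),
                           cfg0)
  expect_true(all(abs(tr$probs - 1 / 3) < 1e-12))
  # hand-coded softmax oracle on nonzero coefficients
  cfg$xi0 <- c(0.5, -0.2)
  set.seed(53)
  Xs <- simulate_covariates(50)
  G <- nonlinear_basis(Xs)
  tau <- c(0.3, -0.4)
  tr2 <- simulate_treatment(Xs, G, rep(1:2, each = 25), cfg, tau = tau)
  D <- ribart:::covariate_design(Xs)
  for (i in c(1, 17, 50)) {
    e1 <- exp(cfg$xi0[1] + sum(D[i, ] * cfg$xi1L) +
                sum(G[i, ] * cfg$xi1NL) + tau[rep(1:2, each = 25)[i]])
    e2 <- exp(cfg$xi0[2] + sum(D[i, ] * cfg$xi2L) +
                sum(G[i, ] * cfg$xi2NL) + tau[rep(1:2, each = 25)[i]])
    expect_equal(unname(tr2$probs[i, ]), c(e1, e2, 1) / (e1 + e2 + 1),
                 tolerance = 1e-12)
  }
})

test_that("intercept calibration hits the target allocation", {
  cfg <- dgp_config()
  # symmetric null case: intercepts stay near zero
  cfg0 <- cfg
  cfg0$xi1L <- cfg0$xi2L <- rep(0, 12)
  cfg0$xi1NL <- cfg0$xi2NL <- rep(0, 4)
  cfg0$tau_sd <- 0
  cfg0$target_alloc <- rep(1, 3) / 3
  set.seed(54)
  xi0 <- calibrate_intercepts(cfg0)
  expect_lt(max(abs(xi0)), 0.05)
  # monotonicity: raising the first intercept raises arm 1's share
  cfg1 <- cfg0
  cfg1$xi0 <- xi0 + c(1, 0)
  X <- simulate_covariates(5000)
  tr <- simulate_treatment(X, nonlinear_basis(X), rep(1:2, 2500), cfg1)
  expect_gt(mean(tr$probs[, 1]), 1 / 3)

  # the reference 6:3:1 design on a fresh seed
  set.seed(55)
  cfg$xi0 <- calibrate_intercepts(cfg, n_mc = 5e4, tol = 0.003)
  set.seed(56)
  Xf <- simulate_covariates(1e5)
  cl <- rep(1:1000, each = 100)
  trf <- simulate_treatment(Xf, nonlinear_basis(Xf), cl, cfg)
  expect_lt(max(abs(as.numeric(prop.table(table(trf$a))) -
                    c(0.6, 0.3, 0.1))), 0.011)
})

test_that("counterfactual times follow the Weibull law", {
  set.seed(57)
  # eta = 2, all coefficients zero, lambda = 1: T = sqrt(-log U)
  cfg <- dgp_config(ph = TRUE, lambda = c(1, 1, 1),
                    beta0 = c(0, 0, 0),
                    betaL = replicate(3, rep(0, 12), simplify = FALSE),
                    betaNL = replicate(3, rep(0, 4), simplify = FALSE),
                    b_sd = 0)
  X <- simulate_covariates(1e5)
  tt <- simulate_counterfactual_times(X, nonlinear_basis(X),
                                      rep(0, 1e5), cfg)
  expect_equal(median(tt[, 1]), sqrt(log(2)), tolerance = 0.01)
  # distributional check against the closed-form survival
  ks <- stats::ks.test(tt[, 2], function(q) 1 - exp(-q^2))
  expect_gt(ks$p.value, 0.01)
  # PH property: log cumulative hazards for two arms differ by a constant
  cfg2 <- cfg
  cfg2$lambda <- c(3000, 1200, 2000)
  tt2 <- simulate_counterfactual_times(X, nonlinear_basis(X),
                                       rep(0, 1e5), cfg2)
  qs <- seq(0.1, 0.9, 0.1)
  ch1 <- -log(1 - qs)  # cumulative hazard at quantiles of arm 1
  t1 <- quantile(tt2[, 1], qs)
  # at arm 1's quantile times, arm 2's cumulative hazard ratio is constant
  ch2 <- (cfg2$lambda[2] / cfg2$lambda[1]) * ch1
  emp_ch2 <- -log(vapply(t1, function(t) mean(tt2[, 2] > t), 0))
  expect_equal(unname(emp_ch2 / ch1), rep(1200 / 3000, 9), tolerance = 0.05)

  # consistency: the observed time equals the selected arm's counterfactual
  sim <- simulate_trial(dgp_config(K = 4, n_k = 40), censoring = 0,
                        seed = 58)
  idx <- cbind(seq_len(sim$data$n), as.integer(sim$data$a))
  expect_identical(sim$data$y, sim$truth$cf_times[idx])

  # non-proportional hazards: the covariate-dependent shape is detectable
  cfgn <- dgp_config(K = 5, n_k = 400, ph = FALSE, b_sd = 1)
  simn <- simulate_trial(cfgn, censoring = 0, seed = 59)
  zph <- survival::cox.zph(survival::coxph(
    survival::Surv(y, delta) ~ a,
    data = data.frame(y = simn$data$y, delta = simn$data$delta,
                      a = simn$data$a)))
  expect_lt(zph$table["GLOBAL", "p"], 0.01)
})

test_that("censoring calibration hits its target", {
  set.seed(60)
  tt <- rweibull(1e4, 2, 50)
  expect_identical(simulate_censoring(tt, 0)$delta, rep(1L, 1e4))
  for (target in c(0.1, 0.4)) {
    cen <- simulate_censoring(tt, target)
    expect_lt(abs(mean(cen$delta == 0) - target), 0.011)
    expect_identical(cen$y, pmin(tt, cen$C))
  }
})

test_that("true effects are null for identical arms and stable in the seed", {
  cfg <- dgp_config(K = 4, n_k = 50, b_sd = 1)
  cfg_null <- cfg
  cfg_null$lambda <- rep(2000, 3)
  cfg_null$beta0 <- rep(-17, 3)
  cfg_null$betaL <- replicate(3, cfg$betaL[[1]], simplify = FALSE)
  cfg_null$betaNL <- replicate(3, cfg$betaNL[[1]], simplify = FALSE)
  set.seed(61)
  expect_lt(abs(true_cate(cfg_null, c(1, 2), "rmst", 60, n_mc = 2e4)), 1e-12)
  set.seed(62)
  t1 <- true_cate(cfg, c(1, 2), "rmst", 60, n_mc = 5e4)
  set.seed(63)
  t2 <- true_cate(cfg, c(1, 2), "rmst", 60, n_mc = 5e4)
  expect_equal(t1, t2, tolerance = 0.1)

  # single-covariate analytic case: quadrature over the covariate density
  cfg1 <- dgp_config(b_sd = 0, ph = TRUE,
                     betaL = list(c(0.8, rep(0, 11)), rep(0, 12),
                                  rep(0, 12)),
                     betaNL = replicate(3, rep(0, 4), simplify = FALSE),
                     beta0 = c(-17, -17, -17))
  quad <- function(j) {
    lam <- cfg1$lambda[j]
    beta <- cfg1$betaL[[j]][1]
    stats::integrate(function(x) {
      cc <- lam * exp(cfg1$beta0[j] + beta * x)
      gamma(0.5) * stats::pgamma(cc * 60^2, 0.5) / (2 * sqrt(cc)) * dnorm(x)
    }, -8, 8, rel.tol = 1e-10)$value
  }
  set.seed(64)
  mc <- true_cate(cfg1, c(1, 2), "rmst", 60, n_mc = 4e5)
  expect_equal(mc, quad(1) - quad(2), tolerance = 5e-3)
})

test_that("the study harness scores an oracle estimator perfectly", {
  cfg <- dgp_config(K = 3, n_k = 30, b_sd = 1)
  oracle <- function(sim, pairs, scale, t_star)
    do.call(rbind, lapply(pairs, function(p) {
      tr <- sample_true_cate(sim, p, scale, t_star)
      data.frame(pair = paste(p, collapse = " vs "),
                 estimate = tr * 1.10, lower = tr - 1, upper = tr + 1)
    }))
  res <- run_simulation_study(cfg, n_reps = 4, censoring = 0,
                              estimator = oracle, seed = 65)
  expect_equal(res$summary$coverage, rep(1, 3))
  # relative-bias sign convention: +10% inflation reports +0.10
  expect_equal(res$summary$rel_bias, rep(0.10, 3), tolerance = 1e-10)
})
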