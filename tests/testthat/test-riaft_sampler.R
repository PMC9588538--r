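test_that("response centring is the censored lognormal MLE", {
  # uncensored: MLE = sample moments of log y
  d <- clustered_survival_data(y = exp(c(-1, 0, 1)), delta = c(1, 1, 1),
                               a = c(1, 2, 1), cluster = c(1, 1, 2))
  cen <- center_responses(d)
  expect_equal(cen$mu_hat, 0, tolerance = 1e-6)
  expect_equal(cen$sigma_hat, sqrt(2 / 3), tolerance = 1e-4)
  # identity: mean log y_cent over events = mean log y - mu_hat
  expect_equal(mean(log(cen$y_cent)), mean(log(d$y)) - cen$mu_hat,
               tolerance = 1e-12)

  # censored sample: compare with a brute-force likelihood grid
  set.seed(21)
  n <- 500
  lt <- rnorm(n, 1.2, 0.8)
  ct <- rnorm(n, 1.6, 0.8)
  y <- exp(pmin(lt, ct))
  delta <- as.integer(lt < ct)
  d2 <- clustered_survival_data(y, delta, rep(1:2, n / 2),
                                rep(1:2, each = n / 2))
  cen2 <- center_responses(d2)
  loglik <- function(mu, s)
    sum(ifelse(delta == 1, dnorm(log(y), mu, s, log = TRUE),
               pnorm(log(y), mu, s, lower.tail = FALSE, log.p = TRUE)))
  mus <- seq(cen2$mu_hat - 0.05, cen2$mu_hat + 0.05, length.out = 41)
  ss <- seq(cen2$sigma_hat - 0.05, cen2$sigma_hat + 0.05, length.out = 41)
  grid <- outer(mus, ss, Vectorize(loglik))
  best <- which(grid == max(grid), arr.ind = TRUE)
  expect_equal(mus[best[1]], cen2$mu_hat, tolerance = 1e-2)
  expect_equal(ss[best[2]], cen2$sigma_hat, tolerance = 1e-2)

  d_all_cens <- clustered_survival_data(y, rep(0L, n), rep(1:2, n / 2),
                                        rep(1:2, each = n / 2))
  expect_error(center_responses(d_all_cens), "censored")
})

test_that("initial state follows the stated rules", {
  toy <- make_toy_data(n = 200, K = 4, seed = 22, cens_rate = 0.3)
  st <- initialize_state(toy$data)
  expect_equal(st$tau2, 1)
  expect_equal(st$alpha, 1)
  expect_length(st$b, 4)
  # lambda calibration: P(sigma < sigma0) = 0.9 under IG(nu/2, nu*lambda/2)
  sigma0 <- sqrt(st$sigma2)
  lam <- st$hyper$lambda
  expect_equal(pinvgamma(sigma0^2, 3 / 2, 3 * lam / 2), 0.9,
               tolerance = 1e-8)
  # numeric-integration cross-check of the same identity
  p_num <- stats::integrate(function(v)
    (3 * lam / 2)^(3 / 2) / gamma(3 / 2) * v^(-5 / 2) *
      exp(-(3 * lam / 2) / v), 0, sigma0^2)$value
  expect_equal(p_num, 0.9, tolerance = 1e-6)
  # censored z starts strictly above the censoring point
  cens <- toy$data$delta == 0
  expect_true(all(st$z[cens] > log(st$centering$y_cent)[cens]))
  expect_equal(st$z[!cens], log(st$centering$y_cent)[!cens])
})

test_that("truncated-normal sampler matches closed-form moments", {
  set.seed(23)
  # untruncated limit: lower far below the mean
  x <- rtruncnorm_lower(1e5, mean = 2, sd = 1, lower = -30)
  expect_equal(mean(x), 2, tolerance = 3 * 1 / sqrt(1e5) * 1.1)
  # truncation at the mean: E = mu + sd * phi(0) / (1 - Phi(0))
  x <- rtruncnorm_lower(1e5, mean = 1, sd = 2, lower = 1)
  expect_equal(mean(x), 1 + 2 * dnorm(0) / 0.5, tolerance = 0.01)
  expect_true(all(x > 1))
  # far tail: exponential-rejection branch stays finite and in support
  x <- rtruncnorm_lower(2000, mean = 0, sd = 1, lower = 7)
  expect_true(all(is.finite(x)) && all(x > 7))
  expect_equal(mean(x), dnorm(7) / pnorm(-7), tolerance = 0.01)
})

test_that("censoring imputation respects support and monotone coupling", {
  toy <- make_toy_data(n = 100, K = 4, seed = 24, cens_rate = 0.5)
  st <- initialize_state(toy$data)
  set.seed(1)
  z <- impute_censored(st, toy$data)
  cens <- toy$data$delta == 0
  expect_true(all(z[cens] > log(st$centering$y_cent)[cens]))
  expect_equal(z[!cens], log(st$centering$y_cent)[!cens])
  # raising a censoring time never lowers the imputed value (matched seed)
  toy2 <- toy
  i <- which(cens)[1]
  st2 <- st
  st2$centering$y_cent[i] <- st$centering$y_cent[i] * 1.5
  set.seed(1)
  z2 <- impute_censored(st2, toy$data)
  expect_gte(z2[i], z[i])
  expect_equal(z2[-i], z[-i])
})

test_that("random-intercept conditionals match their stated moments", {
  # single-subject cluster, residual 1, tau2*alpha = 1, sigma2 = 1:
  # posterior N(1/2, 1/2)
  d <- clustered_survival_data(y = c(1, 1), delta = c(1, 1), a = c(1, 2),
                               cluster = c(1, 2))
  st <- list(z = c(1, 1), f = c(0, 0), b = c(0, 0), sigma2 = 1, tau2 = 1,
             alpha = 1)
  set.seed(25)
  draws <- replicate(1e5, update_random_intercepts(st, d)[1])
  expect_equal(mean(draws), 0.5, tolerance = 0.01)
  expect_equal(var(draws), 0.5, tolerance = 0.02)
  # shrinkage limit: tau2 -> 0 forces b -> 0
  st$tau2 <- 1e-12
  expect_lt(max(abs(update_random_intercepts(st, d))), 1e-4)
})

test_that("alpha and tau2 updates draw from the stated inverse gammas", {
  st <- list(b = c(1, -1), tau2 = 1, alpha = 1)
  # alpha | b: IG(K/2 + 1, 1 + sum(b^2)/(2 tau2)) = IG(2, 2)
  set.seed(26)
  a <- replicate(1e5, update_alpha(st))
  ks <- suppressWarnings(stats::ks.test(a, function(q) pinvgamma(q, 2, 2)))
  expect_gt(ks$p.value, 0.01)
  # tau2 | b, alpha: IG(K/2 + 1, sum(b^2)/(2 alpha) + 1) = IG(2, 2)
  t2 <- replicate(1e5, update_tau2(st))
  ks2 <- suppressWarnings(stats::ks.test(t2, function(q) pinvgamma(q, 2, 2)))
  expect_gt(ks2$p.value, 0.01)
  # scale identity: (sum b^2 + 2 alpha) / (2 alpha)
  expect_equal(2, (sum(st$b^2) + 2 * st$alpha) / (2 * st$alpha))
})

test_that("identical seeds give identical chains", {
  toy <- make_toy_data(n = 80, K = 4, seed = 27, cens_rate = 0.3)
  f1 <- riaft_bart(toy$data, n_burn = 30, n_draws = 40, H = 10, seed = 99)
  f2 <- riaft_bart(toy$data, n_burn = 30, n_draws = 40, H = 10, seed = 99)
  expect_identical(f1$draws$sigma, f2$draws$sigma)
  expect_identical(f1$draws$cf, f2$draws$cf)
  expect_identical(f1$draws$b, f2$draws$b)
})

test_that("the model recovers variance components and a linear surface", {
  set.seed(28)
  K <- 20; n_k <- 50
  toy <- make_toy_data(n = K * n_k, K = K, p = 2, tau = 1, sigma = 0.5,
                       cens_rate = 0.25)
  fit <- riaft_bart(toy$data, n_burn = 300, n_draws = 500, H = 50, seed = 3)
  # sigma and the identified between-cluster scale tau*sqrt(alpha)
  post <- riaft_diagnostics(fit)$summary
  s <- post[post$parameter == "sigma", ]
  expect_lt(abs(s$mean - toy$sigma), 3 * s$sd)
  tt <- post[post$parameter == "tau", ]
  expect_lt(abs(tt$mean - toy$tau), 3 * tt$sd)
  # regression surface: posterior mean f correlates with the truth
  f_true <- toy$mu0 + as.numeric(toy$data$x %*% toy$beta) +
    toy$arm_eff[as.integer(toy$data$a)]
  f_post <- rowMeans(fit$draws$f)
  b_post <- rowMeans(fit$draws$b)[toy$data$cluster]
  expect_gt(cor(f_post + b_post, f_true + toy$b[toy$data$cluster]), 0.9)
})

test_that("extreme-value residuals degrade accuracy only mildly", {
  # same design generated with Weibull (extreme-value) vs lognormal
  # residuals: log-time effect bias should be small in both
  cfg_w <- dgp_config(K = 6, n_k = 80, b_sd = 1)
  cfg_l <- dgp_config(K = 6, n_k = 80, b_sd = 1,
                      outcome_dist = "lognormal")
  bias <- sapply(list(cfg_w, cfg_l), function(cfg) {
    sim <- simulate_trial(cfg, censoring = 0.1, seed = 29)
    fit <- riaft_bart(sim$data, n_burn = 200, n_draws = 300, H = 40,
                      seed = 30)
    estimate_cate(fit, c(1, 2))$estimate -
      sample_true_cate(sim, c(1, 2), "logtime")
  })
  expect_lt(abs(bias[1]), 0.2)
  expect_lt(abs(bias[1]) - abs(bias[2]), 0.15)
})

test_that("parameter expansion does not degrade tau mixing", {
  toy <- make_toy_data(n = 150, K = 5, tau = 0.1, sigma = 0.5, seed = 31)
  f_px <- riaft_bart(toy$data, n_burn = 200, n_draws = 600, H = 20,
                     seed = 32, expand = TRUE,
                     store_counterfactuals = FALSE)
  f_fix <- riaft_bart(toy$data, n_burn = 200, n_draws = 600, H = 20,
                      seed = 32, expand = FALSE,
                      store_counterfactuals = FALSE)
  expect_identical(f_fix$draws$alpha, rep(1, 600))
  expect_gt(ess(f_px$draws$tau), 0.5 * ess(f_fix$draws$tau))
})

test_that("diagnostics behave on null and degenerate chains", {
  toy <- make_toy_data(n = 60, K = 3, seed = 33)
  fit <- riaft_bart(toy$data, n_burn = 50, n_draws = 400, H = 10, seed = 34)
  dg <- riaft_diagnostics(fit)
  expect_true(all(c("sigma", "tau", "alpha", "b_1") %in%
                    dg$summary$parameter))
  # iid draws: rhat near 1, ess near n
  x <- rnorm(2000)
  expect_lt(abs(rhat_split(x) - 1), 0.05)
  expect_gt(ess(x), 1200)
  # strongly autocorrelated chain: small ess
  y <- as.numeric(stats::filter(rnorm(2000), 0.99, "recursive"))
  expect_lt(ess(y), 200)
  # ess agrees with an independent autocorrelation-sum implementation
  ess_oracle <- function(v) {
    n <- length(v)
    rho <- as.numeric(stats::acf(v, lag.max = 100, plot = FALSE)$acf)[-1]
    pos <- which(rho < 0)[1]
    if (!is.na(pos)) rho <- rho[seq_len(pos - 1)]
    min(n, n / (1 + 2 * sum(rho)))
  }
  expect_equal(ess(y), ess_oracle(y), tolerance = 0.1)
})
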