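test_that("confounding specs validate and draw from the right intervals", {
  spec <- confounding_spec(1:3, sign = "either", omega = 1,
                           pairs = list("1|2" = list(sign = "+",
                                                     omega = 0.75),
                                        "2|1" = list(sign = "-")))
  expect_equal(nrow(spec), 6)  # every ordered pair of distinct arms
  expect_error(confounding_spec(1:3, pairs = list("1|1" = list())),
               "unknown pair")
  # omega = 0: all values collapse to the centre
  z <- draw_confounding_values(confounding_spec(1:3, omega = 0), 0.9)
  expect_true(all(z == 0))
  # signed draw stays in (0, omega * sigma_hat); reference residual SD 0.90
  set.seed(71)
  d <- replicate(2000, draw_confounding_values(spec, 0.90))
  expect_true(all(d["1", "2", ] > 0 & d["1", "2", ] < 0.75 * 0.90))
  expect_true(all(d["2", "1", ] < 0 & d["2", "1", ] > -0.90))
  # uniformity over the interval
  ks <- suppressWarnings(stats::ks.test(d["1", "2", ], "punif", 0,
                                        0.75 * 0.90))
  expect_gt(ks$p.value, 0.01)
})

test_that("bias formula matches direct substitution and antisymmetry", {
  cm <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  p <- c("1" = 0.5, "2" = 0.3, "3" = 0.2)
  expect_equal(confounding_bias(cm, p, c(1, 2)), 0)
  cm["1", "2"] <- 0.4; cm["2", "1"] <- -0.3
  cm["1", "3"] <- 0.2; cm["3", "1"] <- -0.1
  cm["2", "3"] <- 0.25; cm["3", "2"] <- -0.15
  hand <- -0.5 * cm["2", "1"] + 0.3 * cm["1", "2"] -
    0.2 * (cm["2", "3"] - cm["1", "3"])
  expect_equal(confounding_bias(cm, p, c(1, 2)), hand)
  # J = 2 reduces to the two-term form
  p2 <- c("1" = 0.6, "2" = 0.4)
  cm2 <- cm[1:2, 1:2]
  expect_equal(confounding_bias(cm2, p2, c(1, 2)),
               -0.6 * cm2["2", "1"] + 0.4 * cm2["1", "2"])
  # a consistently signed function (c(a,b) = -c(b,a), its own sign-flipped
  # transpose) makes the bias antisymmetric in the pair
  cmA <- cm
  cmA[lower.tri(cmA)] <- -t(cmA)[lower.tri(cmA)]
  expect_equal(cmA, -t(cmA))
  expect_equal(confounding_bias(cmA, p, c(1, 2)),
               -confounding_bias(cmA, p, c(2, 1)))
})

test_that("GPS estimation recovers intercepts and coefficients", {
  # intercept-only: predicted probabilities equal the group frequencies
  set.seed(72)
  n <- 600
  a <- factor(sample(1:3, n, TRUE, prob = c(0.6, 0.3, 0.1)))
  d <- clustered_survival_data(rep(1, n), rep(1L, n), a,
                               rep(1:2, n / 2))
  g <- fit_gps(d, Q1 = 3)
  freq <- as.numeric(prop.table(table(a)))
  # cluster indicators are carried but uninformative here: the averaged
  # predictions equal the group frequencies
  expect_equal(unname(colMeans(g$mle)), freq, tolerance = 0.02)
  expect_true(all(abs(rowSums(g$mle) - 1) < 1e-8))
  for (q in 1:3) expect_true(all(abs(rowSums(g$probs[[q]]) - 1) < 1e-8))

  # coefficient recovery on a known multinomial design
  set.seed(73)
  n <- 5000
  x <- rnorm(n)
  e1 <- exp(0.5 + 0.8 * x); e2 <- exp(-0.2 - 0.5 * x)
  pr <- cbind(e1, e2, 1) / (e1 + e2 + 1)
  a2 <- factor(apply(pr, 1, function(p) sample.int(3, 1, prob = p)))
  d2 <- clustered_survival_data(rep(1, n), rep(1L, n), a2,
                                rep(1:2, n / 2),
                                x = data.frame(x = x))
  g2 <- fit_gps(d2, Q1 = 1)
  m <- nnet::multinom(a2 ~ x, trace = FALSE)
  co <- stats::coef(m)
  se <- summary(m)$standard.errors
  # baseline is arm 1, so the true slopes are -0.5 - 0.8 and -0.8
  expect_lt(abs(co["2", "x"] - (-1.3)), 3 * se["2", "x"])
  expect_lt(abs(co["3", "x"] - (-0.8)), 3 * se["3", "x"])
  expect_lt(max(abs(g2$probs[[1]] - pr)), 0.1)
})

test_that("outcome adjustment applies the propensity-weighted shift", {
  toy <- make_toy_data(n = 40, K = 2, seed = 74)
  lv <- levels(toy$data$a)
  cm <- matrix(0, 3, 3, dimnames = list(lv, lv))
  p <- matrix(1 / 3, 40, 3)
  # zero confounding leaves the data unchanged
  expect_equal(adjust_outcomes(toy$data, p, cm)$y, toy$data$y)
  # single-term case: subject in arm 1, p2 = 0.5, c(1,2) = 0.4 -> shift -0.2
  cm["1", "2"] <- 0.4
  p2 <- cbind(0.3, 0.5, 0.2)[rep(1, 40), ]
  adj <- adjust_outcomes(toy$data, p2, cm)
  in1 <- as.character(toy$data$a) == "1"
  expect_equal(log(adj$y[in1]), log(toy$data$y[in1]) - 0.2,
               tolerance = 1e-12)
  expect_equal(adj$y[!in1], toy$data$y[!in1])
  expect_identical(adj$delta, toy$data$delta)
})

test_that("zero-omega sensitivity reproduces the unadjusted analysis", {
  toy <- make_toy_data(n = 90, K = 3, seed = 75, cens_rate = 0.3)
  spec0 <- confounding_spec(levels(toy$data$a), omega = 0)
  res <- suppressWarnings(
    run_sensitivity(toy$data, spec0, Q1 = 1, Q2 = 1,
                    sigma_hat = 0.5, n_burn = 60, n_draws = 80,
                    H = 10, seed = 11))
  # the inner fit's seed is the documented child seed + 1
  cs <- ribart:::child_seed(11, 1, 1)
  fit <- riaft_bart(toy$data, n_burn = 60, n_draws = 80, H = 10,
                    seed = (cs + 1L) %% 2147483647L)
  ct <- estimate_cate(fit, c("1", "2"))
  expect_equal(attr(res, "draws")[["1|2"]], ct$draws, tolerance = 1e-12)
  expect_equal(res$estimate[1], ct$estimate, tolerance = 1e-12)
})

test_that("pooled intervals widen as the confounding bound grows", {
  toy <- make_toy_data(n = 80, K = 2, seed = 76, cens_rate = 0.2)
  widths <- vapply(c(0, 0.5, 1), function(om) {
    spec <- confounding_spec(levels(toy$data$a), sign = "either",
                             omega = om)
    res <- run_sensitivity(toy$data, spec, Q1 = 2, Q2 = 4,
                           sigma_hat = 0.5, n_burn = 50, n_draws = 80,
                           H = 10, seed = 12)
    res$upper[1] - res$lower[1]
  }, 0)
  expect_true(all(diff(widths) >= 0))
})

test_that("random intercepts absorb cluster-level unmeasured confounding", {
  # a cluster-constant unmeasured confounder shifting both treatment
  # assignment and outcomes: the log-time effect stays nearly unbiased
  # even when the cluster effect is large
  set.seed(77)
  K <- 6; n_k <- 120; n <- K * n_k
  cl <- rep(1:K, each = n_k)
  bias_at <- vapply(c(0, 2), function(gam) {
    u_k <- rnorm(K)                      # unmeasured, cluster-constant
    x <- rnorm(n)
    eta1 <- 0.3 * x + gam * u_k[cl]
    eta2 <- -0.2 * x - gam * u_k[cl]
    pr <- cbind(exp(eta1), exp(eta2), 1)
    pr <- pr / rowSums(pr)
    a <- factor(apply(pr, 1, function(p) sample.int(3, 1, prob = p)))
    arm_eff <- c(0.5, 0, -0.2)
    logt <- 3 + 0.4 * x + arm_eff[as.integer(a)] + gam * u_k[cl] +
      0.4 * rnorm(n)
    d <- clustered_survival_data(exp(logt), rep(1L, n), a, cl,
                                 x = data.frame(x = x))
    fit <- riaft_bart(d, n_burn = 150, n_draws = 250, H = 20, seed = 78)
    estimate_cate(fit, c("1", "2"))$estimate - 0.5
  }, 0)
  expect_lt(abs(bias_at[2]), abs(bias_at[1]) + 0.1)
  expect_lt(abs(bias_at[2]), 0.15)
})
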