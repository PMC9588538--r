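# Clustered-survival data-generating process: mixed continuous /
# categorical / binary covariates, random-intercept multinomial logistic
# treatment assignment calibrated to a target allocation ratio, Weibull
# counterfactual survival times under proportional or non-proportional
# hazards, and exponential censoring calibrated to a target proportion.

euler_gamma <- 0.57721566490153286

#' Simulation design configuration
#'
#' Defaults follow the package's reference design: K = 20 clusters of
#' n_k = 500 subjects; 10 confounders (5 standard normal, 2 three-level
#' categoricals with probabilities 0.3/0.3/0.4, 3 Bernoulli with p = 0.6,
#' 0.4, 0.5); treatment assigned by a random-intercept multinomial logistic
#' model with cluster effects `N(0, 1)` and intercepts calibrated to a
#' 6:3:1 allocation; counterfactual times from the Weibull survival curve
#' `S(t) = exp(-lambda_a * exp(lp) * t^eta)` with `lambda = (3000, 1200,
#' 2000)`, `eta = 2` (proportional hazards) or `exp(0.7 + 0.5 x1)`
#' (non-proportional), and cluster intercepts `N(0, 4^2)` in the log
#' hazard.
#'
#' The linear and nonlinear coefficient defaults are documented stand-ins
#' (moderate magnitudes, nonlinear basis `x1^2, x2^2, x1*x3, x4*x8`), as is
#' the per-arm outcome intercept `beta0` which places median survival on
#' the multi-year month scale of the motivating registry data; all are
#' overridable.
#'
#' @param K number of clusters.
#' @param n_k subjects per cluster.
#' @param xi0 treatment-model intercepts (length 2); `NULL` means
#'   "calibrate to `target_alloc` when first needed".
#' @param xi1L,xi2L linear treatment-model coefficients (length 12: the
#'   expanded covariate design).
#' @param xi1NL,xi2NL nonlinear treatment-model coefficients (length 4).
#' @param tau_sd SD of the treatment-model cluster effects.
#' @param target_alloc target marginal allocation (default 6:3:1).
#' @param lambda Weibull baseline rates per arm.
#' @param beta0 per-arm outcome intercepts (stand-in scale calibration).
#' @param betaL list of 3 linear outcome coefficient vectors (length 12).
#' @param betaNL list of 3 nonlinear outcome coefficient vectors (length
#'   4); set to zeros by `linear_only`.
#' @param b_sd SD of the outcome-model cluster intercepts (log-hazard
#'   scale).
#' @param ph proportional hazards (`TRUE`: `eta = 2`) or non-proportional
#'   (`FALSE`: `eta = exp(0.7 + 0.5 x1)` per subject, applied to that
#'   subject's times in all arms).
#' @param linear_only zero out the nonlinear outcome coefficients.
#' @param outcome_dist `"weibull"` (extreme-value AFT residuals, default)
#'   or `"lognormal"` (normal residuals with the same first two moments).
#' @param shared_u use one uniform draw per subject across arms instead of
#'   independent draws per (subject, arm).
#' @return list of class `dgp_config`.
#' @export
dgp_config <- function(K = 20, n_k = 500, xi0 = NULL,
                       xi1L = c(0.4, -0.3, 0.3, 0.2, -0.2, 0.3, -0.2,
                                0.2, -0.3, 0.4, -0.2, 0.2),
                       xi2L = c(-0.2, 0.3, -0.3, 0.2, 0.2, -0.2, 0.3,
                                -0.2, 0.2, -0.3, 0.2, -0.2),
                       xi1NL = c(0.3, -0.2, 0.2, -0.3),
                       xi2NL = c(-0.2, 0.2, -0.3, 0.2),
                       tau_sd = 1,
                       target_alloc = c(0.6, 0.3, 0.1),
                       lambda = c(3000, 1200, 2000),
                       beta0 = c(-18.2, -16.6, -17.4),
                       betaL = list(
                         c(0.5, -0.4, 0.3, -0.3, 0.2, 0.3, -0.2, 0.2,
                           -0.2, 0.3, -0.3, 0.2),
                         c(0.3, -0.2, 0.5, -0.2, 0.3, -0.2, 0.3, -0.3,
                           0.2, 0.2, 0.2, -0.2),
                         c(0.4, -0.3, 0.2, -0.4, 0.4, 0.2, 0.2, -0.2,
                           -0.2, 0.2, -0.2, 0.3)),
                       betaNL = list(c(0.3, -0.2, 0.2, 0.3),
                                     c(0.2, 0.2, -0.2, 0.2),
                                     c(-0.2, 0.3, 0.2, -0.2)),
                       b_sd = 4, ph = TRUE, linear_only = FALSE,
                       outcome_dist = c("weibull", "lognormal"),
                       shared_u = FALSE) {
  outcome_dist <- match.arg(outcome_dist)
  stopifnot(K >= 2, n_k >= 1, all(lambda > 0), length(lambda) == 3,
            length(betaL) == 3, length(betaNL) == 3,
            abs(sum(target_alloc) - 1) < 1e-8, all(target_alloc > 0))
  if (linear_only) betaNL <- lapply(betaNL, function(b) b * 0)
  structure(list(K = K, n_k = n_k, xi0 = xi0, xi1L = xi1L, xi2L = xi2L,
                 xi1NL = xi1NL, xi2NL = xi2NL, tau_sd = tau_sd,
                 target_alloc = target_alloc, lambda = lambda,
                 beta0 = beta0, betaL = betaL, betaNL = betaNL,
                 b_sd = b_sd, ph = ph, linear_only = linear_only,
                 outcome_dist = outcome_dist, shared_u = shared_u),
            class = "dgp_config")
}

#' Simulate the confounder block
#'
#' Five iid standard-normal columns, two three-level categoricals with
#' probabilities (0.3, 0.3, 0.4), and three Bernoulli columns with
#' success probabilities 0.6, 0.4 and 0.5.
#'
#' @param n number of subjects.
#' @return data frame with columns `x1..x5` (numeric), `x6`, `x7`
#'   (factors with levels a/b/c) and `x8..x10` (0/1).
#' @export
simulate_covariates <- function(n) {
  stopifnot(n >= 1)
  out <- data.frame(matrix(stats::rnorm(n * 5), n, 5))
  names(out) <- paste0("x", 1:5)
  for (j in 6:7)
    out[[paste0("x", j)]] <- factor(
      sample(c("a", "b", "c"), n, replace = TRUE,
             prob = c(0.3, 0.3, 0.4)), levels = c("a", "b", "c"))
  probs <- c(0.6, 0.4, 0.5)
  for (j in 8:10)
    out[[paste0("x", j)]] <- stats::rbinom(n, 1, probs[j - 7])
  out
}

# numeric design for the DGP coefficient vectors (12 columns)
covariate_design <- function(X) {
  cbind(as.matrix(X[paste0("x", 1:5)]),
        x6b = as.numeric(X$x6 == "b"), x6c = as.numeric(X$x6 == "c"),
        x7b = as.numeric(X$x7 == "b"), x7c = as.numeric(X$x7 == "c"),
        as.matrix(X[paste0("x", 8:10)]))
}

#' Nonlinear transformations of the confounders
#'
#' The basis `(x1^2, x2^2, x1*x3, x4*x8)` entering both the treatment and
#' outcome models.
#'
#' @param X covariate data frame from [simulate_covariates].
#' @return n x 4 numeric matrix.
#' @export
nonlinear_basis <- function(X) {
  cbind(g1 = X$x1^2, g2 = X$x2^2, g3 = X$x1 * X$x3, g4 = X$x4 * X$x8)
}

# per-subject multinomial-logit probabilities (n x 3)
treatment_probs <- function(D, G, tau, config) {
  e1 <- exp(config$xi0[1] + D %*% config$xi1L + G %*% config$xi1NL + tau)
  e2 <- exp(config$xi0[2] + D %*% config$xi2L + G %*% config$xi2NL + tau)
  p <- cbind(e1, e2, 1)
  p / rowSums(p)
}

#' Calibrate treatment-model intercepts to a target allocation
#'
#' Iterative proportional adjustment of the two intercepts on Monte-Carlo
#' samples of the covariates and cluster effects until the expected
#' marginal allocation is within `tol` of the target.
#'
#' @param config a [dgp_config].
#' @param target target allocation proportions (default from the config).
#' @param n_mc Monte-Carlo sample size per iteration.
#' @param tol convergence tolerance on each arm's share (default 0.005).
#' @param max_iter iteration cap (error on non-convergence).
#' @return length-2 vector of calibrated intercepts.
#' @export
calibrate_intercepts <- function(config, target = config$target_alloc,
                                 n_mc = 20000, tol = 0.005,
                                 max_iter = 100) {
  stopifnot(all(target > 0))
  X <- simulate_covariates(n_mc)
  D <- covariate_design(X)
  G <- nonlinear_basis(X)
  tau <- stats::rnorm(n_mc, 0, config$tau_sd)
  cfg <- config
  cfg$xi0 <- if (is.null(config$xi0)) c(0, 0) else config$xi0
  for (it in seq_len(max_iter)) {
    share <- colMeans(treatment_probs(D, G, tau, cfg))
    if (max(abs(share - target)) < tol) return(cfg$xi0)
    cfg$xi0 <- cfg$xi0 + (log(target / share) - log(target[3] / share[3]))[1:2]
  }
  stop("intercept calibration did not converge in ", max_iter,
       " iterations")
}

#' Assign treatments from the random-intercept multinomial logistic model
#'
#' @param X covariate data frame.
#' @param G nonlinear basis matrix.
#' @param cluster integer cluster index per subject.
#' @param config a [dgp_config] whose `xi0` is set (see
#'   [calibrate_intercepts]).
#' @param tau optional fixed cluster effects (length K); drawn `N(0,
#'   tau_sd^2)` when `NULL`.
#' @return list with factor `a` (levels 1/2/3), the per-subject probability
#'   matrix `probs` and the cluster effects `tau`.
#' @export
simulate_treatment <- function(X, G, cluster, config, tau = NULL) {
  if (is.null(config$xi0)) stop("config$xi0 not set; calibrate first")
  K <- max(cluster)
  if (is.null(tau)) tau <- stats::rnorm(K, 0, config$tau_sd)
  D <- covariate_design(X)
  p <- treatment_probs(D, G, tau[cluster], config)
  a <- apply(p, 1, function(pr) sample.int(3, 1, prob = pr))
  list(a = factor(a, levels = 1:3), probs = p, tau = tau)
}

# per-subject Weibull shape
dgp_eta <- function(X, config) {
  if (config$ph) rep(2, nrow(X)) else exp(0.7 + 0.5 * X$x1)
}

# per-subject per-arm log-hazard-scale linear predictor (includes b)
dgp_lp <- function(X, G, b_subject, config) {
  D <- covariate_design(X)
  vapply(1:3, function(j)
    as.numeric(config$beta0[j] + D %*% config$betaL[[j]] +
                 G %*% config$betaNL[[j]] + b_subject),
    numeric(nrow(X)))
}

#' Simulate counterfactual survival times
#'
#' Draws `T(a_j)` for every arm from `S(t) = exp(-lambda_j exp(lp_j)
#' t^eta)` via `T = (-log U / (lambda_j exp(lp_j)))^(1/eta)`. By default
#' the uniform draw is independent per (subject, arm); `shared_u` in the
#' config reuses one draw per subject across arms. Under
#' `outcome_dist = "lognormal"` the extreme-value residual
#' `log(-log U)/eta` is replaced by a normal residual with the same first
#' two moments.
#'
#' @param X covariate data frame.
#' @param G nonlinear basis.
#' @param b_subject per-subject cluster intercept value.
#' @param config a [dgp_config].
#' @return n x 3 matrix of counterfactual times (months).
#' @export
simulate_counterfactual_times <- function(X, G, b_subject, config) {
  n <- nrow(X)
  eta <- dgp_eta(X, config)
  lp <- dgp_lp(X, G, b_subject, config)
  out <- matrix(NA_real_, n, 3)
  u_shared <- if (config$shared_u) stats::runif(n) else NULL
  for (j in 1:3) {
    m <- (-log(config$lambda[j]) - lp[, j]) / eta
    if (config$outcome_dist == "weibull") {
      u <- if (config$shared_u) u_shared else stats::runif(n)
      out[, j] <- exp(m + log(-log(u)) / eta)
    } else {
      eps <- if (config$shared_u && j > 1) attr(out, "eps") else
        stats::rnorm(n, -euler_gamma, pi / sqrt(6))
      if (config$shared_u && j == 1) attr(out, "eps") <- eps
      out[, j] <- exp(m + eps / eta)
    }
  }
  attr(out, "eps") <- NULL
  out
}

#' Calibrate and apply exponential censoring
#'
#' The exponential rate is found by bisection so that the expected censored
#' fraction `mean(1 - exp(-rate * T))` over the supplied times equals
#' `target_prop`; censoring times are then drawn and the observed data
#' assembled.
#'
#' @param times observed (uncensored) failure times.
#' @param target_prop target censoring proportion in `[0, 1)`.
#' @param rate optional fixed rate (skips calibration).
#' @return list with `C`, `y = pmin(times, C)`, `delta = I(times < C)` and
#'   the `rate` used. `target_prop = 0` yields no censoring.
#' @export
simulate_censoring <- function(times, target_prop, rate = NULL) {
  stopifnot(target_prop >= 0, target_prop < 1, all(times > 0))
  if (target_prop == 0) {
    return(list(C = rep(Inf, length(times)), y = times,
                delta = rep(1L, length(times)), rate = 0))
  }
  if (is.null(rate)) {
    lo <- 1e-8; hi <- 10
    f <- function(r) mean(1 - exp(-r * times)) - target_prop
    while (f(hi) < 0) hi <- hi * 10
    for (it in 1:60) {
      mid <- sqrt(lo * hi)
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    rate <- sqrt(lo * hi)
  }
  C <- stats::rexp(length(times), rate = rate)
  list(C = C, y = pmin(times, C), delta = as.integer(times < C),
       rate = rate)
}

#' Simulate one full clustered-survival trial
#'
#' Covariates, cluster effects, treatment assignment, counterfactual and
#' observed times, and calibrated censoring, bundled with the ground truth
#' needed for closed-form effect computation.
#'
#' @param config a [dgp_config]; its `xi0` is calibrated on the fly if
#'   unset.
#' @param censoring target censoring proportion.
#' @param censor_rate optional fixed exponential censoring rate (skips the
#'   bisection calibration; `censoring` is then ignored).
#' @param cluster_effects optional list with elements `tau` (treatment-model
#'   cluster effects) and `b` (outcome-model cluster intercepts), each of
#'   length K, to condition a fresh draw on previously realised clusters
#'   (e.g. when checking the censoring calibration on new subjects from the
#'   same design).
#' @param seed optional seed.
#' @return list of class `ribart_sim`: `data` (a
#'   [clustered_survival_data]), `truth` (per-subject linear predictors,
#'   shapes, cluster effects, counterfactual times, assignment
#'   probabilities), and the `config` used (with calibrated intercepts).
#' @export
simulate_trial <- function(config = dgp_config(), censoring = 0.1,
                           censor_rate = NULL, cluster_effects = NULL,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config$xi0)) config$xi0 <- calibrate_intercepts(config)
  n <- config$K * config$n_k
  cluster <- rep(seq_len(config$K), each = config$n_k)
  X <- simulate_covariates(n)
  G <- nonlinear_basis(X)
  trt <- simulate_treatment(X, G, cluster, config,
                            tau = cluster_effects$tau)
  b_k <- if (!is.null(cluster_effects$b)) cluster_effects$b
         else stats::rnorm(config$K, 0, config$b_sd)
  cf_times <- simulate_counterfactual_times(X, G, b_k[cluster], config)
  t_obs <- cf_times[cbind(seq_len(n), as.integer(trt$a))]
  cens <- simulate_censoring(t_obs, censoring, rate = censor_rate)
  data <- clustered_survival_data(y = cens$y, delta = cens$delta,
                                  a = trt$a, cluster = cluster, x = X)
  structure(list(
    data = data,
    truth = list(lp = dgp_lp(X, G, b_k[cluster], config),
                 eta = dgp_eta(X, config), b_k = b_k,
                 cluster = cluster, cf_times = cf_times,
                 probs = trt$probs, tau = trt$tau,
                 censor_rate = cens$rate),
    config = config), class = "ribart_sim")
}

# closed-form per-subject counterfactual summaries given scale parameters
# c_j = lambda_j * exp(lp_j) and shape eta (weibull), or the matched
# lognormal; returns an n x 3 matrix on the requested scale
counterfactual_summary <- function(lp, eta, config, scale, t_star) {
  out <- matrix(NA_real_, nrow(lp), 3)
  for (j in 1:3) {
    if (config$outcome_dist == "weibull") {
      cc <- config$lambda[j] * exp(lp[, j])
      out[, j] <- switch(scale,
        logtime = (-log(config$lambda[j]) - lp[, j]) / eta -
          euler_gamma / eta,
        surv = exp(-cc * t_star^eta),
        rmst = gamma(1 / eta) * stats::pgamma(cc * t_star^eta, 1 / eta) /
          (eta * cc^(1 / eta)))
    } else {
      m <- (-log(config$lambda[j]) - lp[, j]) / eta - euler_gamma / eta
      s <- pi / (sqrt(6) * eta)
      out[, j] <- switch(scale,
        logtime = m,
        surv = stats::pnorm((log(t_star) - m) / s, lower.tail = FALSE),
        rmst = rmst_lognormal(m, s, t_star))
    }
  }
  out
}

#' Replicate-conditional true treatment effects
#'
#' The exact (closed-form, no event noise) average counterfactual contrast
#' over a simulated replicate's realised covariates and cluster effects —
#' the truth matching the conditional-average estimand.
#'
#' @param sim a [simulate_trial] result.
#' @param pair ordered pair of arm labels.
#' @param scale `"logtime"`, `"surv"` or `"rmst"`.
#' @param t_star horizon in months.
#' @return the true effect on the requested scale.
#' @export
sample_true_cate <- function(sim, pair, scale = "rmst", t_star = 60) {
  scale <- match.arg(scale, c("logtime", "surv", "rmst"))
  j <- as.integer(as.character(pair))
  s <- counterfactual_summary(sim$truth$lp, sim$truth$eta, sim$config,
                              scale, t_star)
  mean(s[, j[1]] - s[, j[2]])
}

#' Population true treatment effects by Monte Carlo
#'
#' Averages closed-form subject-level counterfactual contrasts over freshly
#' drawn covariates and cluster effects.
#'
#' @param config a [dgp_config].
#' @param pair ordered pair of arm labels.
#' @param scale,t_star effect scale and horizon.
#' @param n_mc Monte-Carlo sample size (default 1e6).
#' @return the true effect.
#' @export
true_cate <- function(config, pair, scale = "rmst", t_star = 60,
                      n_mc = 1e6) {
  scale <- match.arg(scale, c("logtime", "surv", "rmst"))
  X <- simulate_covariates(n_mc)
  G <- nonlinear_basis(X)
  b <- stats::rnorm(n_mc, 0, config$b_sd)
  lp <- dgp_lp(X, G, b, config)
  eta <- dgp_eta(X, config)
  j <- as.integer(as.character(pair))
  s <- counterfactual_summary(lp, eta, config, scale, t_star)
  mean(s[, j[1]] - s[, j[2]])
}
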