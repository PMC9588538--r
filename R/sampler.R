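# The random-intercept AFT model with a BART regression function:
# response centring, censoring data-augmentation, the parameter-expanded
# variance updates, and the full Metropolis-within-Gibbs loop.
#
# Model:  log T_ik = f(A_ik, X_ik) + b_k + eps_ik,
#         b_k ~ N(0, alpha * tau^2),  eps_ik ~ N(0, sigma^2),
# with f a sum of H regularised trees. Right censoring is handled by
# imputing latent log failure times from their truncated normal
# conditionals inside the Gibbs loop.

#' Centre responses with an intercept-only lognormal AFT fit
#'
#' Fits the censored lognormal model `log Y = mu + sigma * eps` by maximum
#' likelihood (censored subjects contribute survival terms) and returns the
#' centred responses `y * exp(-mu_hat)`. The intercept is added back to all
#' posterior draws of the regression function in the final output of
#' [riaft_bart()].
#'
#' @param data a [clustered_survival_data] object.
#' @return list of class `centering_result` with `mu_hat`, `sigma_hat`, and
#'   `y_cent`.
#' @export
center_responses <- function(data) {
  stopifnot(inherits(data, "clustered_survival_data"))
  if (all(data$delta == 0))
    stop("all subjects censored: the centring likelihood has no maximum")
  fit <- survival::survreg(survival::Surv(data$y, data$delta) ~ 1,
                           dist = "lognormal")
  mu_hat <- unname(stats::coef(fit)[1])
  sigma_hat <- fit$scale
  structure(list(mu_hat = mu_hat, sigma_hat = sigma_hat,
                 y_cent = data$y * exp(-mu_hat)),
            class = "centering_result")
}

# design matrix: one-hot treatment indicators (all J levels) then covariates
build_design <- function(data, a_level = NULL) {
  lv <- levels(data$a)
  a <- if (is.null(a_level)) as.character(data$a) else
    rep(as.character(a_level), data$n)
  trt <- matrix(0, data$n, length(lv),
                dimnames = list(NULL, paste0("trt_", lv)))
  trt[cbind(seq_len(data$n), match(a, lv))] <- 1
  if (is.null(data$x)) trt else cbind(trt, data$x)
}

#' Initialise the sampler state
#'
#' Random intercepts start at the per-cluster mean residual from a
#' parametric lognormal AFT fit with the covariates as linear predictors;
#' `sigma(0)` is the standard deviation of the pooled residuals; `lambda`
#' is calibrated so that `P(sigma < sigma(0)) = 0.9` under the
#' `IG(nu/2, nu*lambda/2)` prior; `tau2` and `alpha` start at 1; the latent
#' log times start at the observed centred log times, offset upwards by
#' `0.1 * sigma(0)` for censored subjects.
#'
#' @param data a [clustered_survival_data] object.
#' @param hyper a [bart_hyperparams] object (its `lambda`, if `NULL`, is
#'   replaced by the calibrated value).
#' @param centering optional precomputed [center_responses] result.
#' @return list of class `riaft_state` with elements `z`, `f`, `b`,
#'   `sigma2`, `tau2`, `alpha`, plus `hyper` and `centering`.
#' @export
initialize_state <- function(data, hyper = bart_hyperparams(),
                             centering = NULL) {
  stopifnot(inherits(data, "clustered_survival_data"))
  if (is.null(centering)) centering <- center_responses(data)
  lp <- tryCatch({
    if (is.null(data$x)) stop("no covariates")
    fit <- survival::survreg(survival::Surv(data$y, data$delta) ~ data$x,
                             dist = "lognormal")
    if (any(is.na(stats::coef(fit)))) stop("singular design")
    as.numeric(cbind(1, data$x) %*% stats::coef(fit))
  }, error = function(e) {
    warning("linear AFT initialisation failed (", conditionMessage(e),
            "); falling back to intercept-only residuals")
    rep(centering$mu_hat, data$n)
  })
  r <- log(data$y) - lp
  b0 <- as.numeric(tapply(r, data$cluster, mean))
  sigma0 <- stats::sd(r)
  if (!(sigma0 > 0)) sigma0 <- centering$sigma_hat
  lambda <- hyper$lambda
  if (is.null(lambda))
    lambda <- solve_lambda0(sigma0, hyper$nu)
  hyper$lambda <- lambda
  z <- log(centering$y_cent)
  z[data$delta == 0] <- z[data$delta == 0] + 0.1 * sigma0
  structure(list(z = z, f = rep(0, data$n), b = b0,
                 sigma2 = sigma0^2, tau2 = 1, alpha = 1,
                 hyper = hyper, centering = centering),
            class = "riaft_state")
}

#' Calibrate the residual-variance prior scale
#'
#' Finds `lambda` such that `P(sigma < sigma0) = 0.9` when
#' `sigma^2 ~ IG(nu/2, nu*lambda/2)`.
#'
#' @param sigma0 initial residual scale.
#' @param nu prior shape.
#' @return the calibrated `lambda`.
#' @export
solve_lambda0 <- function(sigma0, nu = 3) {
  stopifnot(sigma0 > 0, nu > 0)
  # P(sigma^2 < s0^2) = P(Gamma(nu/2, rate = nu*lambda/2) > 1/s0^2) = 0.9
  2 * stats::qgamma(0.1, shape = nu / 2, rate = 1) * sigma0^2 / nu
}

#' Impute censored log survival times
#'
#' For each censored subject, draws the latent complete-data centred log
#' time from `N(f + b_cluster, sigma^2)` truncated to `(log y_cent, Inf)`;
#' event subjects keep their observed `log y_cent`.
#'
#' @param state a sampler state (see [initialize_state]).
#' @param data the [clustered_survival_data] the state was built on.
#' @return the updated latent vector `z`.
#' @export
impute_censored <- function(state, data) {
  z <- log(state$centering$y_cent)
  cens <- which(data$delta == 0)
  if (length(cens)) {
    mu <- state$f[cens] + state$b[data$cluster[cens]]
    z[cens] <- rtruncnorm_lower(length(cens), mean = mu,
                                sd = sqrt(state$sigma2), lower = z[cens])
  }
  z
}

#' Gibbs update of the cluster random intercepts
#'
#' Each `b_k` is drawn independently from
#' `N( tau2*alpha * S_k / (n_k*tau2*alpha + sigma2),
#'     sigma2*tau2*alpha / (n_k*tau2*alpha + sigma2) )`,
#' where `S_k` sums the current residuals `z - f` over cluster k.
#'
#' @inheritParams impute_censored
#' @return numeric vector of K new intercepts.
#' @export
update_random_intercepts <- function(state, data) {
  v <- state$tau2 * state$alpha
  r <- state$z - state$f
  s <- as.numeric(tapply(r, factor(data$cluster, levels = seq_len(data$K)),
                         sum))
  s[is.na(s)] <- 0
  nk <- tabulate(data$cluster, nbins = data$K)
  denom <- nk * v + state$sigma2
  stats::rnorm(data$K, mean = v * s / denom,
               sd = sqrt(state$sigma2 * v / denom))
}

#' Gibbs update of the parameter-expansion scalar
#'
#' Draws the shared redundant scale `alpha` from its conjugate conditional
#' `IG(K/2 + 1, 1 + sum(b_k^2) / (2 tau2))` under the `IG(1, 1)` prior and
#' `b_k ~ N(0, alpha tau2)` — the mirror image of the `tau2` update.
#' (Successive-conditional simulation singles this out as the unique
#' shape leaving the joint prior invariant; see the methods vignette.)
#'
#' @param state a sampler state.
#' @return one positive draw of `alpha`.
#' @export
update_alpha <- function(state) {
  stopifnot(state$tau2 > 0)
  rinvgamma(1, shape = length(state$b) / 2 + 1,
            scale = 1 + sum(state$b^2) / (2 * state$tau2))
}

#' Gibbs update of the random-intercept variance component
#'
#' Draws `tau2` from `IG(K/2 + 1, sum(b_k^2)/(2 alpha) + 1)`.
#'
#' @param state a sampler state.
#' @return one positive draw of `tau2`.
#' @export
update_tau2 <- function(state) {
  stopifnot(state$alpha > 0)
  rinvgamma(1, shape = length(state$b) / 2 + 1,
            scale = sum(state$b^2) / (2 * state$alpha) + 1)
}

#' Fit the random-intercept BART accelerated failure time model
#'
#' Runs the full Metropolis-within-Gibbs loop: truncated-normal imputation
#' of censored log times; one backfitting sweep of the sum-of-trees
#' regression function on `z - b`; the conjugate residual-variance update;
#' the random-intercept update; and the parameter-expanded `alpha`/`tau2`
#' updates. Treatment enters the regression function as one-hot indicator
#' columns appended to the covariates, so counterfactual predictions are
#' obtained by switching those indicators.
#'
#' Stored draws of the regression function are reported on the original
#' log-time scale (the centring intercept is added back).
#'
#' @param data a [clustered_survival_data] object.
#' @param n_burn burn-in iterations (default 1000).
#' @param n_draws stored posterior draws (default 3500).
#' @param thin thinning interval (default 1).
#' @param H,k,nu,lambda,base,power BART hyperparameters, see
#'   [bart_hyperparams].
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param store_counterfactuals keep per-draw regression-function values at
#'   the training design under every treatment arm (needed for the causal
#'   estimators; default `TRUE`).
#' @param keep_forests store a compact tree snapshot at every draw, enabling
#'   counterfactual prediction at new covariate rows (default `FALSE`).
#' @param expand use the parameter-expansion update for `alpha` (default
#'   `TRUE`; `FALSE` fixes `alpha = 1`, mainly for mixing comparisons).
#' @param verbose print progress.
#' @return object of class `ribart_fit`: posterior draws (`cf` array
#'   n x J x D of counterfactual f values on the log-time scale, `b` K x D,
#'   `sigma`, `tau2`, `alpha`, `tau = sqrt(alpha*tau2)`), the centring
#'   constants, data dimensions and chain settings.
#' @export
riaft_bart <- function(data, n_burn = 1000, n_draws = 3500, thin = 1,
                       H = 200, k = 2, nu = 3, lambda = NULL,
                       base = 0.95, power = 2, seed = NULL,
                       store_counterfactuals = TRUE, keep_forests = FALSE,
                       expand = TRUE, verbose = FALSE) {
  stopifnot(inherits(data, "clustered_survival_data"), n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  centering <- center_responses(data)
  hyper <- bart_hyperparams(H = H, k = k,
                            sigma_hat_aft = centering$sigma_hat,
                            nu = nu, lambda = lambda, base = base,
                            power = power)
  state <- initialize_state(data, hyper, centering)
  hyper <- state$hyper  # lambda calibrated during initialisation
  leaf_sd <- leaf_prior_sd(centering$sigma_hat, hyper$H, hyper$k)

  X <- build_design(data)
  forest <- bart_forest(X, H = hyper$H, base = hyper$base,
                        power = hyper$power)
  designs <- lapply(levels(data$a), function(a) build_design(data, a))

  D <- n_draws
  n <- data$n; J <- data$J; K <- data$K
  cf <- if (store_counterfactuals) array(NA_real_, c(n, J, D)) else NULL
  f_obs <- matrix(NA_real_, n, D)
  b_dr <- matrix(NA_real_, K, D)
  sig_dr <- tau2_dr <- alpha_dr <- numeric(D)
  forests <- if (keep_forests) vector("list", D) else NULL

  n_iter <- n_burn + n_draws * thin
  d <- 0L
  for (it in seq_len(n_iter)) {
    state$z <- impute_censored(state, data)
    bvec <- state$b[data$cluster]
    state$f <- forest_update_cpp(forest$ptr, state$z - bvec, state$sigma2,
                                 leaf_sd)
    if (!all(is.finite(state$f)))
      stop("numerical overflow in the forest update at iteration ", it)
    state$sigma2 <- update_sigma2(state$z - state$f - bvec, hyper$nu,
                                  hyper$lambda)
    state$b <- update_random_intercepts(state, data)
    state$alpha <- if (expand) update_alpha(state) else 1
    state$tau2 <- update_tau2(state)

    if (it > n_burn && (it - n_burn) %% thin == 0) {
      d <- d + 1L
      if (store_counterfactuals)
        for (j in seq_len(J))
          cf[, j, d] <- forest_predict_cpp(forest$ptr, designs[[j]]) +
            centering$mu_hat
      f_obs[, d] <- state$f + centering$mu_hat
      b_dr[, d] <- state$b
      sig_dr[d] <- sqrt(state$sigma2)
      tau2_dr[d] <- state$tau2
      alpha_dr[d] <- state$alpha
      if (keep_forests) forests[[d]] <- forest_trees_cpp(forest$ptr)
    }
    if (verbose && it %% 500 == 0)
      message("iteration ", it, "/", n_iter)
  }

  structure(list(
    draws = list(cf = cf, f = f_obs, b = b_dr, sigma = sig_dr,
                 tau2 = tau2_dr, alpha = alpha_dr,
                 tau = sqrt(alpha_dr * tau2_dr)),
    mu_hat = centering$mu_hat, sigma_hat_aft = centering$sigma_hat,
    hyper = hyper, treatments = levels(data$a),
    cluster_labels = data$cluster_labels, cluster = data$cluster,
    a_obs = data$a, n = n, J = J, K = K, D = D,
    settings = list(n_burn = n_burn, n_draws = n_draws, thin = thin,
                    seed = seed, expand = expand),
    forests = forests,
    move_rates = forest_summary(forest)),
    class = "ribart_fit")
}

#' @export
print.ribart_fit <- function(x, ...) {
  cat("Random-intercept BART AFT fit\n")
  cat(sprintf("  %d subjects, %d clusters, %d arms; %d stored draws (H = %d trees)\n",
              x$n, x$K, x$J, x$D, x$hyper$H))
  cat(sprintf("  posterior mean sigma = %.3f, between-cluster SD = %.3f (log months)\n",
              mean(x$draws$sigma), mean(x$draws$tau)))
  invisible(x)
}

#' Convergence diagnostics for a fitted model
#'
#' Traces, effective sample sizes and split-chain R-hat for the variance
#' parameters and the random intercepts.
#'
#' @param fit a [riaft_bart] fit with at least 10 stored draws.
#' @return list with a `summary` data frame (parameter, mean, sd, ess,
#'   rhat) and the raw `traces`.
#' @export
riaft_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "ribart_fit"))
  if (fit$D < 10) stop("need at least 10 stored draws")
  traces <- c(list(sigma = fit$draws$sigma,
                   tau = fit$draws$tau,
                   alpha = fit$draws$alpha),
              stats::setNames(lapply(seq_len(fit$K),
                                     function(k) fit$draws$b[k, ]),
                              paste0("b_", seq_len(fit$K))))
  summary <- data.frame(
    parameter = names(traces),
    mean = vapply(traces, mean, 0),
    sd = vapply(traces, stats::sd, 0),
    ess = vapply(traces, ess, 0),
    rhat = vapply(traces, rhat_split, 0),
    row.names = NULL)
  list(summary = summary, traces = traces)
}
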