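# Confounding-function sensitivity analysis for multiple treatments:
# generalized propensity score estimation, confounding-function draws,
# the bias identity, the outcome correction, and the nested
# multiple-imputation loop with pooling.
#
# The confounding function c(a_j, a_m, x, v) is the difference in mean
# potential log survival time under a_j between subjects treated with a_j
# and subjects treated with a_m at the same covariate level; it is zero
# for every pair exactly when there is no individual-level unmeasured
# confounding.

#' Specify confounding functions for every ordered treatment pair
#'
#' Each ordered pair `(a_j, a_m)` carries a sign (`"+"`, `"-"` or
#' `"either"`), a bound `omega` in units of the residual SD unexplained by
#' the measured covariates, and an optional centre. A sensitivity draw is
#' uniform on `centre + (0, omega*sigma_hat)` for sign `"+"`, on
#' `centre + (-omega*sigma_hat, 0)` for `"-"`, and on
#' `centre + (-omega*sigma_hat, omega*sigma_hat)` for `"either"`.
#'
#' @param treatments character vector of treatment labels.
#' @param sign default sign for unspecified pairs.
#' @param omega default bound (default 1).
#' @param pairs optional named list overriding individual ordered pairs,
#'   e.g. `list("1|2" = list(sign = "+", omega = 0.75))` for the pair
#'   (a_1, a_2); entries may also set `center`.
#' @return data frame of class `confounding_spec` with one row per ordered
#'   pair: columns `aj`, `am`, `sign`, `omega`, `center`.
#' @export
confounding_spec <- function(treatments, sign = "either", omega = 1,
                             pairs = NULL) {
  stopifnot(length(treatments) >= 2, omega >= 0)
  treatments <- as.character(treatments)
  grid <- expand.grid(aj = treatments, am = treatments,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$aj != grid$am, ]
  grid$sign <- sign
  grid$omega <- omega
  grid$center <- 0
  rownames(grid) <- paste(grid$aj, grid$am, sep = "|")
  for (key in names(pairs)) {
    if (!key %in% rownames(grid)) stop("unknown pair: ", key)
    p <- pairs[[key]]
    if (!is.null(p$sign)) grid[key, "sign"] <- p$sign
    if (!is.null(p$omega)) grid[key, "omega"] <- p$omega
    if (!is.null(p$center)) grid[key, "center"] <- p$center
  }
  if (!all(grid$sign %in% c("+", "-", "either")))
    stop('sign must be "+", "-" or "either"')
  if (any(grid$omega < 0)) stop("omega must be non-negative")
  class(grid) <- c("confounding_spec", "data.frame")
  grid
}

#' Draw one set of confounding-function values
#'
#' One constant value per ordered pair, uniform over the signed interval
#' scaled by `omega * sigma_hat` (constant in the covariates, matching the
#' constant-function usage of the sensitivity algorithm).
#'
#' @param spec a [confounding_spec].
#' @param sigma_hat residual SD used to scale the bounds (log months).
#' @return J x J matrix `c[aj, am]` with zero diagonal.
#' @export
draw_confounding_values <- function(spec, sigma_hat) {
  stopifnot(inherits(spec, "confounding_spec"), sigma_hat > 0)
  trt <- sort(unique(c(spec$aj, spec$am)))
  cm <- matrix(0, length(trt), length(trt), dimnames = list(trt, trt))
  for (r in seq_len(nrow(spec))) {
    w <- spec$omega[r] * sigma_hat
    lim <- switch(spec$sign[r],
                  "+" = c(0, w), "-" = c(-w, 0), "either" = c(-w, w))
    cm[spec$aj[r], spec$am[r]] <-
      spec$center[r] + stats::runif(1, lim[1], lim[2])
  }
  cm
}

#' Bias of a pairwise treatment-effect estimate under unmeasured confounding
#'
#' For a subject with generalized propensity scores `p`, the bias in the
#' estimated effect of `a_j` versus `a_j'` is
#' `-p_j c(a_j',a_j) + p_j' c(a_j,a_j')
#'  - sum_m p_m [c(a_j',a_m) - c(a_j,a_m)]` over the remaining arms m.
#'
#' @param c_values J x J confounding-value matrix (as from
#'   [draw_confounding_values]).
#' @param gps_probs numeric vector of assignment probabilities, named by
#'   treatment, summing to 1.
#' @param pair ordered pair `c(a_j, a_j')`.
#' @return the bias on the log-time scale.
#' @export
confounding_bias <- function(c_values, gps_probs, pair) {
  stopifnot(abs(sum(gps_probs) - 1) < 1e-6)
  aj <- as.character(pair[1]); ajp <- as.character(pair[2])
  others <- setdiff(names(gps_probs), c(aj, ajp))
  bias <- -gps_probs[[aj]] * c_values[ajp, aj] +
    gps_probs[[ajp]] * c_values[aj, ajp]
  for (m in others)
    bias <- bias - gps_probs[[m]] * (c_values[ajp, m] - c_values[aj, m])
  unname(bias)
}

#' Fit a generalized propensity score model
#'
#' Default: fixed-effects multinomial logistic regression of treatment on
#' covariates plus cluster indicators, with `Q1` nonparametric-bootstrap
#' refits supplying parameter uncertainty for the nested imputation loop.
#' Predicted probabilities are clipped to `[1e-6, 1 - 1e-6]` (with a
#' warning) and renormalised.
#'
#' @param data a [clustered_survival_data] object.
#' @param method `"multinomial"` (the built-in fixed-effects multinomial
#'   logistic model).
#' @param Q1 number of parameter draws (bootstrap refits).
#' @param verbose print bootstrap progress.
#' @return object of class `gps_model`: list with `probs` (list of Q1
#'   n x J probability matrices on the original data), `mle` (the point-fit
#'   probabilities) and `method`.
#' @export
fit_gps <- function(data, method = "multinomial", Q1 = 30, verbose = FALSE) {
  stopifnot(inherits(data, "clustered_survival_data"), Q1 >= 1)
  method <- match.arg(method, "multinomial")
  df <- data.frame(a = data$a, cl = factor(data$cluster))
  if (!is.null(data$x)) df <- cbind(df, as.data.frame(data$x))
  form <- stats::as.formula(paste("a ~", paste(setdiff(names(df), "a"),
                                               collapse = " + ")))
  fit_one <- function(d) {
    m <- nnet::multinom(form, data = d, trace = FALSE, maxit = 300,
                        MaxNWts = 5000)
    p <- stats::predict(m, newdata = df, type = "probs")
    if (is.null(dim(p))) p <- cbind(1 - p, p)  # J = 2 case
    colnames(p) <- levels(data$a)
    p
  }
  mle <- fit_one(df)
  probs <- vector("list", Q1)
  for (q in seq_len(Q1)) {
    for (try in 1:50) {
      idx <- sample.int(nrow(df), replace = TRUE)
      d <- df[idx, , drop = FALSE]
      if (nlevels(droplevels(d$a)) == nlevels(df$a) &&
          nlevels(droplevels(d$cl)) == nlevels(df$cl)) break
      if (try == 50) stop("bootstrap could not retain all arms/clusters")
    }
    probs[[q]] <- fit_one(d)
    if (verbose && q %% 10 == 0) message("GPS bootstrap draw ", q, "/", Q1)
  }
  clipped <- FALSE
  probs <- lapply(probs, function(p) {
    if (any(p < 1e-6 | p > 1 - 1e-6)) clipped <<- TRUE
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    p / rowSums(p)
  })
  if (clipped)
    warning("some propensity scores were clipped to [1e-6, 1 - 1e-6]")
  structure(list(probs = probs, mle = mle, method = method, Q1 = Q1),
            class = "gps_model")
}

#' Apply the confounding-function outcome correction
#'
#' For a subject who received `a_j`, subtracts
#' `sum_{m != j} P(A = a_m | x, v) * c(a_j, a_m)` from the observed log
#' time — the excess of the group-specific mean potential log survival over
#' its covariate-conditional average. Censoring times receive the same
#' shift so truncation thresholds move coherently; event indicators are
#' unchanged.
#'
#' @param data a [clustered_survival_data] object.
#' @param gps_probs n x J matrix of assignment probabilities (columns in
#'   treatment-level order).
#' @param c_values J x J confounding-value matrix.
#' @return a new [clustered_survival_data] with adjusted times.
#' @export
adjust_outcomes <- function(data, gps_probs, c_values) {
  stopifnot(inherits(data, "clustered_survival_data"),
            nrow(gps_probs) == data$n)
  lv <- levels(data$a)
  shift <- numeric(data$n)
  for (j in seq_along(lv)) {
    idx <- which(as.integer(data$a) == j)
    if (!length(idx)) next
    s <- 0
    for (m in seq_along(lv)) {
      if (m == j) next
      s <- s + gps_probs[idx, m] * c_values[lv[j], lv[m]]
    }
    shift[idx] <- s
  }
  out <- data
  out$y <- data$y * exp(-shift)
  out
}

#' Run the nested-multiple-imputation sensitivity analysis
#'
#' For each of `Q1` propensity-score parameter draws and `Q2`
#' confounding-function draws: adjust the outcomes, refit the
#' random-intercept BART AFT model, and collect the posterior draws of each
#' requested pairwise effect. The final estimate and equal-tailed 95%
#' interval come from the pooled draws across the Q1 x Q2 data sets; the
#' pooled variance is decomposed into within- and between-imputation
#' components.
#'
#' @param data a [clustered_survival_data] object.
#' @param spec a [confounding_spec].
#' @param Q1,Q2 imputation counts (defaults 30 and 30).
#' @param pairs list of ordered pairs to report; default: all `(a_j, a_j')`
#'   with j < j'.
#' @param sigma_hat residual SD scaling the bounds; `NULL` estimates it as
#'   the posterior mean of sigma from an unadjusted fit.
#' @param gps optional prefitted [fit_gps] model (must have `Q1` draws).
#' @param scale,t_star effect scale passed to [estimate_cate].
#' @param n_burn,n_draws,H chain settings for every inner fit (reduced
#'   defaults keep Q1 x Q2 fits tractable).
#' @param seed master seed; inner fit q1,q2 uses the deterministic child
#'   seed `(seed + 1000003*q1 + 997*q2) mod (2^31 - 1)` for its
#'   confounding-function draw, and that child seed + 1 for the model fit.
#' @param max_fail_frac abort when more than this fraction of inner fits
#'   fail (default 0.1).
#' @param verbose print progress.
#' @return object of class `sensitivity_result`: per-pair rows with pooled
#'   estimate, 95% interval, pooled/within/between variance and the failure
#'   count; the pooled draws are attached as `draws`.
#' @export
run_sensitivity <- function(data, spec, Q1 = 30, Q2 = 30, pairs = NULL,
                            sigma_hat = NULL, gps = NULL,
                            scale = "logtime", t_star = 60,
                            n_burn = 250, n_draws = 500, H = 50,
                            seed = 1, max_fail_frac = 0.1,
                            verbose = FALSE) {
  stopifnot(Q1 >= 1, Q2 >= 1)
  lv <- levels(data$a)
  if (is.null(pairs)) {
    pairs <- list()
    for (j in seq_along(lv)) for (jp in seq_along(lv))
      if (j < jp) pairs <- c(pairs, list(c(lv[j], lv[jp])))
  }
  if (is.null(sigma_hat)) {
    fit0 <- riaft_bart(data, n_burn = n_burn, n_draws = n_draws, H = H,
                       seed = child_seed(seed, 0, 0),
                       store_counterfactuals = FALSE)
    sigma_hat <- mean(fit0$draws$sigma)
  }
  if (is.null(gps)) {
    set.seed(child_seed(seed, 0, 1))
    gps <- fit_gps(data, Q1 = Q1)
  }
  if (length(gps$probs) < Q1) stop("gps model has fewer than Q1 draws")

  pooled <- stats::setNames(
    replicate(length(pairs), list(numeric(0))),
    vapply(pairs, paste, "", collapse = "|"))
  fit_means <- lapply(pairs, function(p) numeric(0))
  n_fail <- 0L
  for (q1 in seq_len(Q1)) {
    for (q2 in seq_len(Q2)) {
      cs <- child_seed(seed, q1, q2)
      set.seed(cs)
      cvals <- draw_confounding_values(spec, sigma_hat)
      adj <- adjust_outcomes(data, gps$probs[[q1]], cvals)
      res <- tryCatch({
        fit <- riaft_bart(adj, n_burn = n_burn, n_draws = n_draws, H = H,
                          seed = (cs + 1L) %% 2147483647L)
        lapply(pairs, function(p)
          estimate_cate(fit, p, scale = scale, t_star = t_star)$draws)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_fail <- n_fail + 1L
        if (n_fail > max_fail_frac * Q1 * Q2)
          stop("more than ", 100 * max_fail_frac,
               "% of sensitivity fits failed; last error: ",
               conditionMessage(res))
        next
      }
      for (i in seq_along(pairs)) {
        pooled[[i]] <- c(pooled[[i]], res[[i]])
        fit_means[[i]] <- c(fit_means[[i]], mean(res[[i]]))
      }
      if (verbose) message("sensitivity fit q1=", q1, " q2=", q2, " done")
    }
  }

  rows <- lapply(seq_along(pairs), function(i) {
    dr <- pooled[[i]]
    within <- stats::var(dr) - stats::var(fit_means[[i]]) *
      (length(fit_means[[i]]) > 1)
    data.frame(pair = paste(pairs[[i]], collapse = " vs "),
               estimate = mean(dr),
               lower = unname(stats::quantile(dr, 0.025)),
               upper = unname(stats::quantile(dr, 0.975)),
               var_pooled = stats::var(dr),
               var_between = if (length(fit_means[[i]]) > 1)
                 stats::var(fit_means[[i]]) else 0,
               var_within = within,
               n_fits = length(fit_means[[i]]))
  })
  out <- do.call(rbind, rows)
  out$scale <- scale
  attr(out, "draws") <- pooled
  attr(out, "n_fail") <- n_fail
  attr(out, "sigma_hat") <- sigma_hat
  class(out) <- c("sensitivity_result", "data.frame")
  out
}
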