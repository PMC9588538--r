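# Posterior causal inference: counterfactual prediction, conditional
# average treatment effects (overall and on-the-treated), counterfactual
# survival curves, survival probability at a horizon, and restricted mean
# survival time.

#' Counterfactual regression-function draws
#'
#' Per-draw predictions of the regression function with the treatment set to
#' `a` for every subject (log-months, centring intercept included). The
#' cluster intercepts are excluded: they cancel in pairwise log-time
#' contrasts.
#'
#' @param fit a [riaft_bart] fit.
#' @param a a treatment label.
#' @param x optional matrix of new covariate rows (training covariate
#'   dimension); requires the fit to have been run with
#'   `keep_forests = TRUE`. `NULL` (default) uses the training design.
#' @return D x n matrix of per-draw counterfactual values.
#' @export
predict_counterfactual <- function(fit, a, x = NULL) {
  stopifnot(inherits(fit, "ribart_fit"))
  j <- match(as.character(a), fit$treatments)
  if (is.na(j)) stop("unknown treatment label: ", a)
  if (is.null(x)) {
    if (is.null(fit$draws$cf))
      stop("fit was run with store_counterfactuals = FALSE")
    return(t(fit$draws$cf[, j, , drop = TRUE]))
  }
  if (is.null(fit$forests))
    stop("prediction at new covariate rows requires keep_forests = TRUE")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  J <- fit$J
  trt <- matrix(0, nrow(x), J)
  trt[, j] <- 1
  Xnew <- cbind(trt, x)
  out <- matrix(NA_real_, fit$D, nrow(x))
  for (d in seq_len(fit$D))
    out[d, ] <- predict_trees_cpp(fit$forests[[d]], Xnew) + fit$mu_hat
  out
}

# closed-form restricted mean survival time of a lognormal survival curve
# with log-time location m and scale s, up to horizon t_star
rmst_lognormal <- function(m, s, t_star) {
  z <- (log(t_star) - m) / s
  t_star * stats::pnorm(z, lower.tail = FALSE) +
    exp(m + s^2 / 2) * stats::pnorm(z - s)
}

# per-draw subject-level contrast on the requested scale
contrast_draws <- function(fit, j1, j2, idx, scale, t_star,
                           include_cluster = TRUE) {
  cf <- fit$draws$cf
  if (is.null(cf)) stop("fit was run with store_counterfactuals = FALSE")
  D <- fit$D
  out <- numeric(D)
  if (scale == "logtime") {
    dmat <- cf[idx, j1, , drop = FALSE] - cf[idx, j2, , drop = FALSE]
    return(apply(dmat, 3, mean))
  }
  b_of <- if (include_cluster) fit$cluster[idx] else NULL
  for (d in seq_len(D)) {
    boff <- if (include_cluster) fit$draws$b[b_of, d] else 0
    m1 <- cf[idx, j1, d] + boff
    m2 <- cf[idx, j2, d] + boff
    s <- fit$draws$sigma[d]
    if (scale == "surv") {
      v <- stats::pnorm((log(t_star) - m1) / s, lower.tail = FALSE) -
        stats::pnorm((log(t_star) - m2) / s, lower.tail = FALSE)
    } else {
      v <- rmst_lognormal(m1, s, t_star) - rmst_lognormal(m2, s, t_star)
    }
    out[d] <- mean(v)
  }
  out
}

make_cate_result <- function(draws, pair, scale, t_star, n_avg) {
  est <- mean(draws)
  ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
  structure(list(pair = pair, scale = scale, t_star = t_star,
                 draws = draws, estimate = est, ci = ci,
                 sd = stats::sd(draws), n_avg = n_avg),
            class = "cate_result")
}

#' @export
print.cate_result <- function(x, ...) {
  unit <- switch(x$scale, logtime = "log months",
                 surv = sprintf("survival probability at t* = %g", x$t_star),
                 rmst = sprintf("months of RMST at t* = %g", x$t_star))
  cat(sprintf("CATE(%s, %s): %.4f [%.4f, %.4f] (%s; %d draws)\n",
              x$pair[1], x$pair[2], x$estimate, x$ci[1], x$ci[2], unit,
              length(x$draws)))
  invisible(x)
}

#' Conditional average treatment effect between two arms
#'
#' For each posterior draw, averages the subject-level counterfactual
#' contrast over all subjects' covariates; the posterior mean and
#' equal-tailed 95% credible interval are computed from the D per-draw
#' averages. On the log-time scale the contrast is
#' `f_d(a_j, x) - f_d(a_j', x)` (cluster intercepts cancel); on the
#' survival-probability and RMST scales the subject's own cluster
#' intercept enters both arms of the lognormal survival curve.
#'
#' @param fit a [riaft_bart] fit.
#' @param pair ordered pair of treatment labels `c(a_j, a_j')`.
#' @param scale `"logtime"` (difference in expected log survival months,
#'   default), `"surv"` (difference in survival probability at `t_star`) or
#'   `"rmst"` (difference in restricted mean survival months at `t_star`).
#' @param t_star horizon in months for `"surv"`/`"rmst"` (default 60, the
#'   5-year horizon of most clinical relevance in the motivating setting).
#' @return object of class `cate_result` with `draws`, `estimate` and the
#'   95% `ci`.
#' @export
estimate_cate <- function(fit, pair, scale = c("logtime", "surv", "rmst"),
                          t_star = 60) {
  scale <- match.arg(scale)
  j <- match(as.character(pair), fit$treatments)
  if (anyNA(j)) stop("unknown treatment label in pair")
  draws <- contrast_draws(fit, j[1], j[2], seq_len(fit$n), scale, t_star)
  make_cate_result(draws, pair, scale, t_star, fit$n)
}

#' Conditional average treatment effect on the treated
#'
#' As [estimate_cate], but the subject-level contrasts are averaged only
#' over subjects who actually received the reference treatment `pair[1]`.
#'
#' @inheritParams estimate_cate
#' @export
estimate_catt <- function(fit, pair, scale = c("logtime", "surv", "rmst"),
                          t_star = 60) {
  scale <- match.arg(scale)
  j <- match(as.character(pair), fit$treatments)
  if (anyNA(j)) stop("unknown treatment label in pair")
  idx <- which(as.character(fit$a_obs) == as.character(pair[1]))
  if (!length(idx)) stop("reference group is empty")
  draws <- contrast_draws(fit, j[1], j[2], idx, scale, t_star)
  make_cate_result(draws, pair, scale, t_star, length(idx))
}

#' Counterfactual survival curve
#'
#' Per-draw survival probabilities `1 - Phi((log t - f_d(a, x) - b)/
#' sigma_d)` on a time grid. When `cluster` is given the posterior draws of
#' that cluster's intercept are used; otherwise the intercept is
#' marginalised by drawing a new cluster effect `N(0, alpha_d * tau2_d)`
#' per posterior draw.
#'
#' @param fit a [riaft_bart] fit.
#' @param a treatment label.
#' @param subject index of a training row (its covariates are used), or
#'   `NULL` with `x` a single new covariate row (requires
#'   `keep_forests = TRUE`).
#' @param t_grid positive, increasing time grid (months).
#' @param cluster optional cluster index 1..K.
#' @param x optional new covariate row.
#' @return list with `t_grid`, per-draw matrix `surv` (D x length(t_grid))
#'   and the posterior `mean` curve.
#' @export
survival_curve <- function(fit, a, subject = NULL, t_grid, cluster = NULL,
                           x = NULL) {
  stopifnot(all(t_grid > 0), !is.unsorted(t_grid, strictly = TRUE))
  if (is.null(subject) == is.null(x))
    stop("give exactly one of `subject` or `x`")
  j <- match(as.character(a), fit$treatments)
  if (is.na(j)) stop("unknown treatment label: ", a)
  fdr <- if (!is.null(subject)) {
    fit$draws$cf[subject, j, ]
  } else {
    drop(predict_counterfactual(fit, a, matrix(x, nrow = 1)))
  }
  b <- if (!is.null(cluster)) {
    fit$draws$b[cluster, ]
  } else {
    stats::rnorm(fit$D, 0, sqrt(fit$draws$alpha * fit$draws$tau2))
  }
  m <- fdr + b
  s <- fit$draws$sigma
  surv <- do.call(rbind, lapply(seq_len(fit$D), function(d)
    stats::pnorm((log(t_grid) - m[d]) / s[d], lower.tail = FALSE)))
  list(t_grid = t_grid, surv = surv, mean = colMeans(surv))
}

#' Restricted mean survival time by the trapezoidal rule
#'
#' Area under a survival curve from 0 to `t_star`, with `S(0) = 1`
#' prepended and the curve linearly interpolated at `t_star`.
#'
#' @param times positive, increasing time grid.
#' @param surv survival probabilities on `times`.
#' @param t_star horizon; must not exceed `max(times)`.
#' @return RMST in the time unit of `times` (months).
#' @export
rmst <- function(times, surv, t_star) {
  stopifnot(length(times) == length(surv), all(t_star > 0))
  if (t_star > max(times)) stop("t_star exceeds the time grid")
  tt <- c(0, times[times < t_star], t_star)
  ss <- c(1, surv[times < t_star], stats::approx(c(0, times), c(1, surv),
                                                 xout = t_star)$y)
  sum(diff(tt) * (utils::head(ss, -1) + ss[-1]) / 2)
}
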