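# R surface over the C++ sum-of-trees machinery: hyperparameters, the
# regularised leaf prior, backfitting sweeps, prediction and the residual
# variance update.

#' BART hyperparameters
#'
#' Bundles the sum-of-trees settings: the number of trees H, the leaf-prior
#' hyperparameter k, the leaf-prior scale xi = 4 * sigma_hat_aft, the
#' IG(nu/2, nu*lambda/2) residual-variance prior, and the branching prior
#' p(split at depth d) = base * (1+d)^(-power).
#'
#' @param H number of trees (default 200).
#' @param k leaf-prior shrinkage hyperparameter (default 2; larger k shrinks
#'   the regression function harder toward zero).
#' @param sigma_hat_aft residual scale of the intercept-only lognormal AFT
#'   fit used to centre the responses; sets `xi = 4 * sigma_hat_aft`.
#' @param nu residual-variance prior shape (default 3).
#' @param lambda residual-variance prior scale; `NULL` means "calibrate at
#'   initialisation" (see [initialize_state]).
#' @param base,power branching-prior parameters (defaults 0.95 and 2).
#' @return a list of class `bart_hyperparams`.
#' @export
bart_hyperparams <- function(H = 200, k = 2, sigma_hat_aft = 1, nu = 3,
                             lambda = NULL, base = 0.95, power = 2) {
  stopifnot(H >= 1, k > 0, sigma_hat_aft > 0, nu > 0,
            base > 0, base < 1, power > 0)
  if (!is.null(lambda)) stopifnot(lambda > 0)
  structure(list(H = as.integer(H), k = k, sigma_hat_aft = sigma_hat_aft,
                 xi = 4 * sigma_hat_aft, nu = nu, lambda = lambda,
                 base = base, power = power),
            class = "bart_hyperparams")
}

#' Standard deviation of the terminal-node prior
#'
#' The leaf values carry the prior `N(0, xi^2 / (4 H k^2))` with
#' `xi = 4 * sigma_hat_aft`, so that the induced prior on the sum of H trees
#' is `N(0, 4 sigma_hat_aft^2 / k^2)`: with the default k = 2 about 95% of
#' the prior mass on the regression function lies in
#' `[-2 sigma_hat_aft, 2 sigma_hat_aft]`.
#'
#' @param sigma_hat_aft,H,k see [bart_hyperparams].
#' @return the leaf-prior standard deviation `xi / (2 k sqrt(H))`.
#' @export
leaf_prior_sd <- function(sigma_hat_aft, H, k) {
  if (!(sigma_hat_aft > 0) || !(H >= 1) || !(k > 0))
    stop("all arguments must be positive")
  (4 * sigma_hat_aft) / (2 * k * sqrt(H))
}

#' Create a sum-of-trees forest
#'
#' All H trees start as single root nodes with zero leaf value. The object
#' has reference semantics: [update_forest()] modifies it in place (the
#' convention of the C++-backed BART samplers in this field).
#'
#' @param X numeric training design matrix (treatment indicators already
#'   appended, see [riaft_bart]).
#' @param H number of trees.
#' @param base,power branching-prior parameters.
#' @param move_probs probabilities of the grow/prune/change structural
#'   proposals (default 0.25/0.25/0.50).
#' @return an object of class `ribart_forest`.
#' @export
bart_forest <- function(X, H = 200, base = 0.95, power = 2,
                        move_probs = c(0.25, 0.25, 0.5)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(length(move_probs) == 3, abs(sum(move_probs) - 1) < 1e-8)
  obj <- new.env(parent = emptyenv())
  obj$ptr <- forest_create_cpp(X, as.integer(H), base, power,
                               move_probs[1], move_probs[2])
  obj$X <- X
  obj$H <- as.integer(H)
  obj$base <- base
  obj$power <- power
  obj$move_probs <- move_probs
  class(obj) <- "ribart_forest"
  obj
}

#' One Bayesian-backfitting sweep over all trees
#'
#' For each tree in turn: form the partial residual of `response` minus the
#' fit of all other trees, propose one structural move (grow, prune or
#' change) accepted by Metropolis-Hastings under the branching prior with
#' the integrated-likelihood ratio, then redraw every terminal-node value
#' from its conjugate normal conditional.
#'
#' @param forest a [bart_forest] object (updated in place).
#' @param response numeric vector of partial responses (for the survival
#'   model: complete-data centred log times minus the cluster intercepts).
#' @param sigma2 current residual variance (> 0).
#' @param leaf_sd leaf-prior standard deviation, see [leaf_prior_sd].
#' @return the forest, invisibly; its cached fits are refreshed.
#' @export
update_forest <- function(forest, response, sigma2, leaf_sd) {
  stopifnot(inherits(forest, "ribart_forest"))
  if (!(sigma2 > 0)) stop("sigma2 must be positive")
  forest_update_cpp(forest$ptr, as.numeric(response), sigma2, leaf_sd)
  invisible(forest)
}

#' Cached fitted values of a forest
#'
#' @param forest a [bart_forest] object.
#' @return numeric vector of per-subject fitted sums over trees.
#' @export
forest_fitted <- function(forest) {
  forest_fits_cpp(forest$ptr)
}

#' Predict from a forest
#'
#' Routes each row of `newdata` through every tree and sums the terminal
#' node values reached.
#'
#' @param object a [bart_forest] object.
#' @param newdata numeric matrix with the training design's columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.ribart_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != ncol(object$X))
    stop("newdata must have ", ncol(object$X), " columns")
  forest_predict_cpp(object$ptr, newdata)
}

#' Compact tree-structure snapshot of a forest
#'
#' One matrix per tree with columns (var, cut, left, right, mu, depth);
#' `var`/`left`/`right` are 1-based and 0 marks a terminal node. Suitable
#' for JSON checkpointing via [forest_to_json()].
#'
#' @param forest a [bart_forest] object.
#' @return list of per-tree node matrices.
#' @export
forest_trees <- function(forest) {
  forest_trees_cpp(forest$ptr)
}

#' Serialise or restore a forest as JSON
#'
#' @param forest a [bart_forest] object.
#' @return `forest_to_json`: a JSON string of the tree structures and
#'   settings. `forest_from_json`: a restored [bart_forest].
#' @export
forest_to_json <- function(forest) {
  jsonlite::toJSON(list(H = forest$H, base = forest$base,
                        power = forest$power,
                        move_probs = forest$move_probs,
                        trees = forest_trees(forest)),
                   digits = I(17))
}

#' @rdname forest_to_json
#' @param json JSON produced by [forest_to_json()].
#' @param X the training design matrix the forest was built on.
#' @export
forest_from_json <- function(json, X) {
  o <- jsonlite::fromJSON(json, simplifyMatrix = TRUE)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  trees <- lapply(o$trees, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  obj <- new.env(parent = emptyenv())
  obj$ptr <- forest_restore_cpp(X, trees, o$base, o$power,
                                o$move_probs[1], o$move_probs[2])
  obj$X <- X
  obj$H <- as.integer(o$H)
  obj$base <- o$base
  obj$power <- o$power
  obj$move_probs <- o$move_probs
  class(obj) <- "ribart_forest"
  obj
}

#' Structural summary of a forest
#'
#' @param forest a [bart_forest] object.
#' @return list with per-tree terminal-node counts and maximum depths, and
#'   proposal/acceptance counts for the grow, prune and change moves.
#' @export
forest_summary <- function(forest) {
  s <- forest_stats_cpp(forest$ptr)
  names(s$prop) <- names(s$acc) <- c("grow", "prune", "change")
  s
}

#' Gibbs update of the residual variance
#'
#' Draws from the conjugate posterior `IG((nu + n)/2, (nu*lambda +
#' sum(residuals^2))/2)` of the `IG(nu/2, nu*lambda/2)` prior under normal
#' residuals.
#'
#' @param residuals numeric vector of current residuals.
#' @param nu,lambda prior shape and scale.
#' @return one positive draw of the residual variance.
#' @export
update_sigma2 <- function(residuals, nu, lambda) {
  if (length(residuals) == 0) stop("residuals must be non-empty")
  rinvgamma(1, shape = (nu + length(residuals)) / 2,
            scale = (nu * lambda + sum(residuals^2)) / 2)
}
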