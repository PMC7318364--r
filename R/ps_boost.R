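#' Gradient boosted propensity scores with surrogate splits
#'
#' Estimates the exposure log-odds g(x) by stagewise gradient boosting of
#' the Bernoulli log-likelihood: starting from the average log-odds of
#' exposure, each stage fits a depth-limited least-squares regression tree
#' to the current residuals T - p(x) and adds it scaled by the shrinkage
#' parameter.  Missing covariate values never block fitting: a row missing
#' the primary split variable at a node is routed by the best stored
#' surrogate split (an alternative variable/threshold maximizing agreement
#' with the primary partition; only surrogates beating the
#' "go with the majority" rule are kept), falling back to the majority
#' direction.  After every stage the average absolute standardized mean
#' difference (AASM) between exposure groups is computed from the stage's
#' fitted probabilities; the returned propensity scores come from the
#' iteration minimizing the AASM.
#'
#' Depth is interaction depth in the sense of the classical boosting
#' software: each tree is grown best-first (always splitting the terminal
#' node with the largest SSE reduction) to at most \code{depth} splits, so
#' a depth-4 tree has five terminal nodes and can represent up to four-way
#' covariate interactions; no root-to-leaf path ever exceeds \code{depth}
#' splits.  Terminal node values default to the one-step Newton update for
#' the Bernoulli likelihood.  No stochastic subsampling is used, so a fit
#' is a deterministic function of the data.
#'
#' @param X covariate matrix (the balance metric uses these same columns);
#'   may contain NA.
#' @param treat binary exposure vector with both classes present.
#' @param shrinkage learning rate in (0, 1]; default 0.05.
#' @param depth maximum number of splits per tree (interaction depth);
#'   default 4.
#' @param n_trees maximum boosting iterations; default 10000.  A warning
#'   is issued when the AASM minimizer is the final iteration (the
#'   minimum may lie beyond the budget).
#' @param min_node minimum observations per terminal node; default 10.
#' @param max_surrogates surrogates stored per node; default 5.
#' @param keep_trees keep the fitted trees for later prediction
#'   (default TRUE; the simulation driver disables this for speed since it
#'   only needs training-set scores).
#' @param newton use the one-step Newton terminal-node update for the
#'   Bernoulli likelihood, sum(r) / sum(p(1-p)) over the node's rows, as
#'   the classical boosting implementations do (default TRUE);
#'   \code{FALSE} uses the plain mean-residual (least squares) update.
#' @return an object of class \code{"ps_boost"}: list with \code{ps}
#'   (training propensity scores at the AASM-minimizing iteration),
#'   \code{best_iter}, \code{aasm} (trajectory, index 1 = iteration 0),
#'   \code{g0}, \code{shrinkage}, \code{trees}.
#' @examples
#' s <- generate_sample(300, "A", seed = 1)
#' fit <- ps_boost(s$X[, 1:4], s$T, n_trees = 50)
#' fit$best_iter
#' @export
ps_boost <- function(X, treat, shrinkage = 0.05, depth = 4, n_trees = 10000,
                     min_node = 10, max_surrogates = 5, keep_trees = TRUE,
                     newton = TRUE) {
  stopifnot(shrinkage > 0, shrinkage <= 1, depth >= 1, n_trees >= 0)
  if (length(unique(treat)) < 2)
    stop("exposure has a single class; propensity model cannot be fit")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  res <- .boost_cpp(X, as.integer(treat), shrinkage, as.integer(depth),
                    as.integer(n_trees), as.integer(min_node),
                    as.integer(max_surrogates), isTRUE(keep_trees),
                    isTRUE(newton))
  if (n_trees > 0 && res$best_iter == n_trees)
    warning("AASM minimized at the final iteration; ",
            "the minimum may lie beyond n_trees = ", n_trees)
  structure(list(ps = res$ps_best, best_iter = res$best_iter,
                 aasm = res$aasm, g0 = res$g0, shrinkage = shrinkage,
                 depth = depth, n_trees = n_trees, trees = res$trees,
                 columns = colnames(X), estimator = "gbm"),
            class = "ps_boost")
}

#' @export
print.ps_boost <- function(x, ...) {
  cat(sprintf(paste0("ps_boost: %d/%d iterations (AASM-selected), ",
                     "shrinkage %.3g, depth %d\n"),
              x$best_iter, x$n_trees, x$shrinkage, x$depth))
  cat(sprintf("  AASM: %.4f at iteration 0 -> %.4f at best\n",
              x$aasm[1], x$aasm[x$best_iter + 1]))
  invisible(x)
}

#' @export
summary.ps_boost <- function(object, ...) {
  out <- list(best_iter = object$best_iter,
              aasm0 = object$aasm[1],
              aasm_best = object$aasm[object$best_iter + 1],
              ps_range = range(object$ps))
  class(out) <- "summary.ps_boost"
  out
}

#' @export
print.summary.ps_boost <- function(x, ...) {
  cat(sprintf("best iteration %d; AASM %.4f -> %.4f; ps in [%.4f, %.4f]\n",
              x$best_iter, x$aasm0, x$aasm_best,
              x$ps_range[1], x$ps_range[2]))
  invisible(x)
}

#' Predict propensity scores from a boosted model
#'
#' Inverse logit of the initial log-odds plus the shrunken sum of the
#' first \code{n_trees} trees.  Rows with missing split variables are
#' routed via the stored surrogates, else the majority direction.
#'
#' @param object a \code{ps_boost} fit with kept trees.
#' @param newdata covariate matrix with the training columns; may contain
#'   NA.
#' @param n_trees iteration at which to predict (default: the
#'   AASM-selected best iteration).
#' @param ... unused.
#' @return vector of propensity scores.
#' @export
predict.ps_boost <- function(object, newdata, n_trees = object$best_iter, ...) {
  if (length(object$trees) == 0 && n_trees > 0)
    stop("model was fitted with keep_trees = FALSE")
  if (n_trees > length(object$trees) && n_trees > 0)
    stop("n_trees exceeds the number of fitted iterations")
  newdata <- as.matrix(newdata)
  if (!is.null(object$columns) && !is.null(colnames(newdata)))
    newdata <- newdata[, object$columns, drop = FALSE]
  storage.mode(newdata) <- "double"
  .predict_boost_cpp(object$trees, object$g0, object$shrinkage,
                     as.integer(n_trees), newdata)
}

#' Plot the AASM trajectory of a boosted propensity fit
#'
#' @param x a \code{ps_boost} fit.
#' @param ... passed to \code{plot.default}.
#' @export
plot.ps_boost <- function(x, ...) {
  plot(seq_along(x$aasm) - 1L, x$aasm, type = "l",
       xlab = "boosting iteration", ylab = "AASM", ...)
  graphics::abline(v = x$best_iter, lty = 2)
  invisible(x)
}

#' Fit a single surrogate-split regression tree
#'
#' Least-squares CART grown best-first to at most \code{depth} splits,
#' with the same split search, surrogate bookkeeping and missing-value
#' routing as the boosting stages; exposed for inspection and testing.
#' Node values are mean responses (the Newton re-estimate is applied only
#' inside the boosting loop).
#'
#' @param X covariate matrix, possibly with NA.
#' @param y numeric response (residuals, in the boosting context).
#' @param depth maximum number of splits (interaction depth).
#' @param min_node minimum observations per terminal node.
#' @param max_surrogates surrogates stored per node.
#' @return an object of class \code{"reg_tree"}: parallel node vectors
#'   \code{var} (NA = terminal), \code{split}, \code{left}, \code{right},
#'   \code{value}, \code{maj_left} and a per-node \code{surrogates}
#'   matrix (var, split, reversed, agreement), plus the training
#'   \code{fitted} values as an attribute.
#' @export
fit_reg_tree <- function(X, y, depth = 4, min_node = 10, max_surrogates = 5) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  tr <- .fit_tree_cpp(X, as.numeric(y), as.integer(depth),
                      as.integer(min_node), as.integer(max_surrogates))
  tr$columns <- colnames(X)
  class(tr) <- "reg_tree"
  tr
}

#' @export
predict.reg_tree <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  .predict_tree_cpp(unclass(object), newdata)
}

#' @export
print.reg_tree <- function(x, ...) {
  n_int <- sum(!is.na(x$var))
  cat(sprintf("reg_tree: %d internal node(s), %d terminal node(s)\n",
              n_int, length(x$var) - n_int))
  invisible(x)
}

#' Average absolute standardized mean difference (AASM)
#'
#' Covariate balance metric used as the boosting stopping rule: for each
#' column of \code{X}, the absolute difference between the exposed-group
#' mean and the odds-weighted unexposed-group mean (weights
#' p/(1 - p)), divided by the exposed-group standard deviation, averaged
#' over columns.  Cells missing a covariate are dropped pairwise.
#' Columns with zero exposed-group SD are skipped with a warning.
#'
#' @param X covariate matrix (possibly with NA).
#' @param treat binary exposure vector.
#' @param ps propensity scores in (0, 1).
#' @return scalar AASM (non-negative).
#' @examples
#' compute_aasm(matrix(c(1, 3, 0, 2)), c(1, 1, 0, 0), rep(0.5, 4))
#' @export
compute_aasm <- function(X, treat, ps) {
  X <- as.matrix(X)
  stopifnot(all(ps > 0 & ps < 1), nrow(X) == length(treat),
            length(ps) == length(treat))
  w <- ps / (1 - ps)
  vals <- numeric(0)
  skipped <- character(0)
  for (j in seq_len(ncol(X))) {
    x1 <- X[treat == 1, j]
    x1 <- x1[!is.na(x1)]
    s1 <- sd(x1)
    if (length(x1) == 0 || is.na(s1) || s1 == 0) {
      skipped <- c(skipped, colnames(X)[j] %||% as.character(j))
      next
    }
    ok0 <- treat == 0 & !is.na(X[, j])
    wm0 <- sum(w[ok0] * X[ok0, j]) / sum(w[ok0])
    vals <- c(vals, abs(mean(x1) - wm0) / s1)
  }
  if (length(vals) == 0)
    stop("all covariates have zero exposed-group SD; AASM undefined")
  if (length(skipped) > 0)
    warning("AASM skipped zero-SD covariate(s): ",
            paste(skipped, collapse = ", "))
  mean(vals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a boosted propensity fit for inspection
#'
#' Writes the fitted trees as a JSON listing (node tables with split
#' variables, thresholds, surrogate lists and terminal values) and/or the
#' AASM trajectory as a delimited table with one row per iteration.
#'
#' @param object a \code{ps_boost} fit.
#' @param trees_json optional path for the JSON tree dump (requires the
#'   fit to have kept its trees).
#' @param aasm_table optional path for the AASM trajectory
#'   (columns \code{iteration}, \code{aasm}).
#' @param sep field separator for the trajectory table.
#' @return invisibly, the fit.
#' @export
export_boost <- function(object, trees_json = NULL, aasm_table = NULL,
                         sep = ",") {
  stopifnot(inherits(object, "ps_boost"))
  if (!is.null(trees_json)) {
    if (length(object$trees) == 0)
      stop("model was fitted with keep_trees = FALSE; nothing to dump")
    dump <- list(g0 = object$g0, shrinkage = object$shrinkage,
                 best_iter = object$best_iter, columns = object$columns,
                 trees = lapply(object$trees, function(tr)
                   tr[c("var", "split", "left", "right", "value",
                        "maj_left", "surrogates")]))
    jsonlite::write_json(dump, trees_json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  if (!is.null(aasm_table)) {
    utils::write.table(
      data.frame(iteration = seq_along(object$aasm) - 1L,
                 aasm = object$aasm),
      aasm_table, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(object)
}
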