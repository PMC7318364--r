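#' @name ps_logistic_module
#' @title Logistic-regression propensity scores under inclusion strategies
#' @description
#' The logistic propensity model regresses the exposure on a chosen
#' covariate set.  An analyst rarely knows the true confounders, so four
#' main-effects inclusion strategies are studied -- the true confounders
#' x1-x4, x1 left out, the non-confounder x5 added, and both -- plus the
#' fully correct specification of the non-additive scenario ("correct_G"):
#' x1-x7 with the generator's three quadratic and ten interaction terms.
NULL

.STRATEGIES <- list(
  true_confounders    = paste0("x", 1:4),
  leave_x1_out        = paste0("x", 2:4),
  add_x5              = paste0("x", 1:5),
  leave_x1_out_add_x5 = paste0("x", 2:5),
  correct_G           = paste0("x", 1:7)
)

#' Variable sets for the inclusion strategies
#' @return named list of main-effect covariate names per strategy.
#' @export
inclusion_strategies <- function() .STRATEGIES

#' Build a propensity design matrix
#'
#' Intercept plus the strategy's main effects; for \code{"correct_G"} also
#' the scenario-G quadratic and interaction columns.  A missingness
#' pattern factor, when supplied, is expanded to dummies with the largest
#' (modal) group as reference; constant columns are dropped.
#'
#' @param X completed covariate matrix with columns x1..x10.
#' @param strategy one of \code{names(inclusion_strategies())}.
#' @param pattern optional factor of pooled missingness-pattern labels.
#' @return numeric design matrix including the intercept.
#' @export
build_ps_design <- function(X, strategy = "true_confounders", pattern = NULL) {
  strategy <- match.arg(strategy, names(.STRATEGIES))
  vars <- .STRATEGIES[[strategy]]
  if (!all(vars %in% colnames(X)))
    stop("design columns absent: ",
         paste(setdiff(vars, colnames(X)), collapse = ", "))
  D <- cbind(`(Intercept)` = 1, X[, vars, drop = FALSE])
  if (strategy == "correct_G") D <- cbind(D, scenario_g_terms(X))
  if (!is.null(pattern)) {
    pattern <- droplevels(as.factor(pattern))
    if (nlevels(pattern) > 1) {
      ref <- names(which.max(table(pattern)))
      pattern <- stats::relevel(pattern, ref = ref)
      mm <- model.matrix(~pattern)[, -1, drop = FALSE]
      colnames(mm) <- paste0("mp", levels(pattern)[-1])
      D <- cbind(D, mm)
    }
  }
  keep <- apply(D, 2, function(col) stats::sd(col) > 0)
  keep[1] <- TRUE
  D[, keep, drop = FALSE]
}

#' Fit a logistic propensity model on a design matrix
#'
#' Maximum likelihood by iteratively reweighted least squares (tolerance
#' 1e-8 on the deviance change, at most 100 iterations).  Fitted
#' probabilities are clipped to [1e-6, 1 - 1e-6] so downstream inverse
#' probability weights stay finite; the number of clipped values is kept
#' as the \code{n_clipped} attribute.
#'
#' @param design numeric design matrix including an intercept column.
#' @param treat binary exposure vector with both classes present.
#' @return object of class \code{"ps_fit"}: list with \code{ps},
#'   \code{coefficients}, \code{strategy}, \code{estimator}.
#' @export
fit_logistic_ps <- function(design, treat) {
  if (length(unique(treat)) < 2)
    stop("exposure has a single class; propensity model cannot be fit")
  fit <- suppressWarnings(
    glm.fit(design, treat, family = binomial(),
            control = glm.control(epsilon = 1e-8, maxit = 100)))
  if (!fit$converged)
    stop("logistic propensity model did not converge; ",
         "inspect the design for separation or collinearity")
  if (any(abs(coef(fit)[!is.na(coef(fit))]) > 15))
    stop("diverging coefficients suggest perfect separation; inspect the design")
  ps <- fit$fitted.values
  n_clipped <- sum(ps < 1e-6 | ps > 1 - 1e-6)
  ps <- pmin(pmax(ps, 1e-6), 1 - 1e-6)
  structure(list(ps = ps, coefficients = coef(fit), strategy = NA_character_,
                 estimator = "logistic", n_clipped = n_clipped),
            class = "ps_fit")
}

#' Logistic-regression propensity scores
#'
#' Convenience wrapper: builds the design for an inclusion strategy (see
#' \code{\link{build_ps_design}}) and fits the logistic propensity model.
#'
#' @param X completed covariate matrix with columns x1..x10.
#' @param treat binary exposure vector.
#' @param strategy inclusion strategy label.
#' @param pattern optional pooled missingness-pattern factor (MIMP).
#' @return a \code{"ps_fit"} object.
#' @examples
#' s <- generate_sample(400, "A", seed = 1)
#' fit <- ps_logistic(s$X, s$T)
#' summary(fit$ps)
#' @export
ps_logistic <- function(X, treat, strategy = "true_confounders",
                        pattern = NULL) {
  D <- build_ps_design(X, strategy, pattern)
  out <- fit_logistic_ps(D, treat)
  out$strategy <- strategy
  out
}

#' @export
print.ps_fit <- function(x, ...) {
  cat(sprintf("ps_fit (%s%s): n = %d, ps in [%.4f, %.4f]\n", x$estimator,
              if (!is.na(x$strategy)) paste0(", ", x$strategy) else "",
              length(x$ps), min(x$ps), max(x$ps)))
  invisible(x)
}

#' @export
coef.ps_fit <- function(object, ...) object$coefficients
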