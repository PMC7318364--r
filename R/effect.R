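#' @name effect_module
#' @title Stabilized IPW effect estimation and Rubin's rules
#' @description
#' Propensity scores are converted to stabilized inverse probability
#' weights, winsorized at the 1st/99th weight percentiles, and used in a
#' weighted regression of the outcome on the exposure alone; for multiply
#' imputed data the per-imputation estimates are combined by Rubin's
#' rules.
NULL

#' Stabilized inverse probability weights
#'
#' Exposed subjects receive p-hat / p_i and unexposed subjects
#' (1 - p-hat) / (1 - p_i), where p-hat is the mean of the fitted
#' propensity scores.  Stabilization keeps the weights near 1 and reduces
#' variance relative to raw inverse probability weights.
#'
#' @param ps propensity scores in (0, 1).
#' @param treat binary exposure vector.
#' @return positive weight vector.
#' @examples
#' stabilized_weights(c(0.2, 0.8), c(1, 0)) # both 2.5
#' @export
stabilized_weights <- function(ps, treat) {
  stopifnot(all(ps > 0 & ps < 1), length(ps) == length(treat))
  p_hat <- mean(ps)
  ifelse(treat == 1, p_hat / ps, (1 - p_hat) / (1 - ps))
}

#' Trim (winsorize) weights at distribution percentiles
#'
#' Weights below the lower percentile are raised to it and weights above
#' the upper percentile lowered to it; percentiles are computed over the
#' pooled weight vector (both exposure groups).  No rows are dropped under
#' the default winsorization; \code{method = "drop"} instead marks
#' out-of-range weights NA so downstream estimation excludes those rows.
#'
#' @param w positive weight vector.
#' @param lower_q,upper_q trimming percentiles (defaults 0.01 and 0.99).
#' @param method "winsorize" (default) or "drop".
#' @return weight vector of the same length.
#' @export
trim_weights <- function(w, lower_q = 0.01, upper_q = 0.99,
                         method = c("winsorize", "drop")) {
  method <- match.arg(method)
  stopifnot(all(w > 0), lower_q <= upper_q)
  q <- quantile(w, c(lower_q, upper_q), names = FALSE)
  if (method == "winsorize") return(pmin(pmax(w, q[1]), q[2]))
  w[w < q[1] | w > q[2]] <- NA_real_
  w
}

#' Weighted regression of the outcome on the exposure
#'
#' Weighted least squares of Y on (1, T); the coefficient of T is the
#' causal effect estimate and its model-based WLS standard error is
#' reported.  The exposure is the only predictor: confounding control
#' comes entirely from the weights.
#'
#' @param Y outcome vector.
#' @param treat binary exposure vector.
#' @param w weights (rows with NA weight are excluded).
#' @return object of class \code{"ipw_effect"} with \code{estimate},
#'   \code{se}, \code{n_effective} (Kish effective sample size) and labels.
#' @examples
#' weighted_effect(c(0, 1, 2, 3), c(0, 0, 1, 1), rep(1, 4)) # estimate 2
#' @export
weighted_effect <- function(Y, treat, w) {
  keep <- !is.na(w)
  Y <- Y[keep]; treat <- treat[keep]; w <- w[keep]
  if (sum(w[treat == 1]) <= 0 || sum(w[treat == 0]) <= 0)
    stop("an exposure class carries zero total weight")
  fit <- lm(Y ~ treat, weights = w)
  sm <- summary(fit)$coefficients
  structure(list(estimate = unname(coef(fit)["treat"]),
                 se = unname(sm["treat", "Std. Error"]),
                 n_effective = sum(w)^2 / sum(w^2),
                 m = 1L, per_imputation = NULL,
                 method = NA_character_, strategy = NA_character_),
            class = "ipw_effect")
}

#' Combine estimates across imputations by Rubin's rules
#'
#' Point estimate: the mean of the per-imputation estimates.  Total
#' variance: the mean within-imputation variance plus (1 + 1/m) times the
#' between-imputation variance B (sample variance of the estimates,
#' divisor m - 1).  With m = 1, B is zero and the estimate and variance
#' pass through unchanged.
#'
#' @param estimates per-imputation point estimates.
#' @param variances per-imputation squared standard errors.
#' @return an \code{"ipw_effect"} object with the pooled estimate and SE.
#' @examples
#' rubin_combine(c(1, 3), c(1, 1)) # estimate 2, se 2
#' @export
rubin_combine <- function(estimates, variances) {
  m <- length(estimates)
  stopifnot(m >= 1, length(variances) == m, all(variances >= 0))
  est <- mean(estimates)
  B <- if (m > 1) var(estimates) else 0
  total <- mean(variances) + (1 + 1 / m) * B
  structure(list(estimate = est, se = sqrt(total),
                 n_effective = NA_real_, m = m,
                 per_imputation = list(estimates = estimates,
                                       variances = variances),
                 method = NA_character_, strategy = NA_character_),
            class = "ipw_effect")
}

#' Stabilized, trimmed IPW effect estimate from propensity scores
#'
#' Pipeline helper: stabilized weights, percentile winsorization, weighted
#' regression.
#'
#' @param Y outcome vector.
#' @param treat binary exposure vector.
#' @param ps propensity scores in (0, 1).
#' @param trim length-2 trimming percentiles (default c(0.01, 0.99));
#'   NULL skips trimming.
#' @param trim_method passed to \code{\link{trim_weights}}.
#' @return an \code{"ipw_effect"} object.
#' @examples
#' s <- generate_sample(400, "A", seed = 1)
#' fit <- ps_logistic(s$X, s$T)
#' ipw_effect(s$Y, s$T, fit$ps)
#' @export
ipw_effect <- function(Y, treat, ps, trim = c(0.01, 0.99),
                       trim_method = "winsorize") {
  w <- stabilized_weights(ps, treat)
  if (!is.null(trim)) w <- trim_weights(w, trim[1], trim[2], trim_method)
  weighted_effect(Y, treat, w)
}

#' @export
print.ipw_effect <- function(x, ...) {
  cat(sprintf("IPW effect estimate: %.4f (SE %.4f)%s\n", x$estimate, x$se,
              if (x$m > 1) sprintf(" [Rubin, m = %d]", x$m) else ""))
  invisible(x)
}

#' @export
coef.ipw_effect <- function(object, ...) c(treat = object$estimate)

#' @export
summary.ipw_effect <- function(object, ...) {
  ci <- object$estimate + c(-1.96, 1.96) * object$se
  cat(sprintf("estimate %.4f, SE %.4f, 95%% CI [%.4f, %.4f]\n",
              object$estimate, object$se, ci[1], ci[2]))
  if (object$m > 1)
    cat(sprintf("pooled over m = %d imputations (Rubin's rules)\n", object$m))
  invisible(object)
}
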