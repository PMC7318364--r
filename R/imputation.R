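#' @name imputation
#' @title Imputation strategies for the incomplete confounders
#'
#' @description
#' All imputers operate on a \code{ps_incomplete} object and return a
#' \code{ps_imputed} object holding m completed covariate matrices
#' (m = 1 for the single-imputation methods).  The imputation models use
#' the variables x1-x6, x8, x9, T and Y; x7 and x10 are excluded because
#' they are uncorrelated with the incomplete confounders.  Binary
#' confounders are imputed on the continuous scale and never rounded
#' (rounding inflates bias in downstream propensity models).  Observed
#' cells are never altered.
NULL

.IMPUTER_VARS <- c(paste0("x", c(1:6, 8, 9)), "T", "Y")

new_imputed <- function(completed, method, pattern = NULL) {
  structure(list(completed = completed, m = length(completed),
                 method = method, pattern = pattern,
                 imputer_variables = .IMPUTER_VARS),
            class = "ps_imputed")
}

#' @export
print.ps_imputed <- function(x, ...) {
  cat(sprintf("ps_imputed: method %s, m = %d completed dataset(s)\n",
              x$method, x$m))
  invisible(x)
}

#' Treatment mean imputation
#'
#' Every missing cell of a confounder is replaced by the unrounded mean of
#' that confounder's observed values within the subject's exposure group.
#'
#' @param incomplete a \code{ps_incomplete} object.
#' @return a \code{ps_imputed} object with m = 1.
#' @examples
#' s <- generate_sample(200, "A", seed = 1)
#' inc <- impose_mcar(s, 0.25, seed = 2)
#' imp <- impute_treatment_mean(inc)
#' @export
impute_treatment_mean <- function(incomplete) {
  X <- observed_covariates(incomplete)
  tr <- incomplete$base$T
  for (j in 1:4) {
    mis <- is.na(X[, j])
    if (!any(mis)) next
    for (t in c(0, 1)) {
      rows <- mis & tr == t
      if (!any(rows)) next
      obs <- X[!is.na(X[, j]) & tr == t, j]
      if (length(obs) == 0)
        stop(sprintf("no observed values of x%d in exposure group T=%d", j, t))
      X[rows, j] <- mean(obs)
    }
  }
  new_imputed(list(X), "TMI")
}

# One Bayesian (or noise-only) normal regression draw for the missing cells
# of the working-matrix column `ycol`, with predictors `cols` (intercept
# included).  method "norm": sigma^2 ~ SSE / chisq(n_obs - p), beta | sigma
# ~ N(beta_hat, sigma^2 (X'X)^-1); method "norm.nob": beta_hat and the
# residual variance estimate are treated as fixed.  Rank-deficient designs
# drop aliased columns with a warning.
draw_norm <- function(W, ycol, cols, obs, method) {
  y <- W[, ycol]
  # fast path: normal equations via Cholesky; falls back to a pivoted QR
  # when the cross-product is not (numerically) positive definite
  Xo <- W[obs, cols, drop = FALSE]
  R <- tryCatch(chol(crossprod(Xo)), error = function(e) NULL)
  if (!is.null(R)) {
    yo <- y[obs]
    beta <- backsolve(R, forwardsolve(R, crossprod(Xo, yo),
                                      upper.tri = TRUE, transpose = TRUE))
    res <- yo - drop(Xo %*% beta)
    sse <- sum(res^2)
    df <- nrow(Xo) - ncol(Xo)
    if (df <= 0) stop("too few observed rows to fit the imputation model")
    if (method == "norm") {
      sigma <- sqrt(sse / rchisq(1, df))
      beta <- beta + sigma * backsolve(R, rnorm(ncol(Xo)))
    } else {
      sigma <- sqrt(sse / df)
    }
    return(drop(W[!obs, cols, drop = FALSE] %*% beta) +
             sigma * rnorm(sum(!obs)))
  }
  Xd <- W[, cols, drop = FALSE]
  qr_ <- qr(Xd[obs, , drop = FALSE])
  rank <- qr_$rank
  if (rank < ncol(Xd)) {
    keep <- qr_$pivot[seq_len(rank)]
    warning("imputation design rank-deficient; dropping: ",
            paste(colnames(Xd)[-keep], collapse = ", "))
    Xd <- Xd[, keep, drop = FALSE]
    qr_ <- qr(Xd[obs, , drop = FALSE])
    rank <- qr_$rank
  }
  n_obs <- sum(obs)
  df <- n_obs - rank
  if (df <= 0) stop("too few observed rows to fit the imputation model")
  beta <- qr.coef(qr_, y[obs])
  res <- y[obs] - drop(Xd[obs, , drop = FALSE] %*% beta)
  sse <- sum(res^2)
  R <- qr.R(qr_)[seq_len(rank), seq_len(rank), drop = FALSE]
  piv <- qr_$pivot[seq_len(rank)]
  if (method == "norm") {
    sigma <- sqrt(sse / rchisq(1, df))
    bstar <- beta
    bstar[piv] <- beta[piv] + sigma * backsolve(R, rnorm(rank))
  } else {
    sigma <- if (df > 0) sqrt(sse / df) else 0
    bstar <- beta
  }
  mis <- !obs
  drop(Xd[mis, , drop = FALSE] %*% bstar) + sigma * rnorm(sum(mis))
}

#' Chained-equations (fully conditional) imputation
#'
#' Produces m completed datasets.  Each starts by filling missing cells
#' with random draws from the observed margin of its column, then cycles
#' \code{n_cycles} times through the incomplete confounders, refitting a
#' normal linear imputation model of each on the other imputer variables
#' (x1-x6, x8, x9, T, Y) and redrawing its missing cells.  With
#' \code{method = "norm"} the regression parameters are drawn from their
#' noninformative-prior posterior before prediction (prediction error +
#' parameter uncertainty); \code{"norm.nob"} adds residual noise around
#' the least-squares prediction only (prediction error).
#'
#' @param incomplete a \code{ps_incomplete} object.
#' @param m number of imputations (20 for multiple imputation, 1 for the
#'   single-imputation methods).
#' @param n_cycles sweeps of the chained-equation cycle per imputation
#'   (default 10).
#' @param method "norm" (Bayesian parameter draw) or "norm.nob" (fixed
#'   parameters).
#' @param seed optional integer seed.
#' @return a \code{ps_imputed} object.
#' @export
impute_fcs <- function(incomplete, m = 20, n_cycles = 10,
                       method = c("norm", "norm.nob"), seed = NULL) {
  method <- match.arg(method)
  stopifnot(m >= 1)
  X <- observed_covariates(incomplete)
  base <- incomplete$base
  targets <- paste0("x", 1:4)[colSums(is.na(X[, 1:4, drop = FALSE])) > 0]
  if (length(targets) == 0)
    return(new_imputed(rep(list(X), m), if (m > 1) "MI" else method))
  obs_list <- lapply(targets, function(v) !is.na(X[, v]))
  names(obs_list) <- targets
  # working matrix: intercept + the imputer variables, updated in place
  W0 <- cbind(`(Intercept)` = 1, X[, .IMPUTER_VARS[1:8], drop = FALSE],
              T = base$T, Y = base$Y)
  col_of <- setNames(seq_len(ncol(W0)), colnames(W0))
  pred_cols <- lapply(targets, function(v)
    setdiff(seq_along(col_of), col_of[[v]]))
  names(pred_cols) <- targets
  completed <- with_seed(seed, lapply(seq_len(m), function(i) {
    W <- W0
    # initialize from the observed margins
    for (v in targets) {
      mis <- !obs_list[[v]]
      W[mis, v] <- sample(X[obs_list[[v]], v], sum(mis), replace = TRUE)
    }
    for (cyc in seq_len(n_cycles)) {
      for (v in targets) {
        W[!obs_list[[v]], v] <- draw_norm(W, col_of[[v]], pred_cols[[v]],
                                          obs_list[[v]], method)
      }
    }
    out <- X
    for (v in targets) out[, v] <- W[, v]
    out
  }))
  new_imputed(completed, if (m > 1) "MI" else method)
}

#' Single imputation with prediction error (SI + PE)
#'
#' One completed dataset from the chained-equation machinery with residual
#' noise added to least-squares predictions; regression parameters are
#' treated as fixed.
#'
#' @inheritParams impute_fcs
#' @return a \code{ps_imputed} object with m = 1.
#' @export
impute_si_pe <- function(incomplete, n_cycles = 10, seed = NULL) {
  out <- impute_fcs(incomplete, m = 1, n_cycles = n_cycles,
                    method = "norm.nob", seed = seed)
  out$method <- "SI_PE"
  out
}

#' Single imputation with prediction error and parameter uncertainty
#' (SI + PE + PU)
#'
#' As \code{\link{impute_si_pe}} but each imputation model's parameters are
#' drawn from their posterior (scaled inverse chi-square for the residual
#' variance, conditional normal for the coefficients) before predicting.
#'
#' @inheritParams impute_fcs
#' @return a \code{ps_imputed} object with m = 1.
#' @export
impute_si_pe_pu <- function(incomplete, n_cycles = 10, seed = NULL) {
  out <- impute_fcs(incomplete, m = 1, n_cycles = n_cycles,
                    method = "norm", seed = seed)
  out$method <- "SI_PE_PU"
  out
}

#' Pool missingness patterns to a minimum group size
#'
#' Subjects share a pattern when the same subset of x1-x4 is missing (at
#' most 16 raw patterns).  While any group holds fewer than
#' \code{min_count} subjects and more than one group remains, the smallest
#' group is merged into the group with the nearest signature (minimum
#' Hamming distance between signature sets; ties broken toward the larger
#' group, then the lower group index).  Initial groups are ordered by
#' decreasing count, then by signature string.
#'
#' @param mask n x 4 logical matrix (TRUE = missing) over x1-x4.
#' @param min_count minimum subjects per pooled group (default 100).
#' @return list with \code{id} (integer pooled group per subject),
#'   \code{signature} (the raw per-subject pattern string) and
#'   \code{groups} (list of signature sets with counts).
#' @examples
#' mask <- matrix(c(TRUE, FALSE, FALSE, FALSE), 50, 4)
#' pool_patterns(mask, min_count = 10)$groups
#' @export
pool_patterns <- function(mask, min_count = 100) {
  stopifnot(min_count >= 1, ncol(mask) == 4)
  sig <- apply(mask * 1L, 1, paste, collapse = "")
  tab <- table(sig)
  ord <- order(-as.integer(tab), names(tab))
  groups <- lapply(names(tab)[ord], function(s) s)
  counts <- as.integer(tab)[ord]
  hamming <- function(a, b) {
    min(outer(a, b, Vectorize(function(x, y)
      sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]))))
  }
  while (length(groups) > 1 && min(counts) < min_count) {
    g <- which.min(counts) # first minimal = lowest index among ties
    others <- setdiff(seq_along(groups), g)
    d <- vapply(others, function(o) hamming(groups[[g]], groups[[o]]), numeric(1))
    # nearest signature; ties -> larger count, then lower group index
    best <- others[order(d, -counts[others], others)][1]
    groups[[best]] <- c(groups[[best]], groups[[g]])
    counts[best] <- counts[best] + counts[g]
    groups[[g]] <- NULL
    counts <- counts[-g]
  }
  id <- integer(length(sig))
  for (k in seq_along(groups)) id[sig %in% groups[[k]]] <- k
  list(id = id, signature = sig,
       groups = lapply(seq_along(groups),
                       function(k) list(signatures = groups[[k]],
                                        count = counts[k])))
}

#' Multiple imputation with a pooled missingness pattern indicator (MIMP)
#'
#' Chained-equations multiple imputation plus a per-subject pooled
#' missingness-pattern label, to be entered in the propensity score model
#' as categorical dummies.  The pattern depends only on the mask, so the
#' indicator is identical across the m imputations.
#'
#' @inheritParams impute_fcs
#' @param min_count minimum subjects per pooled pattern group (default 100).
#' @return a \code{ps_imputed} object with a \code{pattern} factor.
#' @export
impute_mimp <- function(incomplete, m = 20, min_count = 100, n_cycles = 10,
                        seed = NULL) {
  out <- impute_fcs(incomplete, m = m, n_cycles = n_cycles,
                    method = "norm", seed = seed)
  pool <- pool_patterns(incomplete$mask, min_count)
  out$method <- "MIMP"
  out$pattern <- factor(pool$id)
  out
}

#' Write completed datasets as one delimited table
#'
#' Stacks the m completed covariate matrices with an imputation-index
#' column \code{.imp} (1..m), plus the exposure and outcome.
#'
#' @param imputed a \code{ps_imputed} object.
#' @param incomplete the \code{ps_incomplete} object it was built from
#'   (source of T and Y).
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return invisibly, the data frame written.
#' @export
write_imputations <- function(imputed, incomplete, path, sep = ",") {
  stopifnot(inherits(imputed, "ps_imputed"),
            inherits(incomplete, "ps_incomplete"))
  base <- incomplete$base
  df <- do.call(rbind, lapply(seq_len(imputed$m), function(i)
    data.frame(.imp = i, imputed$completed[[i]], T = base$T, Y = base$Y,
               check.names = FALSE)))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}
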