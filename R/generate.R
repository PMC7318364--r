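#' @name generate
#' @title Synthetic data generation: covariates, exposure, outcome
#'
#' @description
#' The generator emulates an observational study with ten baseline
#' covariates, a binary exposure and a continuous outcome.  Six covariates
#' are Bernoulli (x1, x6, x8 with success probability 0.3; x3, x5, x9 with
#' 0.5) and four are standard normal (x2, x4, x7, x10).  x1-x4 are true
#' confounders (they enter both the exposure and the outcome model);
#' x5-x7 predict only the exposure and x8-x10 only the outcome.  Four
#' covariate pairs are correlated on the latent normal scale.
#'
#' Correlations for mixed binary/continuous pairs are interpreted on the
#' LATENT scale: a Pearson correlation of 0.9 between a Bernoulli(0.3) and
#' an N(0,1) variable is unattainable (the point-biserial maximum is about
#' 0.76), so the ten covariates are derived from one multivariate normal
#' draw whose correlation matrix carries the stated pairwise values, with
#' binary coordinates dichotomized at the quantile giving the configured
#' success probability.
NULL

.BINARY_PROBS <- c(x1 = 0.3, x3 = 0.5, x5 = 0.5, x6 = 0.3, x8 = 0.3, x9 = 0.5)
.TRUE_EFFECT <- -0.4

# default latent correlation pairing: the auxiliaries x5, x6, x8, x9 are
# correlated with the confounders x1, x2, x3, x4 respectively.  The
# "literal" alternative pairs x3 with x7 and x4 with x8 instead.
.CORR_PAIRS <- list(
  auxiliary = cbind(i = c(1, 2, 3, 4), j = c(5, 6, 8, 9),
                    rho = c(0.2, 0.9, 0.2, 0.9)),
  literal   = cbind(i = c(1, 2, 3, 4), j = c(5, 6, 7, 8),
                    rho = c(0.2, 0.9, 0.2, 0.9))
)

#' Generate the covariate matrix
#'
#' Draws n rows of the ten covariates x1..x10 from a latent multivariate
#' normal with the configured pairwise correlations, dichotomizing the six
#' binary coordinates at the normal quantile that yields the configured
#' success probabilities.
#'
#' @param n sample size (a non-negative integer; n = 0 yields an empty
#'   matrix with ten columns).
#' @param seed optional integer seed for the draw.
#' @param corr_pairs a 3-column matrix (i, j, rho) of latent pairwise
#'   correlations, or one of the named presets \code{"auxiliary"}
#'   (default: x1-x5, x2-x6, x3-x8, x4-x9) or \code{"literal"}
#'   (x1-x5, x2-x6, x3-x7, x4-x8).
#' @param binary_probs named numeric vector of success probabilities for
#'   the six binary covariates.
#' @return an n x 10 numeric matrix with columns x1..x10.
#' @examples
#' X <- generate_covariates(100, seed = 1)
#' colMeans(X[, c("x1", "x3")])
#' @export
generate_covariates <- function(n, seed = NULL, corr_pairs = "auxiliary",
                                binary_probs = .BINARY_PROBS) {
  stopifnot(length(n) == 1L, n >= 0)
  if (is.character(corr_pairs)) {
    corr_pairs <- .CORR_PAIRS[[match.arg(corr_pairs, names(.CORR_PAIRS))]]
  }
  sigma <- diag(10)
  for (k in seq_len(nrow(corr_pairs))) {
    i <- corr_pairs[k, 1]; j <- corr_pairs[k, 2]
    sigma[i, j] <- sigma[j, i] <- corr_pairs[k, 3]
  }
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("latent correlation matrix is not positive definite", call. = FALSE))
  X <- with_seed(seed, {
    Z <- matrix(rnorm(n * 10), nrow = n, ncol = 10) %*% ch
    Z
  })
  for (nm in names(binary_probs)) {
    j <- as.integer(sub("x", "", nm))
    X[, j] <- as.numeric(X[, j] > qnorm(1 - binary_probs[[nm]]))
  }
  colnames(X) <- paste0("x", 1:10)
  X
}

#' Exposure model coefficients for a scenario
#'
#' Scenario "A" is a main-effects-only logistic model on x1..x7; scenario
#' "G" adds three quadratic terms and ten two-way interactions (moderate
#' non-additivity and non-linearity).  The intercept is zero in both.
#'
#' @param scenario "A" or "G".
#' @return a list with components \code{scenario}, \code{main} (named
#'   coefficients on x1..x7), \code{quadratic} and \code{interaction}
#'   (empty for scenario A).
#' @export
exposure_model <- function(scenario = c("A", "G")) {
  scenario <- match.arg(scenario)
  main <- c(x1 = 0.8, x2 = -0.25, x3 = 0.6, x4 = -0.4,
            x5 = -0.8, x6 = -0.5, x7 = 0.7)
  quad <- inter <- numeric(0)
  if (scenario == "G") {
    quad <- c(x2 = -0.25, x4 = -0.4, x7 = 0.7)
    inter <- c("x1:x3" = 0.4, "x2:x4" = -0.175, "x3:x5" = 0.3,
               "x4:x6" = -0.28, "x5:x7" = -0.4, "x1:x6" = 0.4,
               "x2:x3" = -0.175, "x3:x4" = 0.3, "x4:x5" = -0.2,
               "x5:x6" = -0.4)
  }
  list(scenario = scenario, main = main, quadratic = quad, interaction = inter)
}

# columns for the scenario-G quadratic and interaction terms, in the order
# of exposure_model("G"); used both by the generator and by the "correct G"
# propensity design
scenario_g_terms <- function(X) {
  mod <- exposure_model("G")
  qn <- names(mod$quadratic)
  out <- matrix(0, nrow(X), length(qn) + length(mod$interaction))
  colnames(out) <- c(paste0("I(", qn, "^2)"), names(mod$interaction))
  for (k in seq_along(qn)) out[, k] <- X[, qn[k]]^2
  for (k in seq_along(mod$interaction)) {
    vars <- strsplit(names(mod$interaction)[k], ":")[[1]]
    out[, length(qn) + k] <- X[, vars[1]] * X[, vars[2]]
  }
  out
}

# linear predictor of the true exposure model
exposure_logit <- function(X, model) {
  lp <- drop(X[, names(model$main), drop = FALSE] %*% model$main)
  if (length(model$quadratic)) {
    for (nm in names(model$quadratic))
      lp <- lp + model$quadratic[[nm]] * X[, nm]^2
    for (nm in names(model$interaction)) {
      vars <- strsplit(nm, ":")[[1]]
      lp <- lp + model$interaction[[nm]] * X[, vars[1]] * X[, vars[2]]
    }
  }
  unname(lp)
}

#' Assign the binary exposure from the true propensity model
#'
#' Computes the true propensity score as the inverse logit of the scenario
#' linear predictor and draws the exposure independently per subject.
#'
#' @param X covariate matrix with columns x1..x10.
#' @param model an \code{\link{exposure_model}} (or a scenario label).
#' @param seed optional integer seed for the Bernoulli draws.
#' @return list with components \code{T} (0/1 vector) and \code{true_ps}.
#' @examples
#' X <- generate_covariates(50, seed = 2)
#' e <- assign_exposure(X, "A", seed = 3)
#' range(e$true_ps)
#' @export
assign_exposure <- function(X, model = "A", seed = NULL) {
  if (is.character(model)) model <- exposure_model(model)
  stopifnot(ncol(X) == 10)
  ps <- plogis(exposure_logit(X, model))
  T <- with_seed(seed, rbinom(nrow(X), 1L, ps))
  list(T = T, true_ps = ps)
}

#' Generate the continuous outcome
#'
#' Y = -3.85 + 0.3 x1 - 0.36 x2 - 0.73 x3 - 0.2 x4 + 0.71 x8 - 0.19 x9
#'     + 0.26 x10 - 0.4 T + e,  e ~ N(0, noise_sd^2).
#'
#' The coefficient on T (-0.4) is the true causal effect targeted by every
#' estimator in the package.  \code{noise_sd = 0} suppresses the noise,
#' which makes the outcome a deterministic function of (X, T) for testing.
#'
#' @param X covariate matrix with columns x1..x10.
#' @param T binary exposure vector.
#' @param seed optional integer seed for the noise draw.
#' @param noise_sd standard deviation of the error term (default 1).
#' @return numeric outcome vector.
#' @export
generate_outcome <- function(X, T, seed = NULL, noise_sd = 1) {
  stopifnot(nrow(X) == length(T))
  b <- c(x1 = 0.3, x2 = -0.36, x3 = -0.73, x4 = -0.2,
         x8 = 0.71, x9 = -0.19, x10 = 0.26)
  mu <- -3.85 + drop(X[, names(b), drop = FALSE] %*% b) + .TRUE_EFFECT * T
  if (noise_sd == 0) return(mu)
  mu + with_seed(seed, rnorm(length(T), 0, noise_sd))
}

#' Generate a complete sample (covariates, exposure, outcome)
#'
#' One call produces everything a replication needs: the covariate matrix,
#' the exposure with its true propensity scores, and the outcome.  The
#' exposure and noise draws use one stream derived from \code{seed}, so a
#' fixed seed reproduces the sample exactly.
#'
#' @param n sample size.
#' @param scenario exposure scenario, "A" (main effects) or "G"
#'   (quadratics + interactions).
#' @param seed optional integer seed.
#' @param corr_pairs passed to \code{\link{generate_covariates}}.
#' @return an object of class \code{"ps_sample"}: a list with \code{X},
#'   \code{T}, \code{Y}, \code{true_ps}, \code{true_effect} (-0.4) and
#'   \code{scenario}.
#' @examples
#' s <- generate_sample(200, "A", seed = 1)
#' mean(s$T)
#' @export
generate_sample <- function(n, scenario = c("A", "G"), seed = NULL,
                            corr_pairs = "auxiliary") {
  scenario <- match.arg(scenario)
  with_seed(seed, {
    X <- generate_covariates(n, corr_pairs = corr_pairs)
    e <- assign_exposure(X, scenario)
    Y <- generate_outcome(X, e$T)
    structure(list(X = X, T = e$T, Y = Y, true_ps = e$true_ps,
                   true_effect = .TRUE_EFFECT, scenario = scenario),
              class = "ps_sample")
  })
}

#' @export
print.ps_sample <- function(x, ...) {
  cat(sprintf("ps_sample: n = %d, scenario %s, exposed %.1f%%\n",
              nrow(x$X), x$scenario, 100 * mean(x$T)))
  invisible(x)
}

#' Write a sample (and optional missingness mask) as a delimited table
#'
#' Emits columns x1..x10, T, Y and, when a mask is attached, the mask
#' columns m1..m4 (1 = missing).  Intended for fixtures consumed by
#' downstream tools; values are written unrounded.
#'
#' @param sample a \code{ps_sample} or \code{ps_incomplete} object.
#' @param path output file path.
#' @param sep field separator (default comma).
#' @return invisibly, the data frame written.
#' @export
write_sample <- function(sample, path, sep = ",") {
  base <- if (inherits(sample, "ps_incomplete")) sample$base else sample
  df <- data.frame(base$X, T = base$T, Y = base$Y, check.names = FALSE)
  if (inherits(sample, "ps_incomplete")) {
    m <- sample$mask
    colnames(m) <- paste0("m", 1:4)
    df <- cbind(df, as.data.frame(m * 1L))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(df)
}
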