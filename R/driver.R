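#' @name sim_driver
#' @title Replicated simulation driver
#' @description
#' A simulation \emph{cell} is one condition: exposure scenario, missingness
#' mechanism and overall rate, sample size, missingness-handling method and
#' propensity-model inclusion strategy.  The driver runs R replications per
#' cell -- generate a complete sample, impose missingness, impute, estimate
#' propensity scores, weight/trim/regress, and (for multiple imputation)
#' combine by Rubin's rules -- and aggregates bias, SD of the estimates,
#' mean model SE, and RMSE about the true effect.
#'
#' Replication seeds derive from (master seed, condition key, replication
#' index).  The complete-sample stream depends only on (scenario, n,
#' replication) and the mask stream only on (scenario, n, mechanism, rate,
#' replication), so every method within a condition analyses the identical
#' data -- a paired comparison minimizing between-method Monte-Carlo noise
#' -- and complete-data baselines are shared across mechanism blocks.
NULL

.METHODS <- c("complete", "comGBM", "TMI", "SI_PE", "SI_PE_PU",
              "MI", "MIMP", "GBM", "GBM_SI_PE")
.GBM_METHODS <- c("comGBM", "GBM", "GBM_SI_PE")

.default_boost <- function() {
  list(shrinkage = 0.05, depth = 4, n_trees = 2000, min_node = 10,
       max_surrogates = 5, newton = TRUE)
}

#' Specify one simulation cell
#'
#' @param scenario exposure scenario, "A" or "G".
#' @param mechanism "none", "MCAR", "MAR1", "MAR2" or "MARSINISTER";
#'   "none" is only valid for the complete-data baselines.
#' @param overall_rate overall missingness rate, 0.25 or 0.5.
#' @param n sample size per replication.
#' @param method missingness-handling / estimation method: one of
#'   "complete", "comGBM" (logistic / boosted trees on the data before
#'   missingness), "TMI", "SI_PE", "SI_PE_PU", "MI", "MIMP" (imputation +
#'   logistic), "GBM" (boosted trees directly on the incomplete data via
#'   surrogate splits) or "GBM_SI_PE" (boosted trees after SI + PE).
#' @param strategy propensity-model inclusion strategy (see
#'   \code{\link{inclusion_strategies}}); boosted-tree methods always use
#'   the true confounders.
#' @param reps number of replications.
#' @param m imputations for MI/MIMP (default 20).
#' @param n_cycles chained-equation sweeps (default 10).
#' @param min_count minimum pooled-pattern size for MIMP (default 100).
#' @param boost list of boosted-tree settings overriding the defaults
#'   (shrinkage 0.05, depth 4, n_trees 2000, min_node 10, max_surrogates 5).
#' @param trim weight-trimming percentiles (default c(0.01, 0.99)).
#' @param true_effect true exposure effect (default -0.4).
#' @param corr_pairs latent correlation preset for the generator.
#' @return a validated list of class \code{"cell_spec"}.
#' @export
cell_spec <- function(scenario = "A", mechanism = "MCAR", overall_rate = 0.25,
                      n = 500, method = "complete",
                      strategy = "true_confounders", reps = 1000,
                      m = 20, n_cycles = 10, min_count = 100,
                      boost = list(), trim = c(0.01, 0.99),
                      true_effect = -0.4, corr_pairs = "auxiliary") {
  scenario <- match.arg(scenario, c("A", "G"))
  if (identical(method, "GBM_incomplete")) method <- "GBM"
  method <- match.arg(method, .METHODS)
  mechanism <- toupper(mechanism)
  mechanism <- match.arg(mechanism,
                         c("NONE", "MCAR", "MAR1", "MAR2", "MARSINISTER"))
  strategy <- match.arg(strategy, names(inclusion_strategies()))
  if ((mechanism == "NONE") != (method %in% c("complete", "comGBM")))
    stop("mechanism 'none' is used exactly for the complete-data baselines")
  if (method %in% .GBM_METHODS && strategy != "true_confounders")
    stop("boosted-tree methods are run with the true-confounder set only")
  if (strategy == "correct_G" &&
      (scenario != "G" || method %in% .GBM_METHODS))
    stop("the correct_G strategy applies to logistic methods in scenario G")
  if (mechanism != "NONE" && !overall_rate %in% c(0.25, 0.5))
    stop("overall_rate must be 0.25 or 0.5")
  structure(list(scenario = scenario, mechanism = mechanism,
                 overall_rate = overall_rate, n = as.integer(n),
                 method = method, strategy = strategy,
                 reps = as.integer(reps), m = as.integer(m),
                 n_cycles = as.integer(n_cycles),
                 min_count = as.integer(min_count),
                 boost = modifyList(.default_boost(), boost),
                 trim = trim, true_effect = true_effect,
                 corr_pairs = corr_pairs),
            class = "cell_spec")
}

cell_key <- function(spec, what = c("data", "mask", "method")) {
  what <- match.arg(what)
  switch(what,
    data = sprintf("data/%s/%d/%s", spec$scenario, spec$n, spec$corr_pairs),
    mask = sprintf("mask/%s/%d/%s/%s/%g", spec$scenario, spec$n,
                   spec$corr_pairs, spec$mechanism, spec$overall_rate),
    method = sprintf("method/%s/%d/%s/%s/%g/%s/%s", spec$scenario, spec$n,
                     spec$corr_pairs, spec$mechanism, spec$overall_rate,
                     spec$method, spec$strategy))
}

# logistic pipeline on one completed covariate matrix
logistic_estimate <- function(X, sample, spec, pattern = NULL) {
  fit <- ps_logistic(X, sample$T, spec$strategy, pattern)
  ipw_effect(sample$Y, sample$T, fit$ps, trim = spec$trim)
}

boost_estimate <- function(X, sample, spec) {
  b <- spec$boost
  fit <- ps_boost(X[, inclusion_strategies()$true_confounders, drop = FALSE],
                  sample$T, shrinkage = b$shrinkage, depth = b$depth,
                  n_trees = b$n_trees, min_node = b$min_node,
                  max_surrogates = b$max_surrogates, keep_trees = FALSE,
                  newton = b$newton)
  ipw_effect(sample$Y, sample$T, fit$ps, trim = spec$trim)
}

#' Run one end-to-end replication of a cell
#'
#' Deterministic given (master_seed, rep_index): generates the complete
#' sample, imposes missingness, applies the cell's method and returns the
#' effect estimate.
#'
#' @param spec a \code{\link{cell_spec}}.
#' @param rep_index replication counter (1-based).
#' @param master_seed study master seed.
#' @return an \code{"ipw_effect"} object.
#' @export
run_replication <- function(spec, rep_index, master_seed = 1L) {
  s <- generate_sample(spec$n, spec$scenario,
                       seed = derive_seed(master_seed, cell_key(spec, "data"),
                                          rep_index),
                       corr_pairs = spec$corr_pairs)
  inc <- NULL
  if (spec$mechanism != "NONE") {
    inc <- impose_missingness(s, spec$mechanism, spec$overall_rate,
                              seed = derive_seed(master_seed,
                                                 cell_key(spec, "mask"),
                                                 rep_index))
  }
  mseed <- derive_seed(master_seed, cell_key(spec, "method"), rep_index)
  suppressWarnings(est <- switch(spec$method,
    complete = logistic_estimate(s$X, s, spec),
    comGBM = boost_estimate(s$X, s, spec),
    TMI = logistic_estimate(impute_treatment_mean(inc)$completed[[1]], s, spec),
    SI_PE = logistic_estimate(
      impute_si_pe(inc, spec$n_cycles, seed = mseed)$completed[[1]], s, spec),
    SI_PE_PU = logistic_estimate(
      impute_si_pe_pu(inc, spec$n_cycles, seed = mseed)$completed[[1]],
      s, spec),
    MI = {
      imp <- impute_fcs(inc, m = spec$m, n_cycles = spec$n_cycles,
                        method = "norm", seed = mseed)
      fits <- lapply(imp$completed, logistic_estimate, sample = s, spec = spec)
      rubin_combine(vapply(fits, `[[`, numeric(1), "estimate"),
                    vapply(fits, `[[`, numeric(1), "se")^2)
    },
    MIMP = {
      imp <- impute_mimp(inc, m = spec$m, min_count = spec$min_count,
                         n_cycles = spec$n_cycles, seed = mseed)
      fits <- lapply(imp$completed, logistic_estimate, sample = s,
                     spec = spec, pattern = imp$pattern)
      rubin_combine(vapply(fits, `[[`, numeric(1), "estimate"),
                    vapply(fits, `[[`, numeric(1), "se")^2)
    },
    GBM = boost_estimate(observed_covariates(inc), s, spec),
    GBM_SI_PE = boost_estimate(
      impute_si_pe(inc, spec$n_cycles, seed = mseed)$completed[[1]], s, spec)
  ))
  est$method <- spec$method
  est$strategy <- spec$strategy
  est
}

#' Run all replications of a cell and aggregate
#'
#' Aggregation follows the standard Monte-Carlo summaries: bias = mean
#' estimate minus the true effect; SD = sample standard deviation of the
#' estimates; SE = mean of the per-replication model standard errors;
#' RMSE = root mean squared deviation of the estimates from the true
#' effect.  Failed replications are excluded (with the completed count
#' adjusted) and counted; a cell with more than 10% failures is flagged
#' invalid.
#'
#' @param spec a \code{\link{cell_spec}}.
#' @param master_seed study master seed.
#' @param progress print a progress message every \code{progress}
#'   replications (0 = silent).
#' @return object of class \code{"sim_cell"}: the condition echo plus
#'   \code{bias}, \code{sd}, \code{mean_se}, \code{rmse},
#'   \code{reps_completed}, \code{failures}, \code{valid} and the raw
#'   \code{estimates}/\code{ses}.
#' @export
run_cell <- function(spec, master_seed = 1L, progress = 0) {
  stopifnot(spec$reps >= 2)
  est <- se <- rep(NA_real_, spec$reps)
  errors <- character(0)
  for (r in seq_len(spec$reps)) {
    out <- tryCatch(run_replication(spec, r, master_seed),
                    error = function(e) e)
    if (inherits(out, "error")) {
      errors <- c(errors, sprintf("rep %d: %s", r, conditionMessage(out)))
    } else {
      est[r] <- out$estimate
      se[r] <- out$se
    }
    if (progress > 0 && r %% progress == 0)
      message(sprintf("  %s/%s %s: %d/%d", spec$mechanism, spec$method,
                      spec$strategy, r, spec$reps))
  }
  ok <- !is.na(est)
  R <- sum(ok)
  if (R < 2) stop("fewer than 2 replications completed")
  agg <- aggregate_estimates(est[ok], se[ok], spec$true_effect)
  structure(c(unclass(spec)[c("scenario", "mechanism", "overall_rate", "n",
                              "method", "strategy")],
              agg,
              list(reps_completed = R, failures = spec$reps - R,
                   valid = (spec$reps - R) <= 0.1 * spec$reps,
                   errors = errors, estimates = est[ok], ses = se[ok])),
            class = "sim_cell")
}

#' Aggregate replication estimates into bias, SD, SE and RMSE
#'
#' @param estimates vector of effect estimates across replications.
#' @param ses vector of per-replication model standard errors.
#' @param true_effect the true effect (default -0.4).
#' @return list with \code{bias}, \code{sd}, \code{mean_se}, \code{rmse}.
#' @export
aggregate_estimates <- function(estimates, ses, true_effect = -0.4) {
  list(bias = mean(estimates) - true_effect,
       sd = sd(estimates),
       mean_se = mean(ses),
       rmse = sqrt(mean((estimates - true_effect)^2)))
}

#' @export
print.sim_cell <- function(x, ...) {
  cat(sprintf("%s | %s %s | %s | %s | n=%d | R=%d\n", x$scenario,
              x$mechanism, if (x$mechanism == "NONE") "" else
                sprintf("(%.0f%%)", 100 * x$overall_rate),
              x$method, x$strategy, x$n, x$reps_completed))
  cat(sprintf("  bias %.4f (SD %.4f)  SE %.4f  RMSE %.4f%s\n",
              x$bias, x$sd, x$mean_se, x$rmse,
              if (!x$valid) "  [INVALID: >10% failures]" else ""))
  invisible(x)
}

.CONFIG_KEYS <- c("master_seed", "reps", "defaults", "cells", "output")
.CELL_KEYS <- c("scenario", "mechanism", "overall_rate", "n", "method",
                "strategy", "reps", "m", "n_cycles", "min_count", "boost",
                "trim", "true_effect", "corr_pairs")

#' Run a study from a configuration
#'
#' The configuration is a YAML file (or an equivalent list) with keys
#' \code{master_seed}, \code{reps}, optional \code{defaults} (cell fields
#' applied to every cell) and \code{cells}, a list of cell field maps.
#' Unknown keys abort with a message listing them.  Results are returned
#' as a data frame with one row per cell and, when \code{out_dir} is
#' given, written to \code{results.csv} (plus \code{failures.log} if any
#' replication failed).
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @param out_dir optional output directory.
#' @param master_seed overrides the configured master seed.
#' @param reps overrides the configured replication count.
#' @param progress passed to \code{\link{run_cell}}.
#' @return data frame of cell results (zero rows for an empty cell list).
#' @export
run_study <- function(config, out_dir = NULL, master_seed = NULL,
                      reps = NULL, progress = 0) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  bad <- setdiff(names(config), .CONFIG_KEYS)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  defaults <- config$defaults %||% list()
  bad <- setdiff(names(defaults), .CELL_KEYS)
  if (length(bad)) stop("unknown default keys: ", paste(bad, collapse = ", "))
  master_seed <- master_seed %||% config$master_seed %||% 1L
  cols <- c("scenario", "mechanism", "overall_rate", "n", "method",
            "strategy", "bias", "sd", "mean_se", "rmse",
            "reps_completed", "failures", "valid")
  rows <- list()
  logs <- character(0)
  for (cl in config$cells %||% list()) {
    bad <- setdiff(names(cl), .CELL_KEYS)
    if (length(bad)) stop("unknown cell keys: ", paste(bad, collapse = ", "))
    args <- modifyList(defaults, cl)
    if (!is.null(reps)) args$reps <- reps
    else if (is.null(args$reps) && !is.null(config$reps))
      args$reps <- config$reps
    spec <- do.call(cell_spec, args)
    res <- run_cell(spec, master_seed, progress = progress)
    logs <- c(logs, res$errors)
    rows[[length(rows) + 1L]] <-
      as.data.frame(res[cols], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    if (length(logs))
      writeLines(logs, file.path(out_dir, "failures.log"))
  }
  out
}

#' Enumerate the cells of one results table
#'
#' The published layout for a (scenario, n, rate) block: the logistic and
#' boosted-tree complete-data baselines, then for each missingness
#' mechanism the five logistic imputation methods crossed with the four
#' main-effects inclusion strategies plus the two boosted-tree methods on
#' the true confounders.  With \code{correct_only = TRUE} the logistic
#' methods instead use the fully specified scenario-G model.
#'
#' @param scenario,n,overall_rate condition of the block.
#' @param correct_only use the correct_G strategy only (scenario G).
#' @return list of cell field maps suitable for \code{\link{run_study}}.
#' @export
table_cells <- function(scenario = "A", n = 500, overall_rate = 0.25,
                        correct_only = FALSE) {
  mechs <- c("MCAR", "MAR1", "MAR2", "MARSINISTER")
  strategies <- if (correct_only) "correct_G" else
    c("true_confounders", "leave_x1_out", "add_x5", "leave_x1_out_add_x5")
  log_methods <- c("SI_PE_PU", "SI_PE", "TMI", "MI", "MIMP")
  cells <- list()
  add <- function(...) cells[[length(cells) + 1L]] <<-
    c(list(scenario = scenario, n = n, overall_rate = overall_rate), ...)
  for (st in strategies) add(mechanism = "none", method = "complete",
                             strategy = st)
  if (!correct_only) add(mechanism = "none", method = "comGBM",
                         strategy = "true_confounders")
  for (mech in mechs) {
    for (meth in log_methods) for (st in strategies)
      add(mechanism = mech, method = meth, strategy = st)
    if (!correct_only) for (meth in c("GBM", "GBM_SI_PE"))
      add(mechanism = mech, method = meth, strategy = "true_confounders")
  }
  cells
}

#' Pivot cell results into a published-table layout
#'
#' One row per (mechanism, method); one column group per inclusion
#' strategy holding bias, SD, SE and RMSE.
#'
#' @param results data frame from \code{\link{run_study}}.
#' @param digits rounding for display (default 3).
#' @return a data frame in wide layout.
#' @export
report_table <- function(results, digits = 3) {
  if (nrow(results) == 0) return(results)
  results$row <- paste(results$mechanism, results$method, sep = "/")
  rows <- unique(results$row)
  strategies <- unique(results$strategy)
  out <- data.frame(mechanism = sub("/.*", "", rows),
                    method = sub(".*/", "", rows),
                    stringsAsFactors = FALSE)
  for (st in strategies) {
    sub_ <- results[results$strategy == st, ]
    idx <- match(rows, sub_$row)
    for (metric in c("bias", "sd", "mean_se", "rmse"))
      out[[paste(st, metric, sep = ".")]] <- round(sub_[[metric]][idx], digits)
  }
  out
}
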