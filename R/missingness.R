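#' @name missingness
#' @title Missingness mechanisms on the confounders x1-x4
#'
#' @description
#' Four mechanisms impose missingness on the true confounders x1-x4 only;
#' x5-x10, the exposure and the outcome are always fully observed.  Each
#' mechanism targets an overall missing rate of 25% or 50%:
#'
#' \itemize{
#'   \item MCAR: every cell independently missing at the overall rate.
#'   \item MAR-1: the rate for x1, x2, x3, x4 depends on the fully observed
#'     drivers x5, x6, x8, x9 respectively -- conditional rates 15%/35%
#'     (overall 25%) or 30%/70% (overall 50%) for driver = 0 / 1.  For the
#'     Bernoulli(0.3) drivers the realized marginal rate is 21%/42%; the
#'     conditional rates are taken as authoritative and not rescaled.
#'   \item MAR-2: subjects are grouped by (driver value, outcome above or
#'     below its realized sample mean) and each group carries a tabulated
#'     rate (see \code{mar2_tables}).
#'   \item MAR-sinister: subjects are randomly split into 20 groups; the
#'     within-group correlation of a (driver, partner) pair -- partner T
#'     or Y -- ranks groups, the lower half receiving 10% (or 30%) and the
#'     upper half 40% (or 70%) missingness.
#' }
NULL

.MAR1_RATES <- list(`0.25` = c(0.15, 0.35), `0.5` = c(0.30, 0.70))
.SINISTER_RATES <- list(`0.25` = c(0.10, 0.40), `0.5` = c(0.30, 0.70))
.MAR1_DRIVERS <- c(x1 = "x5", x2 = "x6", x3 = "x8", x4 = "x9")
.SINISTER_DRIVERS <- list(
  auxiliary = list(x1 = c("x5", "T"), x2 = c("x6", "T"),
                   x3 = c("x8", "Y"), x4 = c("x9", "Y")),
  literal   = list(x1 = c("x5", "T"), x2 = c("x6", "T"),
                   x3 = c("x7", "Y"), x4 = c("x8", "Y"))
)

#' Group-specific missing rates for the MAR-2 mechanism
#'
#' For each target confounder, subjects fall in one of four groups defined
#' by the driver covariate (x5, x6, x8, x9 for x1..x4) and the indicator
#' I\{Y > mean(Y)\}; groups are ordered (0,0), (0,1), (1,0), (1,1).  Each
#' group's cell-missingness probability is tabulated per overall rate.
#'
#' @param overall_rate 0.25 or 0.5.
#' @return named list (x1..x4) of length-4 rate vectors.
#' @export
mar2_tables <- function(overall_rate = 0.25) {
  r25 <- list(x1 = c(0.10, 0.20, 0.30, 0.40),
              x2 = c(0.25, 0.30, 0.20, 0.15),
              x3 = c(0.30, 0.25, 0.15, 0.20),
              x4 = c(0.15, 0.25, 0.35, 0.20))
  stopifnot(overall_rate %in% c(0.25, 0.5))
  if (overall_rate == 0.25) r25 else lapply(r25, `*`, 2)
}

new_incomplete <- function(sample, mask, mechanism) {
  stopifnot(inherits(sample, "ps_sample"),
            nrow(mask) == nrow(sample$X), ncol(mask) == 4)
  colnames(mask) <- paste0("x", 1:4)
  structure(list(base = sample, mask = mask, mechanism = mechanism),
            class = "ps_incomplete")
}

#' @export
print.ps_incomplete <- function(x, ...) {
  cat(sprintf("ps_incomplete: n = %d, mechanism %s, missing %.1f%% of x1-x4 cells\n",
              nrow(x$base$X), x$mechanism, 100 * mean(x$mask)))
  invisible(x)
}

#' Covariate matrix with missing cells set to NA
#'
#' @param incomplete a \code{ps_incomplete} object.
#' @return the n x 10 covariate matrix with NA in masked cells of x1-x4.
#' @export
observed_covariates <- function(incomplete) {
  stopifnot(inherits(incomplete, "ps_incomplete"))
  X <- incomplete$base$X
  for (j in 1:4) X[incomplete$mask[, j], j] <- NA_real_
  X
}

#' Impose MCAR missingness
#'
#' Every cell of x1-x4 is independently missing with probability
#' \code{rate}, regardless of any covariate, the exposure or the outcome.
#'
#' @param sample a \code{ps_sample}.
#' @param rate missing probability in [0, 1].
#' @param seed optional integer seed.
#' @return a \code{ps_incomplete} object.
#' @export
impose_mcar <- function(sample, rate = 0.25, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  n <- nrow(sample$X)
  mask <- with_seed(seed, matrix(runif(n * 4) < rate, n, 4))
  new_incomplete(sample, mask, "MCAR")
}

#' Impose MAR-1 missingness
#'
#' Missingness on x1, x2, x3, x4 depends on the fully observed drivers
#' x5, x6, x8, x9 respectively: conditional rates \code{rates[1]} when the
#' driver is 0 and \code{rates[2]} when it is 1.
#'
#' @param sample a \code{ps_sample}.
#' @param overall_rate 0.25 or 0.5, selecting conditional rates 15%/35%
#'   or 30%/70%.
#' @param seed optional integer seed.
#' @param rates optional length-2 override of the conditional rates.
#' @return a \code{ps_incomplete} object.
#' @export
impose_mar1 <- function(sample, overall_rate = 0.25, seed = NULL, rates = NULL) {
  if (is.null(rates)) {
    stopifnot(overall_rate %in% c(0.25, 0.5))
    rates <- .MAR1_RATES[[as.character(overall_rate)]]
  }
  n <- nrow(sample$X)
  mask <- with_seed(seed, {
    m <- matrix(FALSE, n, 4)
    for (k in 1:4) {
      d <- sample$X[, .MAR1_DRIVERS[[k]]]
      p <- ifelse(d == 1, rates[2], rates[1])
      m[, k] <- runif(n) < p
    }
    m
  })
  new_incomplete(sample, mask, "MAR1")
}

#' Impose MAR-2 missingness
#'
#' Subjects are divided into four groups by the driver covariate and the
#' indicator I\{Y > mean(Y)\} (the realized sample mean, recomputed per
#' call); cells go missing independently at the group's tabulated rate.
#'
#' @param sample a \code{ps_sample}.
#' @param overall_rate 0.25 or 0.5.
#' @param seed optional integer seed.
#' @param tables optional override of \code{\link{mar2_tables}} output.
#' @return a \code{ps_incomplete} object.
#' @export
impose_mar2 <- function(sample, overall_rate = 0.25, seed = NULL, tables = NULL) {
  if (is.null(tables)) tables <- mar2_tables(overall_rate)
  n <- nrow(sample$X)
  hi <- as.integer(sample$Y > mean(sample$Y))
  mask <- with_seed(seed, {
    m <- matrix(FALSE, n, 4)
    for (k in 1:4) {
      d <- sample$X[, .MAR1_DRIVERS[[k]]]
      grp <- 1L + hi + 2L * as.integer(d) # (0,0)=1,(0,1)=2,(1,0)=3,(1,1)=4
      rk <- tables[[paste0("x", k)]]
      if (length(rk) != 4 || anyNA(rk)) stop("MAR-2 table incomplete for x", k)
      m[, k] <- runif(n) < rk[grp]
    }
    m
  })
  new_incomplete(sample, mask, "MAR2")
}

#' Impose MAR-sinister missingness
#'
#' Subjects are randomly partitioned into \code{n_groups} equal-as-possible
#' groups.  For each target confounder, the Pearson correlation between its
#' driver and partner variable (T or Y) is computed within each group;
#' groups are ranked (stable sort by correlation, then group index; a group
#' with zero variance counts as correlation 0) and the lower half receives
#' the low missing rate, the upper half the high rate.
#'
#' @param sample a \code{ps_sample}.
#' @param overall_rate 0.25 (rates 10%/40%) or 0.5 (rates 30%/70%).
#' @param seed optional integer seed.
#' @param drivers \code{"auxiliary"} (default: x5-T, x6-T, x8-Y, x9-Y) or
#'   \code{"literal"} (x5-T, x6-T, x7-Y, x8-Y).
#' @param n_groups number of random groups (default 20; n must be at least
#'   2 per group).
#' @param rates optional length-2 (low, high) override.
#' @return a \code{ps_incomplete} object.
#' @export
impose_mar_sinister <- function(sample, overall_rate = 0.25, seed = NULL,
                                drivers = "auxiliary", n_groups = 20L,
                                rates = NULL) {
  if (is.null(rates)) {
    stopifnot(overall_rate %in% c(0.25, 0.5))
    rates <- .SINISTER_RATES[[as.character(overall_rate)]]
  }
  if (is.character(drivers))
    drivers <- .SINISTER_DRIVERS[[match.arg(drivers, names(.SINISTER_DRIVERS))]]
  n <- nrow(sample$X)
  if (n < 2L * n_groups)
    stop("MAR-sinister needs at least 2 observations per group")
  vars <- cbind(sample$X, T = sample$T, Y = sample$Y)
  mask <- with_seed(seed, {
    # equal-as-possible random partition into n_groups groups
    grp <- rep(seq_len(n_groups), length.out = n)[sample.int(n)]
    m <- matrix(FALSE, n, 4)
    for (k in 1:4) {
      pair <- drivers[[paste0("x", k)]]
      a <- vars[, pair[1]]; b <- vars[, pair[2]]
      cors <- vapply(seq_len(n_groups), function(g) {
        ga <- a[grp == g]; gb <- b[grp == g]
        if (length(ga) < 2 || sd(ga) == 0 || sd(gb) == 0) return(0)
        stats::cor(ga, gb)
      }, numeric(1))
      ord <- order(cors, seq_len(n_groups)) # stable: correlation, then index
      half <- n_groups %/% 2
      rate_of_group <- numeric(n_groups)
      rate_of_group[ord[seq_len(half)]] <- rates[1]
      rate_of_group[ord[(half + 1):n_groups]] <- rates[2]
      m[, k] <- runif(n) < rate_of_group[grp]
    }
    m
  })
  new_incomplete(sample, mask, "MARSINISTER")
}

#' Impose missingness by mechanism label
#'
#' Dispatcher used by the simulation driver.
#'
#' @param sample a \code{ps_sample}.
#' @param mechanism one of "MCAR", "MAR1", "MAR2", "MARSINISTER".
#' @param overall_rate 0.25 or 0.5.
#' @param seed optional integer seed.
#' @param ... passed to the mechanism-specific function.
#' @return a \code{ps_incomplete} object.
#' @export
impose_missingness <- function(sample, mechanism, overall_rate = 0.25,
                               seed = NULL, ...) {
  switch(toupper(mechanism),
         MCAR = impose_mcar(sample, overall_rate, seed, ...),
         MAR1 = impose_mar1(sample, overall_rate, seed, ...),
         MAR2 = impose_mar2(sample, overall_rate, seed, ...),
         MARSINISTER = impose_mar_sinister(sample, overall_rate, seed, ...),
         stop("unknown mechanism: ", mechanism))
}
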