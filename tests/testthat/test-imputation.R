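test_that("treatment mean imputation uses unrounded exposure-group means", {
  # hand-built 6-row fixture: two missing cells per covariate of interest
  s <- generate_sample(6, "A", seed = 201)
  s$T <- c(1, 1, 1, 0, 0, 0)
  s$X[, "x1"] <- c(0, 1, 1, 1, 0, 0)
  s$X[, "x2"] <- c(0.5, -1, 2, 3, 1, -2)
  mask <- matrix(FALSE, 6, 4)
  mask[1, 1] <- TRUE # x1 missing for a T=1 subject
  mask[4, 2] <- TRUE # x2 missing for a T=0 subject
  inc <- with_mask(s, mask)
  out <- impute_treatment_mean(inc)
  X <- out$completed[[1]]
  expect_equal(unname(X[1, "x1"]), mean(c(1, 1)))      # observed T=1 values of x1
  expect_equal(unname(X[4, "x2"]), mean(c(1, -2)))     # observed T=0 values of x2
  # observed cells untouched
  obs <- !is.na(observed_covariates(inc))
  expect_identical(X[obs], s$X[obs])

  # {0,1,1} in the T=1 group imputes 2/3, unrounded
  s2 <- generate_sample(6, "A", seed = 202)
  s2$T <- c(1, 1, 1, 1, 0, 0)
  s2$X[, "x1"] <- c(0, 1, 1, 9, 0, 1)
  m2 <- matrix(FALSE, 6, 4); m2[4, 1] <- TRUE
  out2 <- impute_treatment_mean(with_mask(s2, m2))
  expect_equal(unname(out2$completed[[1]][4, "x1"]), 2 / 3)

  # no missing cells: identity
  out3 <- impute_treatment_mean(impose_mcar(s, 0, seed = 1))
  expect_identical(out3$completed[[1]], s$X)

  # an exposure group with nothing observed errors informatively
  s3 <- generate_sample(4, "A", seed = 203)
  s3$T <- c(1, 1, 0, 0)
  m3 <- matrix(FALSE, 4, 4); m3[1:2, 1] <- TRUE
  expect_error(impute_treatment_mean(with_mask(s3, m3)), "x1.*T=1")
})

test_that("single imputation reproduces the fitted residual variance (PE) and exceeds it with parameter uncertainty (PE+PU)", {
  s <- generate_sample(60, "A", seed = 204)
  mask <- matrix(FALSE, 60, 4); mask[5, 2] <- TRUE
  inc <- with_mask(s, mask)

  # fitted residual variance of the x2 imputation model (the oracle)
  W <- cbind(1, s$X[, c(1, 3:6, 8, 9)], s$T, s$Y)
  obs <- seq_len(60)[-5]
  fit <- lm.fit(W[obs, ], s$X[obs, 2])
  sigma2 <- sum(fit$residuals^2) / (length(obs) - ncol(W))

  draws_pe <- vapply(seq_len(4000), function(i)
    impute_si_pe(inc, n_cycles = 2, seed = i)$completed[[1]][5, 2],
    numeric(1))
  # with fixed parameters the only randomness is the residual draw
  expect_lt(abs(var(draws_pe) / sigma2 - 1), 0.05)

  draws_pu <- vapply(seq_len(4000), function(i)
    impute_si_pe_pu(inc, n_cycles = 2, seed = i)$completed[[1]][5, 2],
    numeric(1))
  expect_gt(var(draws_pu), var(draws_pe))

  # zero residual variance: imputation returns the exact prediction
  s0 <- generate_sample(40, "A", seed = 205)
  s0$X[, "x2"] <- s0$Y            # x2 exactly linear in an imputer variable
  m0 <- matrix(FALSE, 40, 4); m0[7, 2] <- TRUE
  out0 <- impute_si_pe(with_mask(s0, m0), n_cycles = 1, seed = 1)
  expect_equal(unname(out0$completed[[1]][7, 2]), s0$Y[7],
               tolerance = 1e-8)

  # no missing cells: identity, for both SI flavours
  inc_none <- impose_mcar(s, 0, seed = 1)
  expect_identical(impute_si_pe(inc_none, seed = 1)$completed[[1]], s$X)
  expect_identical(impute_si_pe_pu(inc_none, seed = 1)$completed[[1]], s$X)
})

test_that("chained-equations MI returns m datasets with identical observed cells and MCAR-preserving means", {
  s <- generate_sample(5000, "A", seed = 206)
  inc <- impose_mcar(s, 0.25, seed = 207)
  imp <- impute_fcs(inc, m = 5, n_cycles = 5, seed = 208)
  expect_equal(imp$m, 5)
  expect_equal(imp$imputer_variables,
               c(paste0("x", c(1:6, 8, 9)), "T", "Y"))
  obs <- !is.na(observed_covariates(inc))
  for (M in imp$completed) expect_identical(M[obs], s$X[obs])

  # under MCAR the across-imputation mean of imputed x2 cells matches the
  # complete-data mean within 3 Monte-Carlo SEs
  mis2 <- inc$mask[, 2]
  imputed <- unlist(lapply(imp$completed, function(M) M[mis2, 2]))
  mc_se <- sd(imputed) / sqrt(length(imputed))
  expect_lt(abs(mean(imputed) - mean(s$X[, 2])), 3 * mc_se + 0.01)

  # between-imputation variance of an imputed cell is strictly positive
  cell <- which(mis2)[1]
  vals <- vapply(imp$completed, function(M) M[cell, 2], numeric(1))
  expect_gt(var(vals), 0)

  # m datasets with no missingness are all identical to the input
  imp0 <- impute_fcs(impose_mcar(s, 0, seed = 1), m = 3, seed = 2)
  expect_identical(imp0$completed[[2]], s$X)
})

test_that("pattern pooling merges by Hamming distance up to the minimum count", {
  sig_to_mask <- function(sigs, counts) {
    rows <- rep(sigs, counts)
    t(vapply(strsplit(rows, ""), function(b) as.logical(as.integer(b)),
             logical(4)))
  }
  # hand trace: 0111 (60) merges into its Hamming-1 neighbour 1111, then
  # 1011 (70) likewise; one pooled group of 530 remains
  mask <- sig_to_mask(c("1111", "0111", "1011"), c(400, 60, 70))
  pool <- pool_patterns(mask, min_count = 100)
  expect_equal(length(pool$groups), 1)
  expect_equal(pool$groups[[1]]$count, 530)
  expect_true(all(pool$id == 1))

  # pooling stops once every group reaches the minimum
  mask2 <- sig_to_mask(c("0000", "1000", "1100"), c(400, 150, 30))
  pool2 <- pool_patterns(mask2, min_count = 100)
  expect_equal(length(pool2$groups), 2)
  expect_setequal(vapply(pool2$groups, `[[`, numeric(1), "count"),
                  c(400, 180))

  # min_count = 1: identity on raw signatures
  mask3 <- sig_to_mask(c("0000", "0001", "1001"), c(5, 3, 2))
  pool3 <- pool_patterns(mask3, min_count = 1)
  expect_equal(length(pool3$groups), 3)

  # all complete: a single trivial pattern
  pool4 <- pool_patterns(matrix(FALSE, 20, 4), min_count = 100)
  expect_equal(length(pool4$groups), 1)
  expect_equal(pool4$groups[[1]]$signatures, "0000")
})

test_that("MIMP attaches a mask-determined pattern factor with pooled groups above the minimum", {
  s <- generate_sample(500, "A", seed = 209)
  inc <- impose_mcar(s, 0.25, seed = 210)
  imp <- impute_mimp(inc, m = 3, min_count = 100, n_cycles = 3, seed = 211)
  expect_s3_class(imp$pattern, "factor")
  expect_true(all(table(imp$pattern) >= 100))
  # the pattern depends only on the mask, hence is shared by all m datasets
  imp2 <- impute_mimp(inc, m = 2, min_count = 100, n_cycles = 3, seed = 999)
  expect_identical(imp$pattern, imp2$pattern)

  # no missingness: constant indicator, dropped downstream by the design
  inc0 <- impose_mcar(s, 0, seed = 1)
  imp0 <- impute_mimp(inc0, m = 2, n_cycles = 2, seed = 3)
  expect_equal(nlevels(droplevels(imp0$pattern)), 1)
  D <- build_ps_design(imp0$completed[[1]], "true_confounders", imp0$pattern)
  expect_equal(ncol(D), 5) # intercept + x1..x4, no dummies
})
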