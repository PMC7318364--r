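test_that("tree split search equals the brute-force exhaustive oracle on small fixtures", {
  for (seed in 1:6) {
    fx <- make_fixture(n = 20 + 5 * seed, p = 4, seed = seed)
    for (depth in c(1, 2, 4)) {
      tr <- fit_reg_tree(fx$X, fx$y, depth = depth, min_node = 3)
      expect_equal(attr(tr, "fitted"),
                   oracle_tree_fit(fx$X, fx$y, depth, min_node = 3),
                   tolerance = 1e-12,
                   label = sprintf("seed %d depth %d", seed, depth))
    }
  }
  # depth-1 stump: chosen variable, threshold and child means by hand
  fx <- make_fixture(8, p = 2, seed = 99)
  fx$X <- cbind(v1 = c(1, 2, 3, 4, 5, 6, 7, 8), v2 = rep(0:1, 4))
  fx$y <- c(0, 0, 0, 0, 10, 10, 10, 10)
  tr <- fit_reg_tree(fx$X, fx$y, depth = 1, min_node = 2)
  expect_equal(tr$var[1], 1)
  expect_equal(tr$split[1], 4.5)
  expect_equal(sort(tr$value[2:3]), c(0, 10))
})

test_that("surrogates: a duplicated column has agreement 1 and routes exactly as its duplicate", {
  set.seed(401)
  n <- 40
  base <- seq(-2, 2, length.out = n)
  y <- ifelse(base > 0, 5, 0) + rnorm(n, 0, 0.05)
  y[1:5] <- 5 # anomalous rows, observed only on the duplicate column
  X <- cbind(v1 = base, v2 = base, v3 = rbinom(n, 1, 0.5))
  Xm <- X
  Xm[1:5, 1] <- NA # v1's complete cases exclude the anomalies
  tr <- fit_reg_tree(Xm, y, depth = 1, min_node = 5)
  expect_equal(tr$var[1], 1) # clean split on v1 beats the diluted v2 split
  su <- tr$surrogates[[1]]
  expect_equal(su[1, 1], 2)  # best surrogate is the duplicate column
  expect_equal(su[1, 4], 1)  # perfect agreement
  # rows missing v1 are routed exactly as their duplicate value dictates
  fitted <- attr(tr, "fitted")
  side <- ifelse(X[1:5, 2] < tr$split[1], tr$left[1], tr$right[1])
  expect_equal(fitted[1:5], unname(tr$value[side]))

  # complete data: no surrogates are stored anywhere
  tr2 <- fit_reg_tree(X, y, depth = 3, min_node = 5)
  expect_true(all(vapply(tr2$surrogates, nrow, integer(1)) == 0))
})

test_that("a row missing every split variable follows the majority path", {
  fx <- make_fixture(60, p = 3, seed = 402)
  tr <- fit_reg_tree(fx$X, fx$y, depth = 2, min_node = 5)
  # hand-walk the majority path through the serialized tree
  node <- 1
  while (!is.na(tr$var[node]))
    node <- if (tr$maj_left[node]) tr$left[node] else tr$right[node]
  pred <- predict(tr, matrix(NA_real_, 1, 3))
  expect_equal(pred, tr$value[node])
})

test_that("boosting limits: zero iterations and vanishing shrinkage give the prevalence", {
  s <- generate_sample(300, "A", seed = 403)
  X <- s$X[, 1:4]
  b0 <- suppressWarnings(ps_boost(X, s$T, n_trees = 0))
  expect_equal(b0$ps, rep(mean(s$T), 300))
  # AASM at iteration 0 equals the plain unweighted standardized difference
  aasm0 <- mean(vapply(1:4, function(j) {
    x1 <- X[s$T == 1, j]
    abs(mean(x1) - mean(X[s$T == 0, j])) / sd(x1)
  }, numeric(1)))
  expect_equal(b0$aasm[1], aasm0, tolerance = 1e-12)

  btiny <- suppressWarnings(
    ps_boost(X, s$T, shrinkage = 1e-6, n_trees = 20))
  expect_lt(max(abs(btiny$ps - mean(s$T))), 1e-3)
})

test_that("AASM-selected iteration improves balance and is reproducible by prediction", {
  s <- generate_sample(1000, "G", seed = 404)
  b <- suppressWarnings(ps_boost(s$X[, 1:4], s$T, n_trees = 300))
  expect_lt(b$aasm[b$best_iter + 1], b$aasm[1])
  expect_equal(b$best_iter, which.min(b$aasm) - 1L)

  # on incomplete data, training-set prediction at the best iteration
  # reproduces the stored scores bit-for-bit
  inc <- impose_mcar(s, 0.25, seed = 405)
  Xm <- observed_covariates(inc)[, 1:4]
  bm <- suppressWarnings(ps_boost(Xm, s$T, n_trees = 150))
  expect_identical(predict(bm, Xm), bm$ps)
  expect_equal(predict(bm, Xm, n_trees = 0), rep(mean(s$T), 1000))
})

test_that("AASM formula matches hand computation and weight-scale invariance", {
  # single covariate: exposed {1,3} (mean 2, sd sqrt(2)); unexposed {0,2}
  # with equal weights (weighted mean 1) -> AASM = 1/sqrt(2)
  X <- matrix(c(1, 3, 0, 2))
  treat <- c(1, 1, 0, 0)
  expect_equal(compute_aasm(X, treat, rep(0.5, 4)), 1 / sqrt(2))
  # identical groups and constant ps: perfect balance
  Xb <- matrix(c(1, 2, 1, 2))
  expect_equal(compute_aasm(Xb, c(1, 1, 0, 0), rep(0.3, 4)), 0)
  # doubling all unexposed odds-weights leaves the metric unchanged:
  # ps -> ps' with p'/(1-p') = 2 p/(1-p)
  ps <- c(0.5, 0.5, 0.3, 0.6)
  odds2 <- 2 * ps / (1 - ps)
  ps2 <- odds2 / (1 + odds2)
  ps2[treat == 1] <- ps[treat == 1]
  expect_equal(compute_aasm(X, treat, ps), compute_aasm(X, treat, ps2))
  # zero exposed SD on every covariate is an error
  expect_error(
    suppressWarnings(compute_aasm(matrix(c(1, 1, 0, 2)), treat,
                                  rep(0.5, 4))),
    "zero exposed-group SD")
})

test_that("internal per-iteration AASM agrees with the exported metric", {
  s <- generate_sample(400, "A", seed = 406)
  inc <- impose_mcar(s, 0.25, seed = 407)
  Xm <- observed_covariates(inc)[, 1:4]
  b <- suppressWarnings(ps_boost(Xm, s$T, n_trees = 40))
  for (it in c(5L, 40L)) {
    ps_it <- predict(b, Xm, n_trees = it)
    expect_equal(b$aasm[it + 1],
                 suppressWarnings(compute_aasm(Xm, s$T, ps_it)),
                 tolerance = 1e-12)
  }
})

test_that("boosting the Bernoulli log-likelihood is non-decreasing early at small shrinkage", {
  s <- generate_sample(500, "A", seed = 408)
  X <- s$X[, 1:4]
  loglik <- function(ps) sum(s$T * log(ps) + (1 - s$T) * log(1 - ps))
  b <- suppressWarnings(ps_boost(X, s$T, shrinkage = 0.01, n_trees = 30))
  ll <- vapply(0:30, function(it)
    loglik(predict(b, X, n_trees = it)), numeric(1))
  expect_true(all(diff(ll) > -1e-8))
})

test_that("fits and imputations export to plain-text listings", {
  s <- generate_sample(120, "A", seed = 409)
  b <- suppressWarnings(ps_boost(s$X[, 1:4], s$T, n_trees = 5))
  tj <- tempfile(fileext = ".json")
  ta <- tempfile(fileext = ".csv")
  export_boost(b, trees_json = tj, aasm_table = ta)
  on.exit(unlink(c(tj, ta)))
  dump <- jsonlite::read_json(tj)
  expect_equal(length(dump$trees), 5)
  expect_equal(dump$best_iter, b$best_iter)
  traj <- read.csv(ta)
  expect_equal(nrow(traj), 6) # iterations 0..5
  expect_equal(traj$aasm, b$aasm)

  inc <- impose_mcar(s, 0.25, seed = 410)
  imp <- impute_fcs(inc, m = 2, n_cycles = 2, seed = 411)
  ti <- tempfile(fileext = ".csv")
  write_imputations(imp, inc, ti)
  back <- read.csv(ti, check.names = FALSE)
  expect_equal(nrow(back), 240)
  expect_equal(sort(unique(back$.imp)), 1:2)
  unlink(ti)
})
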