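test_that("cell specification validates the factorial design constraints", {
  expect_s3_class(cell_spec(method = "complete", mechanism = "none"),
                  "cell_spec")
  expect_error(cell_spec(method = "TMI", mechanism = "none"), "baselines")
  expect_error(cell_spec(method = "complete", mechanism = "MCAR"),
               "baselines")
  expect_error(cell_spec(method = "GBM", mechanism = "MCAR",
                         strategy = "add_x5"), "true-confounder")
  expect_error(cell_spec(scenario = "A", method = "MI", mechanism = "MCAR",
                         strategy = "correct_G"), "scenario G")
  expect_error(cell_spec(method = "TMI", mechanism = "MCAR",
                         overall_rate = 0.3), "overall_rate")
  # GBM_incomplete is accepted as an alias
  expect_equal(cell_spec(method = "GBM_incomplete",
                         mechanism = "MCAR")$method, "GBM")
})

test_that("replications are deterministic and paired across methods", {
  spec <- cell_spec(method = "MI", mechanism = "MCAR", reps = 5, m = 3,
                    n_cycles = 3, n = 300)
  r1 <- run_replication(spec, 2, master_seed = 7)
  r2 <- run_replication(spec, 2, master_seed = 7)
  expect_identical(r1$estimate, r2$estimate)
  expect_identical(r1$se, r2$se)

  # the complete-data stream ignores mechanism and method; the mask stream
  # ignores the method -- the paired design
  s1 <- cell_spec(method = "TMI", mechanism = "MCAR", n = 300)
  s2 <- cell_spec(method = "MI", mechanism = "MCAR", n = 300)
  s3 <- cell_spec(method = "TMI", mechanism = "MAR1", n = 300)
  key <- psmiss:::cell_key
  expect_identical(key(s1, "data"), key(s2, "data"))
  expect_identical(key(s1, "data"), key(s3, "data"))
  expect_identical(key(s1, "mask"), key(s2, "mask"))
  expect_false(identical(key(s1, "mask"), key(s3, "mask")))
  expect_false(identical(key(s1, "method"), key(s2, "method")))
})

test_that("a TMI replication equals an independently scripted pipeline", {
  spec <- cell_spec(method = "TMI", mechanism = "MCAR", n = 400, reps = 2)
  got <- run_replication(spec, 3, master_seed = 11)

  # hand pipeline with the same derived seeds
  key <- psmiss:::cell_key
  s <- generate_sample(400, "A",
                       seed = derive_seed(11, key(spec, "data"), 3))
  inc <- impose_mcar(s, 0.25, seed = derive_seed(11, key(spec, "mask"), 3))
  X <- observed_covariates(inc)
  for (j in 1:4) {
    obs <- !is.na(X[, j]) # group means from originally observed cells only
    for (t in 0:1) X[!obs & s$T == t, j] <- mean(X[obs & s$T == t, j])
  }
  f <- glm.fit(cbind(1, X[, 1:4]), s$T, family = binomial(),
               control = glm.control(epsilon = 1e-8, maxit = 100))
  ps <- pmin(pmax(f$fitted.values, 1e-6), 1 - 1e-6)
  p_hat <- mean(ps)
  w <- ifelse(s$T == 1, p_hat / ps, (1 - p_hat) / (1 - ps))
  q <- quantile(w, c(0.01, 0.99), names = FALSE)
  w <- pmin(pmax(w, q[1]), q[2])
  fit <- lm(s$Y ~ s$T, weights = w)
  expect_equal(got$estimate, unname(coef(fit)[2]), tolerance = 1e-12)
})

test_that("cell aggregation matches the printed definitions and the rmse identity", {
  agg <- aggregate_estimates(c(-0.3, -0.5), c(0.1, 0.2))
  expect_equal(agg$bias, 0)
  expect_equal(agg$sd, sqrt(0.02), tolerance = 1e-12)
  expect_equal(agg$rmse, 0.1)
  expect_equal(agg$mean_se, 0.15)
  expect_equal(aggregate_estimates(rep(-0.4, 5), rep(0.1, 5))$rmse, 0)

  cell <- run_cell(cell_spec(method = "complete", mechanism = "none",
                             n = 200, reps = 25), master_seed = 5)
  R <- cell$reps_completed
  expect_lt(abs(cell$rmse^2 - (cell$bias^2 + (R - 1) / R * cell$sd^2)),
            1e-10)
  expect_equal(cell$failures, 0)
  expect_true(cell$valid)
})

test_that("run_study validates configs, runs cells, and writes results", {
  expect_equal(nrow(run_study(list(cells = list()))), 0)
  expect_named(run_study(list(cells = list())),
               c("scenario", "mechanism", "overall_rate", "n", "method",
                 "strategy", "bias", "sd", "mean_se", "rmse",
                 "reps_completed", "failures", "valid"))

  expect_error(run_study(list(bogus = 1)), "unknown config keys: bogus")
  expect_error(run_study(list(cells = list(list(method = "TMI",
                                                frobnicate = 2)))),
               "unknown cell keys: frobnicate")

  out_dir <- tempfile()
  cfg <- list(master_seed = 3, reps = 10,
              defaults = list(n = 200, scenario = "A"),
              cells = list(list(method = "complete", mechanism = "none"),
                           list(method = "TMI", mechanism = "MCAR")))
  res <- run_study(cfg, out_dir = out_dir)
  expect_equal(nrow(res), 2)
  expect_equal(res$method, c("complete", "TMI"))
  expect_true(file.exists(file.path(out_dir, "results.csv")))
  back <- read.csv(file.path(out_dir, "results.csv"))
  expect_equal(back$bias, res$bias)

  # identical config and seed reproduce bit-identical results
  res2 <- run_study(cfg)
  expect_identical(res$bias, res2$bias)

  # YAML round trip
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  res3 <- run_study(yml)
  expect_equal(res3$bias, res$bias)
  unlink(c(yml, out_dir), recursive = TRUE)
})

test_that("the published table layout enumerates to 30 report rows", {
  cells <- table_cells("A", 500, 0.25)
  # 4 complete + 1 comGBM + 4 mechanisms x (5 methods x 4 strategies + 2)
  expect_equal(length(cells), 5 + 4 * 22)
  # pivoted report: one row per (mechanism, method)
  fake <- do.call(rbind, lapply(cells, function(cl) {
    data.frame(scenario = cl$scenario, mechanism = toupper(cl$mechanism),
               overall_rate = cl$overall_rate, n = cl$n, method = cl$method,
               strategy = cl$strategy, bias = 0, sd = 0, mean_se = 0,
               rmse = 0, reps_completed = 2, failures = 0, valid = TRUE)
  }))
  rep5 <- report_table(fake)
  expect_equal(nrow(rep5), 30)
  expect_true("true_confounders.bias" %in% names(rep5))

  cells_g <- table_cells("G", 500, 0.25, correct_only = TRUE)
  expect_equal(length(cells_g), 1 + 4 * 5)
})
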