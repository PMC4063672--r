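test_that("the default sweep grid enumerates the full parameter space", {
  g <- sweep_grid()
  expect_identical(nrow(g), 1710L)
  expect_identical(length(unique(g$N)), 19L)
  expect_identical(length(unique(g$f)), 10L)
  expect_identical(length(unique(g$s)), 9L)
  expect_equal(range(g$N), c(50, 500))
  expect_equal(range(g$f), c(4, 40))
  expect_equal(range(g$s), c(5, 30))
})

test_that("repeated experiments are deterministic in the master seed", {
  a <- one_hole_arena()
  tr <- short_trajectory()
  spec <- ensemble_spec(40, 14, 8)
  r1 <- run_learning_experiment(spec, a, tr, repeats = 2, seed = 77,
                                horizon = 300)
  r2 <- run_learning_experiment(spec, a, tr, repeats = 2, seed = 77,
                                horizon = 300)
  expect_identical(r1$t_min, r2$t_min)
  expect_identical(r1$rho, r2$rho)
  expect_identical(r1$loop_durations, r2$loop_durations)
})

test_that("the core filter applies inclusive rho and xi thresholds", {
  res <- data.frame(rho = c(0.7, 0.6, 1.0, 0.8, 0.9),
                    xi = c(0.30, 0.10, 0.31, 0.05, NA))
  kept <- core_filter(res)
  expect_identical(rownames(kept), c("1", "4"))
  expect_identical(nrow(core_filter(res[0, ])), 0L)
  # stricter thresholds
  expect_identical(rownames(core_filter(res, rho_min = 0.75, xi_max = 0.2)),
                   "4")
})

test_that("distribution fits recover parameters and modes", {
  set.seed(31)
  x <- rgamma(5000, shape = 3, rate = 0.5)
  fg <- fit_distribution(x, "gamma")
  expect_lt(abs(fg$mode - 4) / 4, 0.1)
  expect_lt(abs(fg$params[["shape"]] - 3) / 3, 0.1)

  set.seed(32)
  y <- rgev(5000, loc = 10, scale = 2, shape = 0.15)
  fv <- fit_distribution(y, "gev")
  expect_lt(abs(fv$params[["loc"]] - 10) / 10, 0.1)
  expect_lt(abs(fv$params[["scale"]] - 2) / 2, 0.1)
  expect_lt(abs(fv$params[["shape"]] - 0.15), 0.05)
  true_mode <- 10 + 2 * ((1 + 0.15)^(-0.15) - 1) / 0.15
  expect_lt(abs(fv$mode - true_mode) / true_mode, 0.1)

  set.seed(33)
  z <- rnorm(200, 5, 2)
  fn <- fit_distribution(z, "normal")
  expect_equal(fn$mode, mean(z))

  expect_error(fit_distribution(rep(3, 100), "gamma"), "degenerate")
  expect_error(fit_distribution(c(-1, rexp(99)), "gamma"), "positive")
  expect_error(fit_distribution(rnorm(5), "normal"), "at least 10")
})

test_that("gamma fit agrees with an independent reference fit", {
  skip_if_not_installed("fitdistrplus")
  set.seed(35)
  x <- rgamma(2000, shape = 2.5, rate = 1.7)
  ours <- fit_distribution(x, "gamma")
  ref <- fitdistrplus::fitdist(x, "gamma")
  expect_equal(ours$params[["shape"]], unname(ref$estimate["shape"]),
               tolerance = 0.01)
  expect_equal(ours$params[["rate"]], unname(ref$estimate["rate"]),
               tolerance = 0.01)
})

test_that("the KS matrix flags distinct groups and only those", {
  set.seed(41)
  groups <- list(a = rnorm(200), b = rnorm(200, 10), c = rnorm(200, 0.05))
  km <- ks_matrix(groups)
  expect_true(isSymmetric(km$p))
  expect_identical(diag(km$p), c(a = 1, b = 1, c = 1))
  expect_lt(km$p["a", "b"], 1e-10)
  expect_true(km$significant["a", "b"])
  expect_false(km$significant["a", "c"])
  expect_false(any(diag(km$significant)))
  expect_error(ks_matrix(list(a = rnorm(10))), "two sample groups")
  expect_error(ks_matrix(list(a = rnorm(3), b = rnorm(10))), "at least 5")
})
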