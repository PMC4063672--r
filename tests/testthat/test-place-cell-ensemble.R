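test_that("log-normal sampling is moment-matched to the ensemble means", {
  a <- one_hole_arena()
  spec <- ensemble_spec(10000, 20, 12, a = 0.3, b = 0.3)
  ens <- sample_ensemble(spec, a, seed = 1)
  expect_lt(abs(mean(ens$cells$f) - 20) / 20, 0.02)
  expect_lt(abs(mean(ens$cells$s) - 12) / 12, 0.02)
  expect_lt(abs(sd(ens$cells$f) - 6) / 6, 0.05)
  # field extent convention
  expect_equal(ens$cells$L, 3 * ens$cells$s)
  # all centres inside the arena and outside the hole
  expect_true(all(topolearn:::in_arena(a, ens$cells$x, ens$cells$y)))
})

test_that("zero spread collapses the ensemble onto the means", {
  a <- one_hole_arena()
  ens <- sample_ensemble(ensemble_spec(50, 15, 10, a = 0, b = 0), a)
  expect_equal(ens$cells$f, rep(15, 50))
  expect_equal(ens$cells$s, rep(10, 50))
})

test_that("out-of-range ensemble means warn but are allowed", {
  expect_warning(ensemble_spec(50, 2, 10), "4-40")
  expect_warning(ensemble_spec(50, 20, 40), "5-30")
})

test_that("the rate map is a Gaussian bump with the stated closed form", {
  cell <- list(x = 0.5, y = 0.5, f = 20, s = 10)
  expect_equal(firing_rate(cell, 0.5, 0.5), 20)
  # at 3 sigma the rate is f * exp(-4.5)
  expect_equal(firing_rate(cell, 0.5 + 0.3, 0.5), 20 * exp(-4.5))
  expect_equal(firing_rate(cell, 0.5, 0.5 - 0.1), 20 * exp(-0.5))
})

test_that("dynamic fields start near zero with a 0.1 Hz background", {
  cell <- list(x = 0.5, y = 0.5, f = 20, s = 10, tau = 240)
  r0 <- firing_rate(cell, 0.5, 0.5, t = 0, dynamic = TRUE)
  expect_lte(r0, 0.02 * 20 + 0.1)
  # formed field approaches the static peak
  r_late <- firing_rate(cell, 0.5, 0.5, t = 2400, dynamic = TRUE)
  expect_gt(r_late, 0.99 * 20)
  # amplitude grows monotonically through the formation window
  rates <- firing_rate(cell, 0.5, 0.5, t = seq(0, 240, by = 30),
                       dynamic = TRUE)
  expect_true(all(diff(rates) > 0))
})

test_that("Poisson thinning reproduces the integrated rate", {
  # constant-rate cell (huge field): N(spikes) ~ Poisson(r * T)
  tr <- straight_pass(duration = 10)
  ens <- single_cell_ensemble(0.5, 0.5, f = 10, s = 1e4)
  counts <- vapply(1:400, function(sd)
    length(generate_spikes(ens, tr, seed = sd)$spikes[[1]]), 0L)
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 400) * 3)

  # straight pass through a Gaussian field: path-integral oracle
  tr <- straight_pass(duration = 4, v = 0.25)
  ens <- single_cell_ensemble(0.55, 0.5, f = 15, s = 6)
  lam <- function(t) 15 * exp(-((0.05 + 0.25 * t - 0.55)^2) / (2 * 0.06^2))
  expected <- stats::integrate(lam, 0, 4)$value
  counts <- vapply(1:600, function(sd)
    length(generate_spikes(ens, tr, seed = sd)$spikes[[1]]), 0L)
  expect_lt(abs(mean(counts) - expected),
            3 * sqrt(expected / 600) + 0.05 * expected)

  # two more profiles: off-path field and zero modulation
  ens_far <- single_cell_ensemble(0.5, 0.9, f = 15, s = 6)
  lam_far <- function(t) 15 * exp(-((0.05 + 0.25 * t - 0.5)^2 + 0.4^2) /
                                    (2 * 0.06^2))
  exp_far <- stats::integrate(lam_far, 0, 4)$value
  counts_far <- vapply(1:600, function(sd)
    length(generate_spikes(ens_far, tr, seed = sd)$spikes[[1]]), 0L)
  expect_lt(abs(mean(counts_far) - exp_far), 3 * sqrt(max(exp_far, 1) / 600) +
              0.05 * exp_far + 0.02)

  zero_mod <- function(i, t) rep(0, length(t))
  expect_length(generate_spikes(ens, tr, zero_mod, seed = 1)$spikes[[1]], 0)
})

test_that("spike generation is reproducible and validates inputs", {
  tr <- short_trajectory()
  a <- one_hole_arena()
  ens <- sample_ensemble(ensemble_spec(20, 10, 8), a, seed = 2)
  s1 <- generate_spikes(ens, tr, seed = 9)
  s2 <- generate_spikes(ens, tr, seed = 9)
  expect_identical(s1$spikes, s2$spikes)
  expect_true(all(unlist(s1$spikes) >= 0 & unlist(s1$spikes) <= tr$duration))
  expect_false(any(vapply(s1$spikes, is.unsorted, TRUE)))

  bad_tr <- structure(list(x = 0.1, y = 0.1, times = 0, dt = 0.01,
                           duration = 0), class = "trajectory")
  expect_error(generate_spikes(ens, bad_tr, seed = 1), "empty trajectory")
  bad_mod <- function(i, t) rep(2, length(t))
  expect_error(generate_spikes(ens, tr, bad_mod, seed = 1),
               "modulation values")
})

test_that("spatial selectivity of spiking emerges as fields form", {
  a <- one_hole_arena()
  tr <- fixture("traj900dyn", function() generate_trajectory(a, 900, seed = 5))
  spec <- ensemble_spec(60, 20, 8, dynamic_fields = TRUE, tau_mean = 240)
  ens <- sample_ensemble(spec, a, seed = 3)
  sp <- generate_spikes(ens, tr, seed = 4)
  info <- vapply(list(c(0, 60), c(120, 180), c(480, 540)), function(iv)
    spatial_information(sp, tr, iv[1], iv[2]), 0)
  # information rises from the unformed to the formed regime
  expect_gt(info[3], info[1])
  expect_gt(info[2], info[1])
})
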