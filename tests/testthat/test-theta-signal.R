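spectral_peaks <- function(theta, k = 4) {
  n <- length(theta$samples)
  spec <- Mod(fft(theta$samples))[seq_len(floor(n / 2))]
  f_axis <- (seq_len(floor(n / 2)) - 1) * theta$sample_rate / n
  f_axis[order(spec, decreasing = TRUE)][seq_len(k)]
}

out_of_band_fraction <- function(theta) {
  n <- length(theta$samples)
  p <- Mod(fft(theta$samples))[seq_len(floor(n / 2))]^2
  f_axis <- (seq_len(floor(n / 2)) - 1) * theta$sample_rate / n
  sum(p[f_axis < 6 | f_axis > 12]) / sum(p)
}

test_that("theta signals have the stated spectral content", {
  th1 <- make_theta("single", duration = 60)
  expect_equal(spectral_peaks(th1, 1), 8, tolerance = 0.02)
  th4 <- make_theta("four_sinusoid", duration = 120, seed = 3)
  peaks <- sort(spectral_peaks(th4, 4))
  expect_equal(peaks, c(6.5, 8.65, 10.0, 11.5), tolerance = 0.02)
  expect_lte(out_of_band_fraction(th1), 0.01)
  expect_lte(out_of_band_fraction(th4), 0.01)
  # external signals are band-passed on load
  set.seed(1)
  raw <- rnorm(20000)
  ext <- make_theta("external", sample_rate = 500, samples = raw)
  expect_lte(out_of_band_fraction(ext), 0.01)
  expect_error(make_theta("single", sample_rate = 20), "aliasing")
})

test_that("instantaneous phase advances one cycle per period", {
  th <- make_theta("single", duration = 30)
  t0 <- seq(1, 20, by = 0.37)
  d <- (instantaneous_phase(th, t0 + 0.125) - instantaneous_phase(th, t0)) %%
    (2 * pi)
  expect_true(all(pmin(d, 2 * pi - d) < 0.05))
  up <- instantaneous_phase(th, seq(1, 25, by = 0.01), wrap = FALSE)
  expect_true(all(diff(up) > 0))
  expect_error(instantaneous_phase(th, 31), "support")
})

test_that("four-sinusoid instantaneous frequency stays within the theta band", {
  th4 <- make_theta("four_sinusoid", duration = 120, seed = 3)
  tt <- seq(1, 119, by = 0.002)
  up <- instantaneous_phase(th4, tt, wrap = FALSE)
  inst_f <- diff(up) / diff(tt) / (2 * pi)
  # the phase of a multi-component signal slips at envelope minima, so the
  # pointwise in-band fraction saturates near ~0.85 for an equal-amplitude
  # four-tone mixture (value computed by this numeric oracle); the
  # power-weighted mean frequency must sit inside the band
  expect_gte(mean(inst_f >= 6 & inst_f <= 12), 0.80)
  n <- length(th4$samples)
  h <- numeric(n)
  h[1] <- 1; h[2:(floor(n / 2))] <- 2
  env <- Mod(fft(fft(th4$samples) * h, inverse = TRUE) / n)
  env_t <- approx((seq_len(n) - 1) / th4$sample_rate, env, tt)$y
  wmean <- stats::weighted.mean(inst_f, head(env_t, -1)^2)
  expect_gt(wmean, 6)
  expect_lt(wmean, 12)
  # a pure sinusoid has no slips: fully in band
  th1 <- make_theta("single", duration = 30)
  up1 <- instantaneous_phase(th1, seq(1, 29, by = 0.002), wrap = FALSE)
  f1 <- diff(up1) / 0.002 / (2 * pi)
  expect_gte(mean(f1 >= 6 & f1 <= 12), 0.999)
})

test_that("preferred phase precesses linearly from 2*pi to 0", {
  expect_equal(preferred_phase(0, 30), 2 * pi)
  expect_equal(preferred_phase(30, 30), 0)
  expect_equal(preferred_phase(15, 30), pi)
  expect_warning(ph <- preferred_phase(35, 30), "clamped")
  expect_equal(ph, 0)
  expect_error(preferred_phase(-1, 30))
})

test_that("the precession factor is a normalized symmetric bump", {
  expect_equal(precession_factor(1.3, 1.3, 0.1), 1)
  d <- seq(0.1, 3, by = 0.3)
  expect_equal(precession_factor(1 + d, 1, 0.15),
               precession_factor(1 - d, 1, 0.15))
  expect_true(all(precession_factor(seq(0, 2 * pi, 0.1), pi, 0.1) <= 1))
  # epsilon arithmetic: v = 25 cm/s, L = 30 cm, f_theta = 8 Hz
  expect_equal(25 / (30 * 8), 0.104, tolerance = 0.01)
})

test_that("spike phases regress from high to low phase across a field", {
  # straight pass at constant speed through a single field
  tr <- straight_pass(duration = 4, v = 0.25)
  th <- make_theta("single", duration = 5)
  ens <- single_cell_ensemble(0.55, 0.5, f = 40, s = 8)
  mod <- precession_modulation(ens, tr, th)
  phases <- numeric(0); pos <- numeric(0)
  for (sd in 1:30) {
    sp <- generate_spikes(ens, tr, mod, seed = sd)$spikes[[1]]
    inf <- abs(0.05 + 0.25 * sp - 0.55) <= 0.12  # within L/2 of the centre
    phases <- c(phases, instantaneous_phase(th, sp[inf]))
    pos <- c(pos, (0.05 + 0.25 * sp[inf]))
  }
  expect_gt(length(phases), 100)
  # circular-linear association: phase decreases with in-field progress
  r <- cor.test(pos, phases, method = "spearman", exact = FALSE)
  expect_lt(r$estimate, -0.2)
  expect_lt(r$p.value, 0.01)
})

test_that("the raw precession factor only removes spikes", {
  a <- one_hole_arena()
  tr <- short_trajectory()
  th <- fixture("theta300", function() make_theta("single", duration = 301))
  ens <- sample_ensemble(ensemble_spec(30, 15, 8), a, seed = 6)
  raw <- precession_modulation(ens, tr, th, renormalize = FALSE)
  expect_identical(attr(raw, "max_multiplier"), 1)
  n_off <- sum(lengths(generate_spikes(ens, tr, seed = 11)$spikes))
  n_raw <- sum(lengths(generate_spikes(ens, tr, raw, seed = 11)$spikes))
  expect_lte(n_raw, n_off)
})
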