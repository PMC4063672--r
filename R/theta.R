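#' Construct a theta-band oscillation
#'
#' Three kinds of signal are supported: `"single"`, a pure 8 Hz sinusoid;
#' `"four_sinusoid"`, an equal-amplitude sum of sinusoids at 6.5, 8.65, 10.0
#' and 11.5 Hz (random relative phases, seeded) band-passed to 6-12 Hz; and
#' `"external"`, a user-supplied sampled trace (e.g. a band-passed LFP),
#' band-passed to 6-12 Hz on load. The instantaneous phase of the analytic
#' signal is precomputed and unwrapped for use by the precession model.
#'
#' @param kind one of `"single"`, `"four_sinusoid"`, `"external"`.
#' @param duration seconds (ignored for `"external"`).
#' @param sample_rate Hz; must exceed twice the 12 Hz band top.
#' @param seed integer seed (relative phases of the four-sinusoid mixture).
#' @param samples numeric vector of raw samples, required for `"external"`.
#' @return object of class `theta_signal` with elements `samples`,
#'   `sample_rate`, `kind`, `band`, `f_theta` (dominant frequency, Hz),
#'   `phase` (unwrapped instantaneous phase on the sample grid) and
#'   `duration`.
#' @export
make_theta <- function(kind = c("single", "four_sinusoid", "external"),
                       duration = 60, sample_rate = 1000, seed = 1L,
                       samples = NULL) {
  kind <- match.arg(kind)
  band <- c(6, 12)
  if (sample_rate < 2 * band[2])
    stop("sample_rate below twice the band top frequency: aliasing")
  if (kind == "external") {
    if (is.null(samples)) stop("external theta requires `samples`")
    x <- band_pass(as.numeric(samples), sample_rate, band)
    duration <- (length(x) - 1) / sample_rate
  } else {
    n <- floor(duration * sample_rate) + 1L
    if (n < 24) stop("signal too short for the band-pass filter")
    t <- (seq_len(n) - 1) / sample_rate
    if (kind == "single") {
      x <- sin(2 * pi * 8 * t)
    } else {
      freqs <- c(6.5, 8.65, 10.0, 11.5)
      set.seed(seed)
      ph <- runif(4, 0, 2 * pi)
      x <- rowSums(sapply(seq_along(freqs),
                          function(i) sin(2 * pi * freqs[i] * t + ph[i])))
      x <- band_pass(x, sample_rate, band)
    }
  }
  phase <- unwrap_phase(analytic_phase(x))
  # dominant frequency from the FFT magnitude
  n <- length(x)
  spec <- Mod(fft(x))[seq_len(floor(n / 2))]
  f_axis <- (seq_len(floor(n / 2)) - 1) * sample_rate / n
  f_theta <- f_axis[which.max(spec)]
  structure(
    list(samples = x, sample_rate = sample_rate, kind = kind, band = band,
         f_theta = f_theta, phase = phase,
         duration = (length(x) - 1) / sample_rate),
    class = "theta_signal"
  )
}

#' @export
print.theta_signal <- function(x, ...) {
  cat(sprintf("theta signal (%s): %.1f s at %g Hz, dominant %.2f Hz\n",
              x$kind, x$duration, x$sample_rate, x$f_theta))
  invisible(x)
}

# zero-phase FFT band-pass: full gain inside the band with half-cosine
# transitions of `transition` Hz placed just inside the corners, so that
# spectral power strictly outside [band[1], band[2]] is removed
band_pass <- function(x, sample_rate, band = c(6, 12), transition = 0.5) {
  n <- length(x)
  f <- seq(0, sample_rate - sample_rate / n, length.out = n)
  f <- pmin(f, sample_rate - f)  # two-sided frequency axis
  gain <- numeric(n)
  lo <- band[1]; hi <- band[2]
  gain[f >= lo + transition & f <= hi - transition] <- 1
  up <- f >= lo & f < lo + transition
  gain[up] <- 0.5 * (1 - cos(pi * (f[up] - lo) / transition))
  dn <- f > hi - transition & f <= hi
  gain[dn] <- 0.5 * (1 - cos(pi * (hi - f[dn]) / transition))
  Re(fft(fft(x) * gain, inverse = TRUE)) / n
}

# instantaneous phase of the analytic signal (FFT Hilbert construction)
analytic_phase <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * h, inverse = TRUE) / n
  Arg(z)
}

unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(phi[1], phi[1] + cumsum(d))
}

#' Instantaneous theta phase at given times
#'
#' @param theta a [make_theta()] signal.
#' @param t times in seconds within the signal support.
#' @param wrap return phase modulo 2*pi (default) or unwrapped.
#' @return phase(s) in radians; in `[0, 2*pi)` when wrapped.
#' @export
instantaneous_phase <- function(theta, t, wrap = TRUE) {
  stopifnot(inherits(theta, "theta_signal"))
  if (any(t < 0 | t > theta$duration + 1e-9))
    stop("t outside the theta signal support")
  grid <- (seq_along(theta$phase) - 1) / theta$sample_rate
  phi <- approx(grid, theta$phase, t, rule = 2)$y
  if (wrap) phi %% (2 * pi) else phi
}

#' Preferred spiking phase as a function of in-field progress
#'
#' Linear phase precession: at field entry (`l = 0`) the preferred phase is
#' `2*pi`; it decreases linearly with the accumulated in-field path `l`,
#' reaching 0 as the animal exits after travelling the field extent `L`.
#'
#' @param l accumulated in-field path length, cm (vectorised).
#' @param L field extent, cm.
#' @return preferred phase(s) in radians in `[0, 2*pi]`. Values `l > L`
#'   (late exits on curved paths) are clamped to phase 0 with a warning.
#' @export
preferred_phase <- function(l, L) {
  stopifnot(L > 0)
  if (any(l < 0)) stop("path length l must be >= 0")
  if (any(l > L)) {
    warning("l > L: late field exit, preferred phase clamped to 0")
    l <- pmin(l, L)
  }
  2 * pi * (1 - l / L)
}

#' Phase-precession rate modulation factor
#'
#' A wrapped-Gaussian bump in phase, peaking at 1 when the current theta
#' phase equals the preferred phase, with width `2*pi*epsilon` where
#' `epsilon = v / (L * f_theta)` is the fraction of the field traversed in
#' one theta cycle.
#'
#' @param phi current theta phase, radians (vectorised).
#' @param phi_star preferred phase, radians.
#' @param epsilon positive width parameter.
#' @return multiplier(s) in `(0, 1]`.
#' @export
precession_factor <- function(phi, phi_star, epsilon) {
  stopifnot(all(epsilon > 0))
  d <- abs((phi - phi_star + pi) %% (2 * pi) - pi)
  exp(-d^2 / (2 * (2 * pi * epsilon)^2))
}

#' Build a per-cell theta-precession modulation function
#'
#' Returns a function `(cell_index, times) -> multiplier` suitable for
#' [generate_spikes()]. For each cell the trajectory is scanned for place
#' field traversals (entry when the animal comes within `L/2` of the field
#' centre); within a traversal the preferred phase precesses linearly with
#' the accumulated path length, and the Poisson rate is multiplied by
#' [precession_factor()] evaluated at the signal's instantaneous phase.
#' Outside the field the multiplier is 1. The width parameter uses the
#' locally smoothed running speed (200 ms window by default).
#'
#' By default the factor is renormalized to preserve each cell's mean firing
#' rate over a theta cycle (`Lambda / mean_phase(Lambda)`, capped at
#' `max_multiplier`): precession then concentrates spikes at the preferred
#' phase without changing overall excitability, which suppresses weak
#' incidental coincidences (the integrated rate of a low-rate pair over a
#' window drops when spikes are phase-bunched) while leaving saturated
#' in-field coactivity intact. Set `renormalize = FALSE` for the raw
#' `[0, 1]` factor, which uniformly thins spikes instead.
#'
#' @param ensemble a [sample_ensemble()] object.
#' @param trajectory the session trajectory.
#' @param theta a [make_theta()] signal covering the session.
#' @param speed_window smoothing window for the running speed, seconds.
#' @param renormalize preserve each cell's cycle-averaged rate (default).
#' @param max_multiplier cap on the renormalized factor (default 3); keeps
#'   the Poisson thinning bound finite at very low running speeds.
#' @return modulation function, with per-cell traversal data cached lazily
#'   and attribute `max_multiplier` used by [generate_spikes()].
#' @export
precession_modulation <- function(ensemble, trajectory, theta,
                                  speed_window = 0.2, renormalize = TRUE,
                                  max_multiplier = 3) {
  stopifnot(inherits(theta, "theta_signal"))
  if (theta$duration < trajectory$duration - 1e-9)
    stop("theta signal shorter than the trajectory")
  cells <- ensemble$cells
  n <- length(trajectory$x)
  arc <- c(0, cumsum(sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2)))
  vsm <- pmax(smoothed_speed(trajectory, speed_window), 0.01)  # m/s, floored
  # unwrapped phase resampled once onto the trajectory grid
  phase_grid <- (seq_along(theta$phase) - 1) / theta$sample_rate
  phase_traj <- approx(phase_grid, theta$phase, trajectory$times,
                       rule = 2)$y
  dt <- trajectory$dt
  cache <- new.env(parent = emptyenv())

  cell_fields <- function(i) {
    key <- as.character(i)
    if (!is.null(cache[[key]])) return(cache[[key]])
    Lm <- cells$L[i] / 100
    d2 <- (trajectory$x - cells$x[i])^2 + (trajectory$y - cells$y[i])^2
    mask <- d2 <= (Lm / 2)^2
    entry_arc <- rep(NA_real_, n)
    if (any(mask)) {
      starts <- which(mask & !c(FALSE, mask[-n]))
      run_id <- findInterval(seq_len(n), starts)
      entry_arc[mask] <- arc[starts][run_id[mask]]
    }
    res <- list(mask = mask, entry_arc = entry_arc, Lm = Lm)
    cache[[key]] <- res
    res
  }

  mod <- function(i, t) {
    fld <- cell_fields(i)
    idx <- pmin(pmax(round(t / dt) + 1, 1), n)
    out <- rep(1, length(t))
    inf <- fld$mask[idx]
    if (!any(inf)) return(out)
    ii <- idx[inf]
    l_m <- arc[ii] - fld$entry_arc[ii]
    l_frac <- pmin(l_m / fld$Lm, 1)
    phi_star <- 2 * pi * (1 - l_frac)
    # linear interpolation of the unwrapped phase between trajectory samples
    i0 <- pmin(pmax(floor(t[inf] / dt) + 1, 1), n - 1L)
    frac <- pmin(pmax(t[inf] / dt - (i0 - 1), 0), 1)
    phi <- (phase_traj[i0] + frac * (phase_traj[i0 + 1L] - phase_traj[i0])) %%
      (2 * pi)
    eps <- vsm[ii] / (fld$Lm * theta$f_theta)
    lam <- precession_factor(phi, phi_star, eps)
    if (renormalize) {
      sigma <- 2 * pi * eps
      mean_lambda <- sqrt(2 * pi) * eps * (2 * stats::pnorm(pi / sigma) - 1)
      lam <- pmin(lam / mean_lambda, max_multiplier)
    }
    out[inf] <- lam
    out
  }
  attr(mod, "max_multiplier") <- if (renormalize) max_multiplier else 1
  mod
}
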