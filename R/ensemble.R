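#' Specify a place-cell ensemble
#'
#' An ensemble of `N` place cells is characterised by the ensemble-mean peak
#' firing rate `f_mean` (Hz) and ensemble-mean place-field width `s_mean`
#' (cm, the Gaussian width of the rate map). Per-cell peak rates and field
#' widths are log-normally distributed around the ensemble means with
#' standard deviations proportional to the means: `sd(f) = a * f_mean`,
#' `sd(s) = b * s_mean`. With `dynamic_fields = TRUE` each cell's field
#' develops over time with a sigmoidal onset governed by a per-cell time
#' constant drawn log-normally around `tau_mean` seconds.
#'
#' @param N number of cells (>= 1).
#' @param f_mean mean peak rate, Hz. The calibrated sweep range is 4-40 Hz;
#'   values outside it are allowed with a warning.
#' @param s_mean mean field width, cm. Sweep range 5-30 cm, warning outside.
#' @param a,b relative spread of rates and widths (default 0.3 each).
#' @param dynamic_fields logical; fields develop from zero over ~4 minutes.
#' @param tau_mean mean field-formation time constant, seconds (default 240).
#' @param seed integer seed used by [sample_ensemble()].
#' @return object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(N, f_mean, s_mean, a = 0.3, b = 0.3,
                          dynamic_fields = FALSE, tau_mean = 240,
                          seed = 1L) {
  stopifnot(N >= 1, f_mean > 0, s_mean > 0, a >= 0, b >= 0, tau_mean > 0)
  if (f_mean < 4 || f_mean > 40)
    warning("f_mean outside the calibrated 4-40 Hz sweep range")
  if (s_mean < 5 || s_mean > 30)
    warning("s_mean outside the calibrated 5-30 cm sweep range")
  structure(
    list(N = as.integer(N), f_mean = f_mean, s_mean = s_mean, a = a, b = b,
         dynamic_fields = isTRUE(dynamic_fields), tau_mean = tau_mean,
         seed = as.integer(seed)),
    class = "ensemble_spec"
  )
}

# moment-matched log-normal: arithmetic mean m, arithmetic sd s
lognormal_params <- function(m, s) {
  if (m <= 0) stop("log-normal mean must be positive")
  if (!is.finite(s) || s < 0) stop("log-normal sd must be finite and >= 0")
  if (s == 0) return(list(meanlog = log(m), sdlog = 0))
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Sample a place-cell ensemble over an arena
#'
#' Draws per-cell peak rates and field widths from moment-matched log-normal
#' distributions, scatters field centres uniformly over the arena (excluding
#' holes), and, for dynamic ensembles, draws per-cell formation time
#' constants. Field extent is `L = 3 s` (cm).
#'
#' @param spec an [ensemble_spec()].
#' @param arena an [make_arena()] arena.
#' @param seed optional override of `spec$seed` (used to re-scatter centres
#'   between repeats while keeping the spec fixed).
#' @return object of class `place_ensemble`: data frame `cells` with columns
#'   `x`, `y` (m), `f` (Hz), `s` (cm), `L` (cm), `tau` (s), plus the spec.
#' @export
sample_ensemble <- function(spec, arena, seed = spec$seed) {
  stopifnot(inherits(spec, "ensemble_spec"), inherits(arena, "arena"))
  set.seed(seed)
  pf <- lognormal_params(spec$f_mean, spec$a * spec$f_mean)
  ps <- lognormal_params(spec$s_mean, spec$b * spec$s_mean)
  f <- rlnorm(spec$N, pf$meanlog, pf$sdlog)
  s <- rlnorm(spec$N, ps$meanlog, ps$sdlog)
  # centres uniform over the arena, rejection-sampled out of holes
  x <- numeric(spec$N); y <- numeric(spec$N)
  need <- seq_len(spec$N)
  while (length(need)) {
    x[need] <- runif(length(need), 0, arena$width)
    y[need] <- runif(length(need), 0, arena$height)
    need <- need[in_hole(arena, x[need], y[need])]
  }
  tau <- if (spec$dynamic_fields) {
    pt <- lognormal_params(spec$tau_mean, 0.3 * spec$tau_mean)
    rlnorm(spec$N, pt$meanlog, pt$sdlog)
  } else rep(NA_real_, spec$N)
  structure(
    list(cells = data.frame(x = x, y = y, f = f, s = s, L = 3 * s, tau = tau),
         spec = spec, seed = seed),
    class = "place_ensemble"
  )
}

#' @export
print.place_ensemble <- function(x, ...) {
  cat(sprintf(
    "place ensemble: N = %d, f_mean = %.3g Hz, s_mean = %.3g cm%s\n",
    x$spec$N, x$spec$f_mean, x$spec$s_mean,
    if (x$spec$dynamic_fields) sprintf(", dynamic (tau_mean = %g s)",
                                       x$spec$tau_mean) else ""))
  invisible(x)
}

# sigmoidal field-formation factor: ~0 at t = 0, midpoint tau/2, slope tau/8,
# so fields are essentially formed after ~tau seconds (about four minutes at
# the default tau = 240 s)
formation_factor <- function(t, tau) 1 / (1 + exp(-(t - tau / 2) / (tau / 8)))

# Background rate during field formation, Hz
BACKGROUND_RATE_HZ <- 0.1

#' Place-cell firing rate at a position (and time)
#'
#' Static fields: `lambda = f * exp(-d^2 / (2 s^2))` with `d` the distance to
#' the field centre (s converted from cm to m). Dynamic fields: both the
#' amplitude and the width follow a sigmoid in time starting near zero with
#' midpoint `2 tau` and slope `tau / 2`, plus a background rate of 0.1 Hz that
#' fades as the field forms.
#'
#' @param cell a one-row slice of `ensemble$cells` (or any list with `x`,
#'   `y`, `f`, `s` and, if dynamic, `tau`).
#' @param x,y position, metres (vectorised).
#' @param t time in seconds (vectorised or scalar; ignored when static).
#' @param dynamic logical; use the time-developing field.
#' @return firing rate(s) in Hz, always >= 0.
#' @export
firing_rate <- function(cell, x, y, t = 0, dynamic = FALSE) {
  d2 <- (x - cell$x)^2 + (y - cell$y)^2
  if (!dynamic) {
    sm <- cell$s / 100
    return(cell$f * exp(-d2 / (2 * sm^2)))
  }
  g <- formation_factor(t, cell$tau)
  sm <- pmax(cell$s * g, 1e-6) / 100
  cell$f * g * exp(-d2 / (2 * sm^2)) + BACKGROUND_RATE_HZ * (1 - g)
}
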