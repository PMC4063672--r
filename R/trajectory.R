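#' Generate a correlated-random-walk exploratory trajectory
#'
#' Emulates a rodent's exploratory path: an Ornstein-Uhlenbeck heading process
#' with speed jitter, reflected off the outer walls and off hole boundaries.
#' The path is sampled at a uniform step `dt` and never enters a hole or
#' leaves the arena. The same seed always reproduces the same path; within an
#' experiment the trajectory is generated once and held fixed across repeats.
#'
#' @param arena an [make_arena()] arena.
#' @param duration session length in seconds.
#' @param mean_speed mean running speed in cm/s (default 25).
#' @param dt time step in seconds (default 0.01).
#' @param seed integer seed.
#' @param heading_diffusion rotational diffusion of the heading in rad^2/s;
#'   controls path tortuosity (default 1.5).
#' @param speed_jitter relative speed fluctuation amplitude (default 0.2).
#' @return object of class `trajectory`: `times` (s), `x`, `y` (m), `dt`,
#'   `mean_speed` (cm/s), `seed`.
#' @export
generate_trajectory <- function(arena, duration, mean_speed = 25, dt = 0.01,
                                seed = 1L, heading_diffusion = 1.5,
                                speed_jitter = 0.2) {
  stopifnot(inherits(arena, "arena"), duration > 0, dt > 0, mean_speed > 0)
  v0 <- mean_speed / 100  # m/s
  vmax <- v0 * (1 + speed_jitter)
  min_hole_dim <- if (length(arena$holes)) {
    min(vapply(arena$holes, function(h) min(h[3] - h[1], h[4] - h[2]), 0))
  } else Inf
  if (vmax * dt > min_hole_dim)
    stop("dt too large for this speed: a single step could jump across a hole")

  n <- floor(duration / dt) + 1L
  set.seed(seed)
  x <- numeric(n); y <- numeric(n)
  # start at a valid point
  repeat {
    sx <- runif(1, 0, arena$width); sy <- runif(1, 0, arena$height)
    if (in_arena(arena, sx, sy)) break
  }
  x[1] <- sx; y[1] <- sy
  heading <- runif(1, 0, 2 * pi)
  dtheta <- rnorm(n, 0, sqrt(heading_diffusion * dt))
  # Ornstein-Uhlenbeck speed multiplier around 1
  sj <- numeric(n); sj[1] <- 0
  sj_noise <- rnorm(n, 0, speed_jitter * sqrt(2 * dt))
  for (i in 2:n) {
    heading <- heading + dtheta[i]
    sj[i] <- sj[i - 1] - sj[i - 1] * dt + sj_noise[i]
    v <- v0 * max(1 - speed_jitter, min(1 + speed_jitter, 1 + sj[i]))
    step <- v * dt
    nx <- x[i - 1] + step * cos(heading)
    ny <- y[i - 1] + step * sin(heading)
    if (!in_arena(arena, nx, ny)) {
      # try reflected headings; if all fail, stay put and randomise heading
      ok <- FALSE
      for (h2 in c(pi - heading, -heading, heading + pi,
                   runif(3, 0, 2 * pi))) {
        tx <- x[i - 1] + step * cos(h2)
        ty <- y[i - 1] + step * sin(h2)
        if (in_arena(arena, tx, ty)) {
          heading <- h2; nx <- tx; ny <- ty; ok <- TRUE
          break
        }
      }
      if (!ok) { nx <- x[i - 1]; ny <- y[i - 1]; heading <- runif(1, 0, 2 * pi) }
    }
    x[i] <- nx; y[i] <- ny
  }
  structure(
    list(times = (seq_len(n) - 1) * dt, x = x, y = y, dt = dt,
         duration = (n - 1L) * dt, mean_speed = mean_speed, seed = seed),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %.1f s at %.0f cm/s, dt = %g s (%d samples)\n",
              x$duration, x$mean_speed, x$dt, length(x$x)))
  invisible(x)
}

#' Fraction of occupancy-grid bins visited
#'
#' Diagnostic coverage measure: the arena (minus holes) is discretised into
#' square bins and the fraction of valid bins containing at least one
#' trajectory sample up to time `t` is reported.
#'
#' @param trajectory a [generate_trajectory()] object.
#' @param arena the arena it was generated in.
#' @param t time horizon in seconds (default: full duration).
#' @param bin_size occupancy bin side in metres (default 0.05).
#' @return fraction in `[0, 1]`.
#' @export
occupancy_fraction <- function(trajectory, arena, t = Inf, bin_size = 0.05) {
  keep <- trajectory$times <= t
  gx <- pmin(floor(trajectory$x[keep] / bin_size),
             ceiling(arena$width / bin_size) - 1)
  gy <- pmin(floor(trajectory$y[keep] / bin_size),
             ceiling(arena$height / bin_size) - 1)
  visited <- unique(gx + 1i * gy)
  nx <- ceiling(arena$width / bin_size); ny <- ceiling(arena$height / bin_size)
  cx <- (rep(seq_len(nx), ny) - 0.5) * bin_size
  cy <- (rep(seq_len(ny), each = nx) - 0.5) * bin_size
  valid <- !in_hole(arena, cx, cy)
  length(visited) / sum(valid)
}

#' Interpolate trajectory position at arbitrary times
#'
#' @param trajectory a trajectory.
#' @param t numeric vector of times within the session.
#' @return list with `x` and `y` (metres).
#' @export
position_at <- function(trajectory, t) {
  if (any(t < 0 | t > trajectory$duration + trajectory$dt))
    stop("times outside trajectory support")
  # uniform grid: direct linear interpolation
  n <- length(trajectory$x)
  i0 <- pmin(pmax(floor(t / trajectory$dt) + 1, 1), n - 1L)
  frac <- pmin(pmax(t / trajectory$dt - (i0 - 1), 0), 1)
  list(x = trajectory$x[i0] + frac * (trajectory$x[i0 + 1L] - trajectory$x[i0]),
       y = trajectory$y[i0] + frac * (trajectory$y[i0 + 1L] - trajectory$y[i0]))
}

# smoothed speed (m/s) on the trajectory grid, moving average over `window_s`
smoothed_speed <- function(trajectory, window_s = 0.2) {
  v <- c(0, sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2)) / trajectory$dt
  k <- max(1L, round(window_s / trajectory$dt))
  if (k > 1) {
    kern <- rep(1 / k, k)
    v <- stats::filter(v, kern, sides = 2)
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v <- as.numeric(v)
  }
  v
}

#' Time spent inside each region of a partition
#'
#' @param trajectory a trajectory.
#' @param regions list of regions from [partition_arena()].
#' @return numeric vector of occupancy times (s), one per region; sums to the
#'   session duration.
#' @export
region_occupancy <- function(trajectory, regions) {
  vapply(regions, function(r)
    sum(in_region(r, trajectory$x, trajectory$y)) * trajectory$dt, 0)
}
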