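#' Default coactivity-window scan grid
#'
#' 24 widths log-spaced over 0.1 to 5 theta-periods (12.5 ms to 625 ms).
#'
#' @param n number of widths.
#' @param range range in theta-periods.
#' @return numeric vector of widths in theta-periods.
#' @export
window_grid <- function(n = 24L, range = c(0.1, 5)) {
  exp(seq(base::log(range[1]), base::log(range[2]), length.out = n))
}

#' Scan coactivity-window widths for one ensemble
#'
#' Runs the repeated learning experiment at every window width and records
#' the convergence rate `rho(w)` and the mean learning time `T_min(w)`.
#' The same master seed (hence the same centre/spike seeds) is used at every
#' width, so curves differ only through the window.
#'
#' @param spec an [ensemble_spec()].
#' @param arena,trajectory,theta as in [run_learning_experiment()].
#' @param w_grid window widths in theta-periods (default [window_grid()]).
#' @param repeats repeats per width.
#' @param seed master seed.
#' @param horizon assessment horizon, seconds.
#' @return object of class `window_curve`: data frame `w` (theta-periods),
#'   `w_s_seconds`, `rho`, `t_min_mean`, `xi`.
#' @export
scan_windows <- function(spec, arena, trajectory, theta = NULL,
                         w_grid = window_grid(), repeats = 5L, seed = 1L,
                         horizon = min(trajectory$duration, 3600)) {
  if (length(w_grid) < 2) stop("w_grid needs at least two widths")
  rows <- lapply(w_grid, function(wtp) {
    res <- run_learning_experiment(
      spec, arena, trajectory, theta,
      window = coactivity_window(w = theta_periods_to_s(wtp)),
      repeats = repeats, seed = seed, horizon = horizon)
    data.frame(w = wtp, w_seconds = theta_periods_to_s(wtp),
               rho = res$rho, t_min_mean = res$t_min_mean, xi = res$xi)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("window_curve", "data.frame")
  out
}

#' Opening window width
#'
#' The smallest window width at which the ensemble begins to produce the
#' correct topological signature (`rho > 0`).
#'
#' @param curve a [scan_windows()] curve.
#' @return width in theta-periods, or `NA` (with a warning) if no width
#'   converges.
#' @export
opening_width <- function(curve) {
  idx <- which(curve$rho > 0)
  if (length(idx) == 0) {
    warning("no window width converged; opening width undefined")
    return(NA_real_)
  }
  curve$w[min(idx)]
}

#' Stabilization window width
#'
#' The smallest width from which successive relative changes of the mean
#' learning time stay below `rel_tol` across the converged part of the curve
#' (up to the failure region where convergence is lost again).
#'
#' @param curve a [scan_windows()] curve.
#' @param rel_tol plateau tolerance on successive relative changes
#'   (default 0.1).
#' @return width in theta-periods, or `NA` (with a warning) if fewer than 3
#'   converged widths or no plateau exists.
#' @export
stabilization_width <- function(curve, rel_tol = 0.1) {
  conv <- which(!is.na(curve$t_min_mean) & curve$rho > 0)
  if (length(conv) < 3) {
    warning("need at least 3 converged widths for a plateau")
    return(NA_real_)
  }
  tm <- curve$t_min_mean[conv]
  relchg <- abs(diff(tm)) / pmax(head(tm, -1), .Machine$double.eps)
  # smallest index from which all successive changes stay below tolerance
  ok_from <- which(rev(cummax(rev(relchg))) < rel_tol)
  if (length(ok_from) == 0) {
    warning("no plateau found at tolerance ", rel_tol)
    return(NA_real_)
  }
  curve$w[conv[min(ok_from)]]
}

#' Power-law fit of the learning-time/window-width relation
#'
#' Tests the inverse power-law hypothesis `T_min(w) = C / w^alpha` by
#' computing the product `T_min(w) * w^alpha` across the converged widths
#' for each candidate `alpha` and reporting the value that minimises the
#' coefficient of variation of the product.
#'
#' @param curve a [scan_windows()] curve.
#' @param alpha_grid candidate exponents (default 12 values spanning the
#'   open interval (1, 2)).
#' @param min_points minimal number of converged widths (default 5).
#' @return list: `alpha_star`, `cv` (per-alpha coefficient of variation),
#'   `alpha_grid`, `degenerate` (TRUE when the curve is flat and the
#'   minimiser sits at the grid edge).
#' @export
power_law_fit <- function(curve, alpha_grid = seq(1.05, 1.95,
                                                  length.out = 12),
                          min_points = 5L) {
  conv <- which(!is.na(curve$t_min_mean) & curve$rho > 0)
  if (length(conv) < min_points)
    stop("need at least ", min_points, " converged widths")
  w <- curve$w[conv]; tm <- curve$t_min_mean[conv]
  cv <- vapply(alpha_grid, function(a) {
    prod <- tm * w^a
    sd(prod) / mean(prod)
  }, 0)
  i <- which.min(cv)
  list(alpha_star = alpha_grid[i], cv = cv, alpha_grid = alpha_grid,
       degenerate = (i == 1L || i == length(alpha_grid)) &&
         (max(tm) - min(tm)) / mean(tm) < 1e-9)
}
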