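#' Resample place-field centres, keeping rates and widths fixed
#'
#' Between simulation repeats the trajectory and per-cell rate/width draws
#' are held fixed while the field centres are re-scattered over the arena.
#'
#' @param ensemble a [sample_ensemble()] object.
#' @param arena the arena.
#' @param seed integer seed for the new centres.
#' @return a `place_ensemble` with new `x`, `y`.
#' @export
resample_centers <- function(ensemble, arena, seed) {
  set.seed(seed)
  n <- nrow(ensemble$cells)
  x <- numeric(n); y <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x[need] <- runif(length(need), 0, arena$width)
    y[need] <- runif(length(need), 0, arena$height)
    need <- need[in_hole(arena, x[need], y[need])]
  }
  ensemble$cells$x <- x
  ensemble$cells$y <- y
  ensemble$seed <- seed
  ensemble
}

#' Run one end-to-end map-formation simulation
#'
#' Generates spike trains for a given ensemble over a trajectory (with
#' optional theta-precession modulation), bins them into coactivity events,
#' assembles the temporal complex, computes its persistence barcode and
#' derives the learning outcome against the arena's true topology.
#'
#' @param ensemble a sampled `place_ensemble`.
#' @param arena the arena.
#' @param trajectory the session trajectory.
#' @param theta `NULL` (theta off) or a [make_theta()] signal.
#' @param window a [coactivity_window()].
#' @param horizon assessment horizon, seconds (default: session length,
#'   capped at 3600 s).
#' @param seed spike-generation seed.
#' @param max_complex_dim simplex dimension cap (default 2: enough for
#'   components and 1D loops).
#' @param min_spikes spikes per cell per bin required for coactivity
#'   (default 1; use 2 to burst-gate the read-out, e.g. to reject the 0.1 Hz
#'   stochastic background of still-forming place fields).
#' @return list with `outcome` ([detect_tmin()] result), `loops`
#'   ([loop_stats()]), `eta` (connectivity indices at `T_min`, or at the
#'   horizon when not converged), `barcode`, `complex`, `spikes`.
#' @export
run_learning <- function(ensemble, arena, trajectory, theta = NULL,
                         window = coactivity_window(),
                         horizon = min(trajectory$duration, 3600),
                         seed = 1L, max_complex_dim = 2L, min_spikes = 1L) {
  if (horizon > trajectory$duration + 1e-9)
    stop("horizon exceeds the session length")
  modulation <- if (!is.null(theta))
    precession_modulation(ensemble, trajectory, theta) else NULL
  spikes <- generate_spikes(ensemble, trajectory, modulation, seed = seed)
  events <- detect_coactivity(spikes, window, min_spikes = min_spikes)
  complex <- build_complex(events, max_dim = max_complex_dim)
  barcode <- compute_barcode(complex, max_dim = 1L)
  outcome <- detect_tmin(barcode, arena$true_betti, horizon)
  loops <- loop_stats(barcode, arena$true_betti, horizon)
  t_eval <- if (outcome$converged) outcome$t_min else horizon
  fv <- f_vector(complex, t_eval, N = ensemble$spec$N)
  list(outcome = outcome, loops = loops,
       eta = c(eta1 = fv$eta[2],
               eta2 = if (length(fv$eta) >= 3) fv$eta[3] else NA_real_),
       barcode = barcode, complex = complex, spikes = spikes)
}

#' Repeat a learning experiment and summarise convergence statistics
#'
#' The trajectory and the per-cell rate/width draws stay fixed across
#' repeats; field centres are re-scattered and new spike trains are drawn
#' each repeat. Reports the convergence rate `rho` (fraction of repeats that
#' converged), the mean learning time over converged repeats, and its
#' relative variability `xi = sd(T_min) / mean(T_min)`.
#'
#' @param spec an [ensemble_spec()].
#' @param arena the arena.
#' @param trajectory the (fixed) session trajectory.
#' @param theta `NULL` or a theta signal.
#' @param window a [coactivity_window()].
#' @param repeats number of repeats (>= 1).
#' @param seed master seed for this experiment; per-repeat centre and spike
#'   seeds are derived with [child_seeds()].
#' @param horizon assessment horizon, seconds.
#' @param keep_runs keep the per-repeat `run_learning` outputs (memory-heavy).
#' @return object of class `ensemble_result`: the spec coordinates, vectors
#'   `t_min` and `converged` per repeat, `rho`, `t_min_mean`, `xi`, mean
#'   `eta1`/`eta2` over converged repeats, pooled spurious-loop `durations`,
#'   and per-repeat `mean_live`/`max_live` loop counts.
#' @export
run_learning_experiment <- function(spec, arena, trajectory, theta = NULL,
                                    window = coactivity_window(),
                                    repeats = 10L, seed = 1L,
                                    horizon = min(trajectory$duration, 3600),
                                    keep_runs = FALSE, min_spikes = 1L) {
  stopifnot(repeats >= 1)
  base <- sample_ensemble(spec, arena, seed = child_seeds(seed, SALT_ENSEMBLE))
  cseeds <- child_seeds(seed, SALT_REPEAT, repeats)
  sseeds <- child_seeds(seed, SALT_SPIKES, repeats)
  runs <- vector("list", repeats)
  t_min <- rep(NA_real_, repeats)
  conv <- logical(repeats)
  eta1 <- rep(NA_real_, repeats); eta2 <- rep(NA_real_, repeats)
  mean_live <- numeric(repeats); max_live <- integer(repeats)
  durations <- list()
  for (r in seq_len(repeats)) {
    ens <- resample_centers(base, arena, cseeds[r])
    run <- run_learning(ens, arena, trajectory, theta, window,
                        horizon = horizon, seed = sseeds[r],
                        min_spikes = min_spikes)
    conv[r] <- run$outcome$converged
    if (conv[r]) {
      t_min[r] <- run$outcome$t_min
      eta1[r] <- run$eta[["eta1"]]
      eta2[r] <- run$eta[["eta2"]]
    }
    mean_live[r] <- run$loops$mean_live
    max_live[r] <- run$loops$max_live
    durations[[r]] <- run$loops$durations[!run$loops$censored]
    if (keep_runs) runs[[r]] <- run
  }
  tt <- t_min[conv]
  structure(
    list(N = spec$N, f = spec$f_mean, s = spec$s_mean,
         t_min = t_min, converged = conv,
         rho = mean(conv),
         t_min_mean = if (length(tt)) mean(tt) else NA_real_,
         xi = if (length(tt) >= 2 && mean(tt) > 0) sd(tt) / mean(tt)
              else NA_real_,
         eta1 = mean(eta1, na.rm = TRUE), eta2 = mean(eta2, na.rm = TRUE),
         loop_durations = unlist(durations, use.names = FALSE),
         mean_live = mean_live, max_live = max_live,
         runs = if (keep_runs) runs else NULL),
    class = "ensemble_result"
  )
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf(
    "ensemble (N=%d, f=%.3g Hz, s=%.3g cm): rho = %.2f, T_min = %.1f s, xi = %.2f\n",
    x$N, x$f, x$s, x$rho, x$t_min_mean, x$xi))
  invisible(x)
}

#' The default learning-region sweep grid
#'
#' 19 ensemble sizes from 50 to 500 cells, 10 mean rates from 4 to 40 Hz and
#' 9 mean field widths from 5 to 30 cm, linearly spaced: 1710 ensembles.
#'
#' @param N,f,s value vectors for each axis.
#' @return data frame with one row per `(N, f, s)` combination.
#' @export
sweep_grid <- function(N = seq(50, 500, length.out = 19),
                       f = seq(4, 40, length.out = 10),
                       s = seq(5, 30, length.out = 9)) {
  grid <- expand.grid(N = as.integer(round(N)), f = f, s = s,
                      KEEP.OUT.ATTRS = FALSE)
  grid[order(grid$N, grid$f, grid$s), , drop = FALSE]
}

#' Run a learning-region parameter sweep
#'
#' Runs [run_learning_experiment()] for every `(N, f, s)` row of a grid on a
#' fixed trajectory, with deterministic per-row seeds derived from the
#' master seed, and returns one tidy row per ensemble.
#'
#' @param grid a [sweep_grid()]-style data frame.
#' @param arena,trajectory,theta,window,repeats,horizon as in
#'   [run_learning_experiment()].
#' @param seed master seed.
#' @param a,b,dynamic_fields forwarded to [ensemble_spec()].
#' @param progress print one line per ensemble.
#' @return data frame: `N`, `f`, `s`, `rho`, `t_min_mean`, `xi`, `eta1`,
#'   `eta2`, `mean_live`, `max_live`, `n_loop_durations`; the pooled
#'   spurious-loop durations are attached as attribute `loop_durations`
#'   (list column-free tidy export via [write_sweep_csv()]).
#' @export
run_sweep <- function(grid, arena, trajectory, theta = NULL,
                      window = coactivity_window(), repeats = 10L,
                      seed = 1L, horizon = min(trajectory$duration, 3600),
                      a = 0.3, b = 0.3, dynamic_fields = FALSE,
                      progress = FALSE) {
  rows <- vector("list", nrow(grid))
  seeds <- child_seeds(seed, SALT_REPEAT, nrow(grid))
  durations <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    spec <- ensemble_spec(grid$N[i], grid$f[i], grid$s[i], a = a, b = b,
                          dynamic_fields = dynamic_fields)
    res <- run_learning_experiment(spec, arena, trajectory, theta, window,
                                   repeats = repeats, seed = seeds[i],
                                   horizon = horizon)
    rows[[i]] <- data.frame(
      N = res$N, f = res$f, s = res$s, rho = res$rho,
      t_min_mean = res$t_min_mean, xi = res$xi,
      eta1 = res$eta1, eta2 = res$eta2,
      mean_live = mean(res$mean_live), max_live = max(res$max_live),
      n_loop_durations = length(res$loop_durations))
    durations[[i]] <- res$loop_durations
    if (progress)
      message(sprintf("[%d/%d] N=%d f=%.3g s=%.3g rho=%.2f Tmin=%.0f s",
                      i, nrow(grid), res$N, res$f, res$s, res$rho,
                      res$t_min_mean))
  }
  out <- do.call(rbind, rows)
  attr(out, "loop_durations") <- durations
  out
}
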