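#' Generate inhomogeneous Poisson spike trains along a trajectory
#'
#' Each cell fires as an inhomogeneous Poisson process whose rate is its
#' place-field rate map evaluated at the animal's current position,
#' optionally multiplied by a time-varying modulation factor in `[0, 1]`
#' (e.g. the theta-precession factor from [precession_modulation()]).
#' Spikes are drawn by thinning against the cell's peak rate.
#'
#' @param ensemble a [sample_ensemble()] object.
#' @param trajectory a [generate_trajectory()] object.
#' @param modulation `NULL`, or a function `(cell_index, times) -> multiplier`
#'   vectorised over `times`, with values in `[0, max_multiplier]` where
#'   `max_multiplier` is an attribute of the function (default 1, i.e. a
#'   `[0, 1]` thinning factor).
#' @param seed integer seed.
#' @param dynamic logical; use time-developing fields (defaults to the
#'   ensemble spec's `dynamic_fields`).
#' @return object of class `spike_train_set`: `spikes` (list of sorted spike
#'   time vectors, one per cell), `duration` (s), `n_cells`, `provenance`.
#' @export
generate_spikes <- function(ensemble, trajectory, modulation = NULL,
                            seed = 1L,
                            dynamic = ensemble$spec$dynamic_fields) {
  stopifnot(inherits(ensemble, "place_ensemble"),
            inherits(trajectory, "trajectory"))
  if (length(trajectory$x) < 2) stop("empty trajectory")
  cells <- ensemble$cells
  duration <- trajectory$duration
  mod_max <- if (is.null(modulation)) 1 else
    (attr(modulation, "max_multiplier") %||% 1)
  set.seed(seed)
  spikes <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    rate_max <- cell$f + if (dynamic) BACKGROUND_RATE_HZ else 0
    n_cand <- rpois(1, rate_max * mod_max * duration)
    if (n_cand == 0) { spikes[[i]] <- numeric(0); next }
    tc <- sort(runif(n_cand, 0, duration))
    # stage 1: thin against the place-field rate map (bound rate_max)
    pos <- position_at(trajectory, tc)
    lam <- firing_rate(cell, pos$x, pos$y, tc, dynamic = dynamic)
    tc <- tc[runif(n_cand) < lam / rate_max]
    # stage 2: thin against the modulation factor (bound mod_max)
    if (!is.null(modulation) && length(tc)) {
      m <- modulation(i, tc)
      if (any(m < -1e-9 | m > mod_max + 1e-9))
        stop("modulation values must be in [0, ", mod_max, "]")
      tc <- tc[runif(length(tc)) < pmin(pmax(m, 0), mod_max) / mod_max]
    }
    spikes[[i]] <- tc
  }
  structure(
    list(spikes = spikes, duration = duration, n_cells = nrow(cells),
         provenance = list(ensemble_seed = ensemble$seed, spike_seed = seed,
                           trajectory_seed = trajectory$seed,
                           dynamic = dynamic)),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("spike trains: %d cells, %d spikes over %.1f s\n",
              x$n_cells, sum(lengths(x$spikes)), x$duration))
  invisible(x)
}

#' Flatten a spike-train set into a tidy table
#'
#' @param spikes a `spike_train_set`.
#' @return data frame with columns `cell_id`, `spike_time_s`, sorted by cell
#'   then time.
#' @export
spike_table <- function(spikes) {
  data.frame(
    cell_id = rep(seq_along(spikes$spikes), lengths(spikes$spikes)),
    spike_time_s = as.numeric(unlist(spikes$spikes, use.names = FALSE))
  )
}

#' Spatial information rate of the spikes fired in a time interval
#'
#' Skaggs-style spatial information of the ensemble activity on an occupancy
#' grid, reported as an information *rate* (bits/s, i.e. bits/spike weighted
#' by the firing rate). The rate form is the meaningful monotone diagnostic
#' of field formation: a half-formed, very narrow field emits few spikes that
#' are individually highly informative, so bits/spike can decrease while the
#' map is still improving, whereas bits/s grows as fields gain both rate and
#' spatial structure.
#'
#' @param spikes a `spike_train_set`.
#' @param trajectory the trajectory the spikes were generated on.
#' @param t0,t1 interval bounds in seconds.
#' @param bin_size spatial bin in metres.
#' @param per_spike return bits/spike instead of bits/s.
#' @return mean per-cell spatial information (NA if no spikes).
#' @export
spatial_information <- function(spikes, trajectory, t0 = 0, t1 = Inf,
                                bin_size = 0.1, per_spike = FALSE) {
  keep_t <- trajectory$times >= t0 & trajectory$times <= t1
  if (!any(keep_t)) return(NA_real_)
  gx <- floor(trajectory$x[keep_t] / bin_size)
  gy <- floor(trajectory$y[keep_t] / bin_size)
  occ_key <- paste(gx, gy)
  occ <- table(occ_key)
  p_occ <- as.numeric(occ) / sum(occ)
  info <- vapply(spikes$spikes, function(st) {
    st <- st[st >= t0 & st <= t1]
    if (length(st) < 2) return(NA_real_)
    pos <- position_at(trajectory, st)
    key <- paste(floor(pos$x / bin_size), floor(pos$y / bin_size))
    cnt <- table(factor(key, levels = names(occ)))
    lam <- as.numeric(cnt) / (as.numeric(occ) * trajectory$dt)
    lbar <- sum(p_occ * lam)
    if (lbar <= 0) return(NA_real_)
    ok <- lam > 0
    bits_per_spike <- sum(p_occ[ok] * (lam[ok] / lbar) * log2(lam[ok] / lbar))
    if (per_spike) bits_per_spike else bits_per_spike * lbar
  }, 0)
  mean(info, na.rm = TRUE)
}
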