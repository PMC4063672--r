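#' Restrict spikes to an arena region on the region's own clock
#'
#' Keeps only the spikes emitted while the animal is inside the region, and
#' converts session time to the region's learning clock, which accumulates
#' only in-region time. The region-restricted spike set can then be fed
#' through the usual binning/complex/persistence pipeline, so the region is
#' "learned" on its own occupancy time.
#'
#' @param spikes a `spike_train_set`.
#' @param trajectory the session trajectory.
#' @param region a region from [partition_arena()].
#' @param min_extent_cm warn when the region is narrower than this (regions
#'   much smaller than 2-3 place-field extents cannot carry a meaningful
#'   map); default `NULL` skips the check.
#' @return a `spike_train_set` on the region clock, with `duration` the
#'   total in-region time and extra fields `region_id` and `occupancy_s`.
#'   `NULL` (with a warning) when the region was never visited.
#' @export
restrict_to_region <- function(spikes, trajectory, region,
                               min_extent_cm = NULL) {
  stopifnot(inherits(region, "arena_region"))
  if (!is.null(min_extent_cm)) {
    width_cm <- (region$rect[3] - region$rect[1]) * 100
    if (width_cm < min_extent_cm)
      warning(sprintf("region %d is %.0f cm wide, below the ~%.0f cm floor",
                      region$id, width_cm, min_extent_cm))
  }
  mask <- in_region(region, trajectory$x, trajectory$y)
  occ <- sum(mask) * trajectory$dt
  if (occ == 0) {
    warning("region ", region$id, " has zero occupancy")
    return(NULL)
  }
  # region clock: cumulative in-region time at each trajectory sample
  clock <- cumsum(mask) * trajectory$dt
  n <- length(trajectory$x)
  restricted <- lapply(spikes$spikes, function(st) {
    if (length(st) == 0) return(numeric(0))
    idx <- pmin(pmax(round(st / trajectory$dt) + 1, 1), n)
    keep <- mask[idx]
    sort(clock[idx[keep]])
  })
  structure(
    list(spikes = restricted, duration = occ, n_cells = spikes$n_cells,
         provenance = c(spikes$provenance, list(region_id = region$id)),
         region_id = region$id, occupancy_s = occ),
    class = "spike_train_set"
  )
}

#' Piecewise (Mayer-Vietoris) learning over an arena partition
#'
#' Computes the learning time of each region on the region's own occupancy
#' clock, against the region's own true Betti numbers, and compares the
#' summed per-region learning times with the whole-arena learning time.
#' When the partition's pairwise intersections are topologically trivial,
#' per-region homologies add up to the whole-arena homology, so the whole
#' map can be learned piece by piece.
#'
#' Restriction is performed at the coactivity-bin level: the session is
#' binned once, each bin is attributed to the region containing the
#' animal's position at the bin midpoint, and the bin's birth time is the
#' region's accumulated occupancy at that moment. Restricting whole bins
#' (rather than raw spike times) avoids artificial coactivity between cells
#' observed on different visits that would become adjacent if disjoint
#' visits were spliced together on the region clock.
#'
#' @param arena the arena.
#' @param partition regions from [partition_arena()].
#' @param spikes session spike trains.
#' @param trajectory the session trajectory.
#' @param window a [coactivity_window()].
#' @param whole_outcome optional precomputed whole-arena
#'   [detect_tmin()] outcome (recomputed from `spikes` if `NULL`).
#' @param max_complex_dim simplex dimension cap.
#' @return list: `regions` data frame (`id`, `occupancy_s`, `true_beta1`,
#'   `converged`, `t_min`), `t_min_sum`, `whole_t_min`, `additivity_gap`
#'   (`t_min_sum - whole_t_min`, NA when any part is nonconvergent).
#' @export
piecewise_learning <- function(arena, partition, spikes, trajectory,
                               window = coactivity_window(),
                               whole_outcome = NULL,
                               max_complex_dim = 2L) {
  events <- detect_coactivity(spikes, window)
  mid <- pmin(events$bin_times + window$w / 2, trajectory$duration)
  pos <- position_at(trajectory, mid)
  n <- length(trajectory$x)
  region_rows <- lapply(partition, function(reg) {
    mask_traj <- in_region(reg, trajectory$x, trajectory$y)
    occ <- sum(mask_traj) * trajectory$dt
    keep <- in_region(reg, pos$x, pos$y)
    if (occ == 0 || !any(keep))
      return(data.frame(id = reg$id, occupancy_s = occ, true_beta1 =
                          reg$true_betti[2], converged = FALSE,
                        t_min = NA_real_))
    clock <- cumsum(mask_traj) * trajectory$dt
    idx <- pmin(pmax(round(mid[keep] / trajectory$dt) + 1, 1), n)
    revents <- structure(list(bin_times = clock[idx],
                              cells = events$cells[keep]),
                         class = "coactivity_events")
    cx <- build_complex(revents, max_dim = max_complex_dim)
    bc <- compute_barcode(cx, max_dim = 1L)
    out <- detect_tmin(bc, reg$true_betti, horizon = occ)
    data.frame(id = reg$id, occupancy_s = occ,
               true_beta1 = reg$true_betti[2],
               converged = out$converged, t_min = out$t_min)
  })
  regions <- do.call(rbind, region_rows)
  if (is.null(whole_outcome)) {
    cx <- build_complex(events, max_dim = max_complex_dim)
    bc <- compute_barcode(cx, max_dim = 1L)
    whole_outcome <- detect_tmin(bc, arena$true_betti,
                                 horizon = spikes$duration)
  }
  t_min_sum <- if (all(regions$converged)) sum(regions$t_min) else NA_real_
  whole_t_min <- if (whole_outcome$converged) whole_outcome$t_min else
    NA_real_
  list(regions = regions, t_min_sum = t_min_sum, whole_t_min = whole_t_min,
       additivity_gap = t_min_sum - whole_t_min)
}
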