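#' Specify a coactivity integration window
#'
#' A read-out neuron integrates its presynaptic spike trains over a window of
#' width `w` seconds: cells that fire within the same window are treated as
#' coactive. The session is partitioned into consecutive bins of width `w`;
#' the bin grid may be shifted by a fraction of `w`, and the interior bin
#' edges may be jittered by a seeded uniform perturbation, to probe the
#' (in)sensitivity of the learning time to bin placement.
#'
#' @param w window width in seconds (default two theta-periods, 0.25 s).
#' @param bin_shift shift of the bin grid as a fraction of `w` in `[0, 1)`.
#' @param jitter maximal edge jitter as a fraction of `w` in `[0, 0.5]`.
#' @param jitter_seed integer seed for the jitter draw.
#' @return object of class `coactivity_window`.
#' @export
coactivity_window <- function(w = 2 * THETA_PERIOD_S, bin_shift = 0,
                              jitter = 0, jitter_seed = 1L) {
  if (w <= 0) stop("window width w must be positive")
  stopifnot(bin_shift >= 0, bin_shift < 1, jitter >= 0, jitter <= 0.5)
  structure(list(w = w, bin_shift = bin_shift, jitter = jitter,
                 jitter_seed = as.integer(jitter_seed)),
            class = "coactivity_window")
}

#' Detect per-bin coactive cell groups
#'
#' Partitions the session into consecutive bins of width `w` (with optional
#' shift and jitter) and reports, for every bin containing spikes from at
#' least `min_cells` cells, the set of cells with at least `min_spikes`
#' spikes in that bin.
#'
#' @param spikes a `spike_train_set` (or a bare list of spike-time vectors
#'   plus a `duration` attribute).
#' @param window a [coactivity_window()].
#' @param min_spikes spikes per cell per bin required to count the cell as
#'   active (default 1).
#' @param min_cells minimal group size for a bin to be reported (default 1,
#'   so lone active cells still contribute vertices).
#' @return object of class `coactivity_events`: `bin_times` (bin start
#'   times, s) and `cells` (list of sorted integer vectors).
#' @export
detect_coactivity <- function(spikes, window = coactivity_window(),
                              min_spikes = 1L, min_cells = 1L) {
  stopifnot(inherits(window, "coactivity_window"))
  duration <- spikes$duration
  w <- window$w
  edges <- seq(-window$bin_shift * w, duration + w, by = w)
  if (window$jitter > 0 && length(edges) > 2) {
    set.seed(window$jitter_seed)
    interior <- seq(2, length(edges) - 1)
    edges[interior] <- edges[interior] +
      runif(length(interior), -window$jitter * w, window$jitter * w)
    edges <- sort(edges)
  }
  nb <- length(edges) - 1L
  # (bin, cell) incidence with spike counts
  cell_id <- rep(seq_along(spikes$spikes), lengths(spikes$spikes))
  st <- unlist(spikes$spikes, use.names = FALSE)
  if (length(st) == 0)
    return(structure(list(bin_times = numeric(0), cells = list()),
                     class = "coactivity_events"))
  bin <- findInterval(st, edges, rightmost.closed = FALSE)
  ok <- bin >= 1 & bin <= nb
  bin <- bin[ok]; cell_id <- cell_id[ok]
  key <- paste(bin, cell_id)
  if (min_spikes > 1) {
    cnt <- table(key)
    keep_key <- names(cnt)[cnt >= min_spikes]
    sel <- !duplicated(key) & key %in% keep_key
  } else {
    sel <- !duplicated(key)
  }
  bin <- bin[sel]; cell_id <- cell_id[sel]
  o <- order(bin, cell_id)
  bin <- bin[o]; cell_id <- cell_id[o]
  groups <- split(cell_id, bin)
  sizes <- lengths(groups)
  keep <- sizes >= min_cells
  groups <- groups[keep]
  bt <- pmax(edges[as.integer(names(groups))], 0)
  structure(list(bin_times = as.numeric(bt), cells = unname(groups)),
            class = "coactivity_events")
}

#' @export
print.coactivity_events <- function(x, ...) {
  cat(sprintf("coactivity events: %d occupied bins, largest group %d cells\n",
              length(x$cells),
              if (length(x$cells)) max(lengths(x$cells)) else 0L))
  invisible(x)
}

#' Assemble the time-filtered coactivity simplicial complex
#'
#' Every group of `k + 1 <= max_dim + 1` cells observed coactive in a bin
#' contributes a `k`-simplex (and all of its faces), with birth time the
#' earliest bin in which that exact cell subset was jointly active. The
#' result is a filtered simplicial complex: faces are born no later than
#' their cofaces, and the complex grows monotonically with time.
#'
#' @param events [detect_coactivity()] output (bins must be time-sorted).
#' @param max_dim simplex dimension cap (default 3; use 2 when only
#'   connectivity and 1D loops are analysed downstream).
#' @return object of class `temporal_complex`: data frame `simplices` with
#'   columns `dim`, `birth`, `v1..v4` (0 = unused), sorted by
#'   `(birth, dim)`; plus `vertices` (ids present) and `max_dim`.
#' @export
build_complex <- function(events, max_dim = 3L) {
  stopifnot(inherits(events, "coactivity_events"))
  if (is.unsorted(events$bin_times)) stop("events must be time-sorted")
  if (length(events$cells) == 0) {
    simp <- data.frame(dim = integer(0), birth = numeric(0),
                       v1 = integer(0), v2 = integer(0),
                       v3 = integer(0), v4 = integer(0))
    return(structure(list(simplices = simp, vertices = integer(0),
                          max_dim = as.integer(max_dim)),
                     class = "temporal_complex"))
  }
  res <- cpp_collect_simplices(events$cells, events$bin_times,
                               as.integer(max_dim))
  o <- order(res$birth, res$dim)
  simp <- data.frame(dim = res$dim[o], birth = res$birth[o],
                     v1 = res$verts[o, 1], v2 = res$verts[o, 2],
                     v3 = res$verts[o, 3], v4 = res$verts[o, 4])
  structure(list(simplices = simp,
                 vertices = sort(unique(simp$v1[simp$dim == 0])),
                 max_dim = as.integer(max_dim)),
            class = "temporal_complex")
}

#' @export
print.temporal_complex <- function(x, ...) {
  fv <- f_vector(x, t = Inf)
  cat(sprintf("temporal complex: %d vertices, f-vector (%s)\n",
              length(x$vertices),
              paste(fv$f, collapse = ", ")))
  invisible(x)
}

#' f-vector and connectivity indices of the complex at a time
#'
#' Counts simplices of each dimension with birth time `<= t`. When the
#' ensemble size `N` is supplied, the connectivity indices
#' `eta_n = f_n / choose(N, n + 1)` are reported: the fraction of all
#' possible `(n+1)`-cell groups realised as simplices.
#'
#' @param complex a [build_complex()] object.
#' @param t time in seconds (`Inf` for the saturated complex).
#' @param N ensemble size; must be at least the number of vertices present.
#' @return list with `t`, `f` (counts for dims `0..max_dim`) and, if `N`
#'   given, `eta`.
#' @export
f_vector <- function(complex, t = Inf, N = NULL) {
  stopifnot(inherits(complex, "temporal_complex"), t >= 0 || t == Inf)
  sel <- complex$simplices$birth <= t
  f <- vapply(0:complex$max_dim,
              function(d) sum(complex$simplices$dim[sel] == d), 0L)
  out <- list(t = t, f = f)
  if (!is.null(N)) {
    if (N < length(complex$vertices))
      stop("N smaller than the number of vertices present in the complex")
    out$eta <- f / choose(N, seq_along(f))
  }
  out
}

#' Time course of the connectivity indices
#'
#' @param complex a `temporal_complex`.
#' @param times evaluation times (s).
#' @param N ensemble size.
#' @return data frame with `t`, `eta1`, `eta2`.
#' @export
eta_curve <- function(complex, times, N) {
  rows <- lapply(times, function(t) {
    fv <- f_vector(complex, t, N)
    data.frame(t = t, eta1 = fv$eta[2],
               eta2 = if (length(fv$eta) >= 3) fv$eta[3] else NA_real_)
  })
  do.call(rbind, rows)
}
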