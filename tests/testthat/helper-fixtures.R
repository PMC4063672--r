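# Shared lightweight fixtures, memoised per test session.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_cache[[name]]))
    .fixture_cache[[name]] <- builder()
  .fixture_cache[[name]]
}

one_hole_arena <- function() {
  fixture("arena1", function()
    make_arena(1, 1, holes = list(c(0.35, 0.35, 0.65, 0.65))))
}

# a 5-minute reference trajectory for cheap unit tests
short_trajectory <- function() {
  fixture("traj300", function()
    generate_trajectory(one_hole_arena(), 300, seed = 42))
}

# straight constant-speed pass through the arena centre on a hole-free arena,
# for closed-form oracles (path integrals, phase regression)
straight_pass <- function(duration = 4, v = 0.25, dt = 0.01) {
  n <- floor(duration / dt) + 1L
  tt <- (seq_len(n) - 1) * dt
  structure(
    list(times = tt, x = 0.05 + v * tt, y = rep(0.5, n), dt = dt,
         duration = (n - 1L) * dt, mean_speed = v * 100, seed = 0L),
    class = "trajectory"
  )
}

# one-cell ensemble with prescribed parameters at a given position
single_cell_ensemble <- function(x, y, f, s, N = 1L, arena = NULL) {
  spec <- suppressWarnings(ensemble_spec(N, f, s))
  structure(
    list(cells = data.frame(x = x, y = y, f = f, s = s, L = 3 * s,
                            tau = NA_real_),
         spec = spec, seed = 0L),
    class = "place_ensemble"
  )
}

# barcode constructed directly from intervals, for outcome-logic tests
manual_barcode <- function(dim, birth, death, max_dim = 1L) {
  structure(data.frame(dim = dim, birth = birth, death = death),
            class = c("barcode", "data.frame"), max_dim = max_dim)
}
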