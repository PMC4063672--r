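events_from <- function(times, groups) {
  structure(list(bin_times = as.numeric(times),
                 cells = lapply(groups, as.integer)),
            class = "coactivity_events")
}

test_that("hand-reduced barcodes: cycle, tree, filled triangle", {
  # 4-cycle: edges appear at t = 1..4, never filled -> one open 1D bar at 4
  ev <- events_from(1:4, list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  bc <- compute_barcode(build_complex(ev), max_dim = 1)
  loops <- bc[bc$dim == 1, ]
  expect_identical(nrow(loops), 1L)
  expect_equal(loops$birth, 4)
  expect_identical(loops$death, Inf)
  expect_identical(betti_at(bc, 4), c(1L, 1L))

  # tree on 5 vertices: 5 components merging to 1, no loops
  ev <- events_from(1:5, list(1, c(1, 2), c(2, 3), c(2, 4), c(4, 5)))
  bc <- compute_barcode(build_complex(ev), max_dim = 1)
  expect_identical(sum(bc$dim == 1), 0L)
  expect_identical(betti_at(bc, 5), c(1L, 0L))
  expect_identical(betti_at(bc, 1), c(1L, 0L))

  # triangle boundary at t = 1 filled at t = 2: 1D bar [1, 2)
  ev <- events_from(c(1, 1, 1, 2),
                    list(c(1, 2), c(2, 3), c(1, 3), c(1, 2, 3)))
  bc <- compute_barcode(build_complex(ev), max_dim = 1)
  loops <- bc[bc$dim == 1, ]
  expect_identical(nrow(loops), 1L)
  expect_equal(loops$birth, 1)
  expect_equal(loops$death, 2)
  expect_identical(betti_at(bc, 1.5), c(1L, 1L))
  expect_identical(betti_at(bc, 2), c(1L, 0L))
  expect_identical(betti_at(bc, 0.5), c(0L, 0L))
})

test_that("barcodes agree with the GF(2) rank oracle on random complexes", {
  for (seed in 1:40) {
    ev <- random_events(n_vertices = 8, n_bins = 10, seed = seed)
    cx <- build_complex(ev, max_dim = 3)
    bc <- compute_barcode(cx, max_dim = 2)
    curve <- betti_curve(bc, ev$bin_times)
    oracle <- oracle_betti_curve(cx, ev$bin_times, max_hom_dim = 2)
    expect_identical(unname(as.matrix(curve[, c("beta0", "beta1", "beta2")])),
                     unname(oracle), label = paste("seed", seed))
  }
})

test_that("Euler characteristic matches the alternating Betti sum stepwise", {
  for (seed in c(3, 11, 27)) {
    ev <- random_events(n_vertices = 8, n_bins = 12, seed = seed)
    cx <- build_complex(ev, max_dim = 3)
    bc <- compute_barcode(cx, max_dim = 3)
    for (t in ev$bin_times) {
      f <- f_vector(cx, t)$f
      chi_f <- sum(f * c(1, -1, 1, -1))
      b <- betti_at(bc, t)
      chi_b <- sum(b * c(1, -1, 1, -1))
      expect_equal(chi_f, chi_b)
    }
  }
})

test_that("learning-time detection scans the Betti trace to the horizon", {
  # persistent (1,1) from 180 s, last spurious loop dies at 420 s
  bc <- manual_barcode(dim = c(0, 1, 1), birth = c(0, 180, 300),
                       death = c(Inf, Inf, 420))
  out <- detect_tmin(bc, c(1, 1), horizon = 3600)
  expect_true(out$converged)
  expect_equal(out$t_min, 420)

  # never correct
  bc2 <- manual_barcode(dim = c(0, 0), birth = c(0, 10), death = c(Inf, Inf))
  expect_false(detect_tmin(bc2, c(1, 1), horizon = 100)$converged)

  # correct from the first event
  bc3 <- manual_barcode(dim = c(0, 1), birth = c(0, 0), death = c(Inf, Inf))
  out3 <- detect_tmin(bc3, c(1, 1), horizon = 50)
  expect_true(out3$converged)
  expect_equal(out3$t_min, 0)
})

test_that("spurious-loop statistics census the 1D bars", {
  # constructed barcode: bars [1,3), [2,6), [4, Inf); true beta1 = 1
  bc <- manual_barcode(dim = c(0, 1, 1, 1), birth = c(0, 1, 2, 4),
                       death = c(Inf, 3, 6, Inf))
  ls <- loop_stats(bc, c(1, 1), horizon = 10)
  expect_setequal(ls$durations, c(2, 4))
  expect_identical(ls$max_live, 2L)
  expect_lte(ls$mean_live, ls$max_live)
  expect_false(any(ls$censored))

  # single persistent loop only
  bc1 <- manual_barcode(dim = c(0, 1), birth = c(0, 2), death = c(Inf, Inf))
  ls1 <- loop_stats(bc1, c(1, 1), horizon = 10)
  expect_length(ls1$durations, 0)
  expect_identical(ls1$max_live, 1L)

  # an open non-persistent bar is censored at the horizon
  bc2 <- manual_barcode(dim = c(0, 1, 1), birth = c(0, 1, 5),
                        death = c(Inf, Inf, Inf))
  ls2 <- loop_stats(bc2, c(1, 1), horizon = 10)
  expect_identical(ls2$n_spurious, 1L)
  expect_true(any(ls2$censored))
  expect_equal(ls2$durations[ls2$censored], 5)  # 10 - birth 5
})

test_that("invalid filtrations are rejected", {
  # face born after coface
  simp <- data.frame(dim = c(0L, 0L, 1L), birth = c(1, 3, 2),
                     v1 = c(1L, 2L, 1L), v2 = c(0L, 0L, 2L),
                     v3 = 0L, v4 = 0L)
  simp <- simp[order(simp$birth, simp$dim), ]
  cx <- structure(list(simplices = simp, vertices = c(1L, 2L), max_dim = 3L),
                  class = "temporal_complex")
  expect_error(compute_barcode(cx, max_dim = 1), "born after|missing face")
})
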