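spike_set <- function(spikes, duration) {
  structure(list(spikes = spikes, duration = duration,
                 n_cells = length(spikes), provenance = list()),
            class = "spike_train_set")
}

test_that("coactivity binning groups cells by window", {
  sp <- spike_set(list(1.00, 1.05), duration = 2)
  ev <- detect_coactivity(sp, coactivity_window(w = 0.25))
  grp <- ev$cells[[which(ev$bin_times <= 1 & ev$bin_times + 0.25 > 1)]]
  expect_identical(grp, c(1L, 2L))

  # spikes 2 s apart are never coactive at w = 0.25
  sp2 <- spike_set(list(0.5, 2.5), duration = 3)
  ev2 <- detect_coactivity(sp2, coactivity_window(w = 0.25))
  expect_true(all(lengths(ev2$cells) == 1))

  expect_error(coactivity_window(w = 0), "positive")
})

test_that("binning matches exhaustive enumeration on a printed spike set", {
  spikes <- list(c(0.05, 0.31, 0.55, 0.93), c(0.07, 0.61, 0.95),
                 c(0.12, 0.33, 0.58))
  sp <- spike_set(spikes, duration = 1)
  w <- 0.1
  ev <- detect_coactivity(sp, coactivity_window(w = w))
  # brute force: for every bin [k*w, (k+1)*w), list cells with a spike in it
  expected <- list()
  for (k in 0:10) {
    cells <- which(vapply(spikes, function(st)
      any(st >= k * w & st < (k + 1) * w), TRUE))
    if (length(cells)) expected[[length(expected) + 1]] <-
        list(t = k * w, cells = as.integer(cells))
  }
  expect_identical(length(ev$cells), length(expected))
  for (i in seq_along(expected)) {
    expect_equal(ev$bin_times[i], expected[[i]]$t)
    expect_identical(ev$cells[[i]], expected[[i]]$cells)
  }
})

test_that("the temporal complex closes coactive groups under faces", {
  ev <- structure(list(bin_times = 5, cells = list(c(1L, 2L, 3L))),
                  class = "coactivity_events")
  cx <- build_complex(ev)
  fv <- f_vector(cx, 5)
  expect_identical(fv$f[1:3], c(3L, 3L, 1L))
  expect_true(all(cx$simplices$birth == 5))

  # growing complex: edge precedes the triangle that contains it
  ev2 <- structure(list(bin_times = c(1, 2),
                        cells = list(c(1L, 2L), c(1L, 2L, 3L))),
                   class = "coactivity_events")
  cx2 <- build_complex(ev2)
  s <- cx2$simplices
  expect_equal(s$birth[s$dim == 1 & s$v1 == 1 & s$v2 == 2], 1)
  expect_equal(s$birth[s$dim == 2], 2)
  # face-before-coface, exhaustively
  for (i in which(s$dim > 0)) {
    v <- unlist(s[i, c("v1", "v2", "v3", "v4")])
    v <- v[v > 0]
    for (omit in seq_along(v)) {
      fv2 <- v[-omit]
      j <- which(s$dim == length(fv2) - 1 &
                   apply(as.matrix(s[, c("v1", "v2", "v3", "v4")]), 1,
                         function(r) identical(as.integer(r[r > 0]),
                                               as.integer(fv2))))
      expect_true(length(j) == 1 && s$birth[j] <= s$birth[i])
    }
  }

  # empty input
  cx0 <- build_complex(structure(list(bin_times = numeric(0), cells = list()),
                                 class = "coactivity_events"))
  expect_identical(nrow(cx0$simplices), 0L)
})

test_that("f-vector counts and connectivity indices are normalized correctly", {
  ev <- structure(list(bin_times = c(1, 2),
                       cells = list(c(1L, 2L), c(3L, 4L))),
                  class = "coactivity_events")
  cx <- build_complex(ev)
  fv <- f_vector(cx, 2, N = 5)
  expect_identical(fv$f[2], 2L)
  expect_equal(fv$eta[2], 2 / choose(5, 2))
  expect_equal(fv$eta[1], 4 / 5)
  expect_identical(f_vector(cx, 0.5)$f, c(0L, 0L, 0L, 0L))
  expect_error(f_vector(cx, 2, N = 3), "smaller")

  # complete pairwise coactivity saturates eta_1
  evc <- structure(list(bin_times = 1, cells = list(1:6)),
                   class = "coactivity_events")
  expect_equal(f_vector(build_complex(evc), 1, N = 6)$eta[2], 1)
})

test_that("the filtered complex grows monotonically with time", {
  sp <- generate_spikes(sample_ensemble(ensemble_spec(25, 12, 8),
                                        one_hole_arena(), seed = 4),
                        short_trajectory(), seed = 5)
  cx <- build_complex(detect_coactivity(sp, coactivity_window()), max_dim = 2)
  f1 <- vapply(seq(0, 300, by = 30), function(t) sum(f_vector(cx, t)$f), 0L)
  expect_true(all(diff(f1) >= 0))
  # births sorted, faces present with earlier-or-equal birth (spot check)
  expect_false(is.unsorted(cx$simplices$birth))
})
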