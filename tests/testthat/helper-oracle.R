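# Independent brute-force homology oracle: Betti numbers of a simplicial
# complex from Gauss-eliminated boundary-matrix ranks over GF(2). Kept
# deliberately separate from the package's persistence reduction.

gf2_rank <- function(M) {
  if (is.null(dim(M)) || nrow(M) == 0 || ncol(M) == 0) return(0L)
  M <- M %% 2L
  rank <- 0L
  nr <- nrow(M); nc <- ncol(M)
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(M[row:nr, col] == 1L)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    for (r in seq_len(nr)) {
      if (r != row && M[r, col] == 1L) M[r, ] <- (M[r, ] + M[row, ]) %% 2L
    }
    rank <- rank + 1L
    row <- row + 1L
    if (row > nr) break
  }
  rank
}

# simplices: data frame with dim, v1..v4 (0 = unused); returns beta_0..beta_maxd
oracle_betti <- function(simp, max_hom_dim = 1L) {
  key_of <- function(r) {
    v <- sort(as.integer(r[r > 0]))
    paste(v, collapse = "-")
  }
  vm <- as.matrix(simp[, c("v1", "v2", "v3", "v4")])
  keys <- apply(vm, 1, key_of)
  betti <- integer(max_hom_dim + 1)
  for (d in 0:max_hom_dim) {
    idx_d <- which(simp$dim == d)
    n_d <- length(idx_d)
    if (n_d == 0) { betti[d + 1] <- 0L; next }
    # rank of boundary_d (maps d-simplices to (d-1)-simplices)
    rk_d <- 0L
    if (d > 0) {
      idx_dm1 <- which(simp$dim == d - 1)
      rows <- stats::setNames(seq_along(idx_dm1), keys[idx_dm1])
      M <- matrix(0L, length(idx_dm1), n_d)
      for (j in seq_len(n_d)) {
        v <- sort(as.integer(vm[idx_d[j], ][vm[idx_d[j], ] > 0]))
        for (omit in seq_along(v)) {
          fk <- paste(v[-omit], collapse = "-")
          M[rows[[fk]], j] <- 1L
        }
      }
      rk_d <- gf2_rank(M)
    }
    # rank of boundary_{d+1}
    idx_dp1 <- which(simp$dim == d + 1)
    rk_dp1 <- 0L
    if (length(idx_dp1) > 0) {
      rows <- stats::setNames(seq_along(idx_d), keys[idx_d])
      M <- matrix(0L, n_d, length(idx_dp1))
      for (j in seq_along(idx_dp1)) {
        v <- sort(as.integer(vm[idx_dp1[j], ][vm[idx_dp1[j], ] > 0]))
        for (omit in seq_along(v)) {
          fk <- paste(v[-omit], collapse = "-")
          M[rows[[fk]], j] <- 1L
        }
      }
      rk_dp1 <- gf2_rank(M)
    }
    betti[d + 1] <- n_d - rk_d - rk_dp1
  }
  betti
}

# Betti curve of a temporal complex at given times, via the rank oracle
oracle_betti_curve <- function(complex, times, max_hom_dim = 1L) {
  t(vapply(times, function(t) {
    sub <- complex$simplices[complex$simplices$birth <= t, , drop = FALSE]
    if (nrow(sub) == 0) return(integer(max_hom_dim + 1))
    oracle_betti(sub, max_hom_dim)
  }, integer(max_hom_dim + 1)))
}

# random filtered coactivity complex on <= n_vertices vertices
random_events <- function(n_vertices = 8, n_bins = 12, seed = 1) {
  set.seed(seed)
  cells <- lapply(seq_len(n_bins), function(b) {
    k <- sample(1:min(4, n_vertices), 1)
    sort(sample(seq_len(n_vertices), k))
  })
  structure(list(bin_times = as.numeric(seq_len(n_bins)), cells = cells),
            class = "coactivity_events")
}
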