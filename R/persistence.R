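#' Persistent homology of a temporal coactivity complex
#'
#' Computes the Z/2 persistence barcode of the time-filtered complex:
#' intervals `[birth, death)` in session seconds for homology classes in
#' dimensions `0..max_dim`. Uses the standard boundary-matrix column
#' reduction with the clearing optimisation (compiled). Classes still alive
#' at the end of the filtration are reported with `death = Inf`.
#'
#' @param complex a [build_complex()] object. Simplices of dimension up to
#'   `max_dim + 1` participate (cofaces are needed to kill classes).
#' @param max_dim highest homology dimension reported (default 1: components
#'   and loops).
#' @return object of class `barcode`: data frame with columns `dim`,
#'   `birth`, `death` (may be `Inf`). Zero-persistence pairs are dropped.
#' @export
compute_barcode <- function(complex, max_dim = 1L) {
  stopifnot(inherits(complex, "temporal_complex"), max_dim >= 0)
  simp <- complex$simplices[complex$simplices$dim <= max_dim + 1L, ,
                            drop = FALSE]
  if (nrow(simp) == 0) {
    bc <- data.frame(dim = integer(0), birth = numeric(0), death = numeric(0))
    return(structure(bc, class = c("barcode", "data.frame"),
                     max_dim = as.integer(max_dim)))
  }
  verts <- as.matrix(simp[, c("v1", "v2", "v3", "v4")])
  storage.mode(verts) <- "integer"
  res <- cpp_persistence_pairs(verts, as.integer(simp$dim), simp$birth)
  b <- res$birth_idx; d <- res$death_idx; e <- res$essential_idx
  bars <- data.frame(dim = simp$dim[b], birth = simp$birth[b],
                     death = simp$birth[d])
  bars <- bars[bars$death > bars$birth, , drop = FALSE]
  ess <- data.frame(dim = simp$dim[e], birth = simp$birth[e], death = Inf)
  bc <- rbind(bars, ess)
  bc <- bc[bc$dim <= max_dim, , drop = FALSE]
  bc <- bc[order(bc$dim, bc$birth, bc$death), , drop = FALSE]
  rownames(bc) <- NULL
  structure(bc, class = c("barcode", "data.frame"),
            max_dim = as.integer(max_dim))
}

#' Betti numbers at a time
#'
#' A bar `[birth, death)` is alive at `t` when `birth <= t < death`.
#'
#' @param barcode a [compute_barcode()] result.
#' @param t time in seconds.
#' @return integer vector `(beta0, beta1, ...)` up to the barcode's
#'   `max_dim`.
#' @export
betti_at <- function(barcode, t) {
  md <- attr(barcode, "max_dim")
  vapply(0:md, function(d)
    sum(barcode$dim == d & barcode$birth <= t & barcode$death > t), 0L)
}

#' Betti curves over a set of times
#'
#' @param barcode a barcode.
#' @param times evaluation times.
#' @return data frame `t`, `beta0`, `beta1`, ...
#' @export
betti_curve <- function(barcode, times) {
  md <- attr(barcode, "max_dim")
  out <- data.frame(t = times)
  for (d in 0:md)
    out[[paste0("beta", d)]] <- vapply(times, function(t)
      sum(barcode$dim == d & barcode$birth <= t & barcode$death > t), 0L)
  out
}

# distinct event times of a barcode, restricted to [0, horizon]
filtration_steps <- function(barcode, horizon) {
  ts <- c(barcode$birth, barcode$death)
  sort(unique(ts[is.finite(ts) & ts <= horizon]))
}

#' Minimal learning time of a barcode
#'
#' `T_min` is the earliest time from which the Betti numbers `(beta0, beta1)`
#' equal the environment's true values and remain equal up to the horizon.
#' If the Betti numbers at the horizon are not the true ones (or never reach
#' them), the map has not converged.
#'
#' @param barcode a [compute_barcode()] barcode with `max_dim >= 1`.
#' @param true_betti length-2 integer vector `(beta0, beta1)` of the arena.
#' @param horizon end of the assessment period, seconds (must not exceed the
#'   session length).
#' @return object of class `learning_outcome`: `converged`, `t_min` (s, NA
#'   if not converged), `horizon`, `betti_horizon`.
#' @export
detect_tmin <- function(barcode, true_betti, horizon) {
  true_betti <- as.integer(true_betti[1:2])
  steps <- filtration_steps(barcode, horizon)
  if (length(steps) == 0) {
    return(structure(list(converged = FALSE, t_min = NA_real_,
                          horizon = horizon, betti_horizon = c(0L, 0L)),
                     class = "learning_outcome"))
  }
  bmat <- vapply(steps, function(t) betti_at(barcode, t)[1:2], integer(2))
  ok <- bmat[1, ] == true_betti[1] & bmat[2, ] == true_betti[2]
  b_hor <- betti_at(barcode, horizon)[1:2]
  if (!all(b_hor == true_betti) || !ok[length(ok)]) {
    return(structure(list(converged = FALSE, t_min = NA_real_,
                          horizon = horizon, betti_horizon = b_hor),
                     class = "learning_outcome"))
  }
  bad <- which(!ok)
  t_min <- if (length(bad) == 0) steps[1] else steps[max(bad) + 1L]
  structure(list(converged = TRUE, t_min = t_min, horizon = horizon,
                 betti_horizon = b_hor),
            class = "learning_outcome")
}

#' @export
print.learning_outcome <- function(x, ...) {
  if (x$converged)
    cat(sprintf("converged: T_min = %.1f s (%.2f min), horizon %.0f s\n",
                x$t_min, x$t_min / 60, x$horizon))
  else
    cat(sprintf("not converged by %.0f s; Betti at horizon (%d, %d)\n",
                x$horizon, x$betti_horizon[1], x$betti_horizon[2]))
  invisible(x)
}

#' Spurious-loop statistics of a barcode
#'
#' Identifies the persistent 1D classes (the `true_betti[2]` longest-lived
#' bars alive at the horizon, ties broken by earlier birth); every other 1D
#' bar is a spurious loop. Reports spurious-loop durations (bars still open
#' at the horizon are censored there and flagged) and the mean and maximum
#' number of live 1D loops sampled at the filtration steps.
#'
#' @param barcode a barcode with `max_dim >= 1`.
#' @param true_betti arena Betti numbers `(beta0, beta1)`.
#' @param horizon seconds.
#' @return list: `durations` (s), `censored` (logical, same length),
#'   `mean_live`, `max_live`, `n_spurious`.
#' @export
loop_stats <- function(barcode, true_betti, horizon) {
  loops <- barcode[barcode$dim == 1 & barcode$birth <= horizon, , drop = FALSE]
  if (nrow(loops) == 0)
    return(list(durations = numeric(0), censored = logical(0),
                mean_live = 0, max_live = 0L, n_spurious = 0L))
  alive_end <- loops$death > horizon
  persistent <- rep(FALSE, nrow(loops))
  n_true <- as.integer(true_betti[2])
  if (n_true > 0 && any(alive_end)) {
    cand <- which(alive_end)
    life <- pmin(loops$death[cand], horizon) - loops$birth[cand]
    o <- order(-life, loops$birth[cand])
    persistent[cand[o[seq_len(min(n_true, length(cand)))]]] <- TRUE
  }
  spur <- loops[!persistent, , drop = FALSE]
  censored <- spur$death > horizon
  durations <- pmin(spur$death, horizon) - spur$birth
  steps <- filtration_steps(barcode, horizon)
  live <- vapply(steps, function(t)
    sum(loops$birth <= t & loops$death > t), 0L)
  list(durations = as.numeric(durations), censored = censored,
       mean_live = if (length(live)) mean(live) else 0,
       max_live = if (length(live)) max(live) else 0L,
       n_spurious = nrow(spur))
}
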