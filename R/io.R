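#' Spike-train CSV round trip
#'
#' Tidy format: columns `cell_id`, `spike_time_s`. An empty file (header
#' only) reads back as an empty spike set.
#'
#' @param spikes a `spike_train_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spike_csv <- function(spikes, path) {
  write.csv(spike_table(spikes), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_csv
#' @param n_cells number of cells (defaults to the largest id present).
#' @param duration session length in seconds (defaults to the last spike).
#' @export
read_spike_csv <- function(path, n_cells = NULL, duration = NULL) {
  df <- read.csv(path)
  if (!all(c("cell_id", "spike_time_s") %in% names(df)))
    stop("malformed spike file: need columns cell_id, spike_time_s")
  df$spike_time_s <- suppressWarnings(as.numeric(df$spike_time_s))
  bad <- which(!is.finite(df$spike_time_s) | df$spike_time_s < 0)
  if (length(bad))
    stop("malformed spike time at line ", bad[1] + 1L)
  if (is.null(n_cells)) n_cells <- if (nrow(df)) max(df$cell_id) else 0L
  if (is.null(duration)) duration <- if (nrow(df)) max(df$spike_time_s) else 0
  spikes <- split(df$spike_time_s, factor(df$cell_id, levels = seq_len(n_cells)))
  structure(
    list(spikes = lapply(unname(spikes), function(x) sort(as.numeric(x))),
         duration = duration, n_cells = as.integer(n_cells),
         provenance = list(source = path)),
    class = "spike_train_set"
  )
}

#' Barcode CSV round trip
#'
#' Columns `dim`, `birth_s`, `death_s`; an open interval is serialised with
#' an empty death field and parsed back as `Inf`.
#'
#' @param barcode a [compute_barcode()] barcode.
#' @param path file path.
#' @return `path` invisibly / the parsed `barcode`.
#' @export
write_barcode_csv <- function(barcode, path) {
  df <- data.frame(dim = barcode$dim, birth_s = barcode$birth,
                   death_s = ifelse(is.finite(barcode$death),
                                    barcode$death, NA))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_csv
#' @export
read_barcode_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("dim", "birth_s", "death_s") %in% names(df)))
    stop("malformed barcode file: need columns dim, birth_s, death_s")
  bc <- data.frame(dim = as.integer(df$dim), birth = df$birth_s,
                   death = ifelse(is.na(df$death_s), Inf, df$death_s))
  structure(bc, class = c("barcode", "data.frame"),
            max_dim = if (nrow(bc)) max(bc$dim) else 0L)
}

#' Trajectory CSV export
#'
#' @param trajectory a trajectory.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(data.frame(t = trajectory$times, x = trajectory$x,
                       y = trajectory$y), path, row.names = FALSE)
  invisible(path)
}

#' Sweep-result CSV export
#'
#' @param results a [run_sweep()] data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(results, path) {
  write.csv(as.data.frame(results), path, row.names = FALSE)
  invisible(path)
}

validate_config <- function(config) {
  required <- c("arena", "ensemble", "window", "duration_s", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("config schema error: missing field(s) ",
         paste(missing, collapse = ", "))
  if (is.null(config$window$w))
    stop("config schema error: missing field window$w")
  if (is.null(config$ensemble$N) || is.null(config$ensemble$f_mean) ||
      is.null(config$ensemble$s_mean))
    stop("config schema error: ensemble needs N, f_mean, s_mean")
  config
}

#' Read a run configuration from YAML
#'
#' Schema: `arena` (`width`, `height`, optional `holes` as list of 4-number
#' lists), `ensemble` (`N`, `f_mean`, `s_mean`, optional `a`, `b`,
#' `dynamic_fields`, `tau_mean`), `theta` (`"off"`, `"single"`,
#' `"four_sinusoid"`), `window` (`w` seconds, optional `bin_shift`,
#' `jitter`), `duration_s`, optional `horizon_s`, `mean_speed_cm_s`, `dt_s`,
#' `repeats`, and `seed`.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  config <- yaml::read_yaml(path)
  # YAML 1.1 quirks: a bare key `N` parses as boolean FALSE, and the value
  # `off` as logical FALSE; normalise both
  if (!is.null(config$ensemble) && !is.null(config$ensemble[["FALSE"]]) &&
      is.null(config$ensemble$N)) {
    config$ensemble$N <- config$ensemble[["FALSE"]]
    config$ensemble[["FALSE"]] <- NULL
  }
  if (isFALSE(config$theta)) config$theta <- "off"
  validate_config(config)
}

#' Run the simulate pipeline from a configuration
#'
#' Generates the arena, trajectory, ensemble, optional theta signal and
#' spike trains, builds the coactivity complex and barcode, and writes the
#' artifact bundle into `out_dir`: `trajectory.csv`, `spikes.csv`,
#' `barcode.csv`, `betti_curve.csv`, `outcome.json` and `manifest.json`.
#' Re-running with the same config reproduces identical artifacts.
#'
#' @param config a config list (see [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return the outcome list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)
  holes <- lapply(config$arena$holes %||% list(), as.numeric)
  arena <- make_arena(config$arena$width, config$arena$height, holes)
  trajectory <- generate_trajectory(
    arena, duration = config$duration_s,
    mean_speed = config$mean_speed_cm_s %||% 25,
    dt = config$dt_s %||% 0.01,
    seed = child_seeds(seed, SALT_TRAJECTORY))
  ens_cfg <- config$ensemble
  spec <- ensemble_spec(ens_cfg$N, ens_cfg$f_mean, ens_cfg$s_mean,
                        a = ens_cfg$a %||% 0.3, b = ens_cfg$b %||% 0.3,
                        dynamic_fields = isTRUE(ens_cfg$dynamic_fields),
                        tau_mean = ens_cfg$tau_mean %||% 240)
  ensemble <- sample_ensemble(spec, arena,
                              seed = child_seeds(seed, SALT_ENSEMBLE))
  theta_mode <- config$theta %||% "off"
  theta <- if (identical(theta_mode, "off")) NULL else
    make_theta(theta_mode, duration = trajectory$duration + 1,
               seed = child_seeds(seed, SALT_THETA))
  window <- coactivity_window(w = config$window$w,
                              bin_shift = config$window$bin_shift %||% 0,
                              jitter = config$window$jitter %||% 0,
                              jitter_seed = child_seeds(seed, SALT_JITTER))
  horizon <- config$horizon_s %||% min(trajectory$duration, 3600)
  run <- run_learning(ensemble, arena, trajectory, theta, window,
                      horizon = horizon,
                      seed = child_seeds(seed, SALT_SPIKES))
  write_trajectory_csv(trajectory, file.path(out_dir, "trajectory.csv"))
  write_spike_csv(run$spikes, file.path(out_dir, "spikes.csv"))
  write_barcode_csv(run$barcode, file.path(out_dir, "barcode.csv"))
  steps <- filtration_steps(run$barcode, horizon)
  write.csv(betti_curve(run$barcode, steps),
            file.path(out_dir, "betti_curve.csv"), row.names = FALSE)
  outcome <- list(
    converged = run$outcome$converged,
    t_min_s = if (run$outcome$converged) run$outcome$t_min else NA_real_,
    horizon_s = horizon,
    betti_horizon = as.integer(run$outcome$betti_horizon),
    true_betti = as.integer(arena$true_betti),
    eta1 = run$eta[["eta1"]], eta2 = run$eta[["eta2"]],
    n_spurious_loops = run$loops$n_spurious,
    max_live_loops = run$loops$max_live)
  jsonlite::write_json(outcome, file.path(out_dir, "outcome.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(package = "topolearn",
                   version = as.character(utils::packageVersion("topolearn")),
                   config = config,
                   seeds = list(
                     master = seed,
                     trajectory = child_seeds(seed, SALT_TRAJECTORY),
                     ensemble = child_seeds(seed, SALT_ENSEMBLE),
                     theta = child_seeds(seed, SALT_THETA),
                     spikes = child_seeds(seed, SALT_SPIKES)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outcome)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
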