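# Config-driven experiment runners: configuration validation, artifact
# serialization (CSV traces, YAML summaries, run manifest), and full-state
# checkpointing with exact resume for the long tissue runs.

.experiments <- c("single_cell", "min_acs", "sheet", "threshold")

.default_configs <- function() list(
  single_cell = list(
    experiment = "single_cell",
    cell_type = "ENDO",          # model variant
    g_k1 = .GK1_AC,              # nS/pF
    duration_ms = 510000,        # past the 500,000 ms stabilization mark
    dt = .DT_DEFAULT,            # ms
    sample_dt = 1,               # ms
    stable_after_ms = 500000,    # start of the stable-state window
    window_ms = 10000,           # averaging window width
    threshold_mv = -20,          # upstroke threshold
    seed = 1L                    # reserved; the core is deterministic
  ),
  min_acs = list(
    experiment = "min_acs",
    max_n = 8L,
    duration_ms = 900000,
    dt = .DT_DEFAULT,
    dh = .DH_DEFAULT,            # mm
    D = .D_DEFAULT,              # cm^2/ms
    ac_gk1 = .GK1_AC,
    vm_type = "ENDO",
    threshold_mv = 0,            # full-AP criterion for the driven VM
    sample_dt = 1,
    seed = 1L
  ),
  sheet = list(
    experiment = "sheet",
    layout = "fig9",             # fig2 | fig9 | direct | custom
    grid_file = NULL,            # for layout = "custom": a write_tissue_grid() file
    vm_rows = NULL,              # builder overrides (NULL = builder default)
    vm_cols = NULL,
    n_ac = 625L,                 # direct layout only
    duration_ms = 600000,
    dt = .DT_DEFAULT,
    dh = .DH_DEFAULT,
    D = .D_DEFAULT,
    ac_gk1 = .GK1_AC,
    vm_type = "ENDO",
    sample_dt = 1,
    snapshot_dt = 0,             # ms; 0 = traces only
    electrode = c(330, 160),     # (x0, y0) in pixel coordinates
    sigma = 1,
    period_window_ms = 10000,    # per-window mean period reporting
    threshold_mv = -20,
    probe = "vm_near",           # probe used for the period summary
    checkpoint_every_ms = 0,     # 0 = no checkpoints
    resume = FALSE,
    seed = 1L
  ),
  threshold = list(
    experiment = "threshold",
    g_lo = 0.05,
    g_hi = 3.0,
    tol = 0.05,
    window_ms = 30000,
    cell_type = "ENDO",
    dt = .DT_DEFAULT,
    seed = 1L
  )
)

#' Default experiment configuration
#'
#' Returns the default configuration list of one of the built-in experiments:
#' `"single_cell"` (spontaneous activity of one IK1-suppressed cell),
#' `"min_acs"` (minimum chain of automatic cells that drives one myocyte),
#' `"sheet"` (2D pacemaker layouts with period summary and pseudo-ECG), and
#' `"threshold"` (bisection for the automaticity boundary in G_K1). All
#' quantities carry the units documented in the field comments: ms for times,
#' mm for `dh`, cm^2/ms for `D`, nS/pF for conductances, mV for thresholds.
#'
#' @param experiment Experiment name.
#' @return A named list.
#' @export
default_config <- function(experiment = .experiments) {
  experiment <- match.arg(experiment)
  .default_configs()[[experiment]]
}

#' Load and validate an experiment configuration
#'
#' Reads a YAML configuration, merges it over the experiment's defaults and
#' validates it: unknown keys are rejected and basic unit/range checks are
#' applied.
#'
#' @param path Path to a YAML file with at least an `experiment` key.
#' @return The validated configuration list.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$experiment)) stop("config must name an 'experiment'")
  validate_config(cfg)
}

#' @rdname load_config
#' @param config A configuration list (as from [default_config()], possibly
#'   modified).
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$experiment) || !config$experiment %in% .experiments)
    stop("experiment must be one of: ", paste(.experiments, collapse = ", "))
  def <- default_config(config$experiment)
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s) for ", config$experiment, ": ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  pos <- function(key) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || !(v > 0)))
      stop("config field '", key, "' must be a positive number")
  }
  nonneg <- function(key) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v < 0))
      stop("config field '", key, "' must be a non-negative number")
  }
  for (k in intersect(names(cfg), c("duration_ms", "dt", "sample_dt", "dh",
                                    "D", "window_ms", "period_window_ms",
                                    "tol")))
    pos(k)
  for (k in intersect(names(cfg), c("g_k1", "ac_gk1", "g_lo", "snapshot_dt",
                                    "checkpoint_every_ms")))
    nonneg(k)
  if (!is.null(cfg$cell_type) &&
      !cfg$cell_type %in% c("ENDO", "MID", "EPI", "PURKINJE"))
    stop("config field 'cell_type' must be ENDO, MID, EPI or PURKINJE")
  if (!is.null(cfg$vm_type) && !cfg$vm_type %in% c("ENDO", "MID", "EPI"))
    stop("config field 'vm_type' must be ENDO, MID or EPI")
  if (!is.null(cfg$layout) &&
      !cfg$layout %in% c("fig2", "fig9", "direct", "custom"))
    stop("config field 'layout' must be fig2, fig9, direct or custom")
  if (identical(cfg$layout, "custom") && is.null(cfg$grid_file))
    stop("layout = 'custom' requires 'grid_file'")
  if (!is.null(cfg$electrode) &&
      (length(cfg$electrode) != 2L || !all(is.finite(as.numeric(cfg$electrode)))))
    stop("config field 'electrode' must be two finite numbers (x0, y0)")
  cfg
}

# fingerprint of a config for the run manifest (md5 of its canonical YAML)
.config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config[order(names(config))], tf)
  unname(tools::md5sum(tf))
}

.write_manifest <- function(out_dir, config, t_wall) {
  manifest <- list(
    package = "ventpace",
    version = as.character(utils::packageVersion("ventpace")),
    r_version = R.version.string,
    config_md5 = .config_hash(config),
    wall_time_s = round(t_wall, 3),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  invisible(manifest)
}

# windowed mean cycle lengths over consecutive windows of width window_ms
.windowed_periods <- function(markers, t_start, t_end, window_ms) {
  starts <- seq(t_start, t_end - window_ms, by = window_ms)
  data.frame(
    window_start = starts,
    window_end = starts + window_ms,
    mean_cl_ms = vapply(starts, function(s)
      mean_cycle_length(markers, s, s + window_ms), numeric(1)))
}

#' Run a configured experiment
#'
#' Dispatches on `config$experiment` and executes the corresponding workflow.
#' When `out_dir` is given, traces are written as CSV, the summary and the
#' validated configuration as YAML, together with a run manifest (package
#' version, config fingerprint, wall time). Runs are deterministic and
#' idempotent given a configuration.
#'
#' @param config Configuration list (see [default_config()], [load_config()]).
#' @param out_dir Optional output directory (created if missing).
#' @param verbose Print progress lines (one per averaging window for the
#'   sheet experiment).
#' @return The experiment result, invisibly when `out_dir` is given:
#'   \describe{
#'     \item{single_cell}{list with the `trace`, `markers`, stable and
#'       windowed cycle lengths}
#'     \item{min_acs}{a `min_acs` object (see [min_acs_to_drive()])}
#'     \item{sheet}{list with probe `traces`, `periods` per window, optional
#'       `ecg` and snapshots, and the final state}
#'     \item{threshold}{the threshold estimate in nS/pF}
#'   }
#' @export
run_experiment <- function(config, out_dir = NULL, verbose = FALSE) {
  cfg <- validate_config(config)
  t0 <- proc.time()[["elapsed"]]
  res <- switch(cfg$experiment,
    single_cell = .run_single_cell_experiment(cfg, out_dir),
    min_acs = .run_min_acs_experiment(cfg, out_dir, verbose),
    sheet = .run_sheet_experiment(cfg, out_dir, verbose),
    threshold = .run_threshold_experiment(cfg, out_dir))
  if (!is.null(out_dir))
    .write_manifest(out_dir, cfg, proc.time()[["elapsed"]] - t0)
  if (is.null(out_dir)) res else invisible(res)
}

.ensure_dir <- function(out_dir) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  out_dir
}

.run_single_cell_experiment <- function(cfg, out_dir) {
  .ensure_dir(out_dir)
  if (cfg$duration_ms < cfg$stable_after_ms + cfg$window_ms)
    stop("duration_ms (", cfg$duration_ms, ") must cover stable_after_ms + ",
         "window_ms (", cfg$stable_after_ms + cfg$window_ms, ")")
  tr <- run_single_cell(cell_params(cfg$cell_type, g_k1 = cfg$g_k1),
                        cfg$duration_ms, sample_dt = cfg$sample_dt,
                        dt = cfg$dt)
  mk <- detect_upstrokes(tr, threshold_mv = cfg$threshold_mv)
  stable_cl <- mean_cycle_length(mk, cfg$stable_after_ms,
                                 cfg$stable_after_ms + cfg$window_ms)
  early_cl <- mean_cycle_length(mk, 70000, 80000)
  windows <- .windowed_periods(mk, 0, cfg$duration_ms, cfg$window_ms)
  summary <- list(
    n_upstrokes = length(mk$upstroke_times),
    stable_cl_ms = stable_cl,
    early_cl_70_80s_ms = early_cl,
    stable_window = c(cfg$stable_after_ms, cfg$stable_after_ms + cfg$window_ms))
  if (!is.null(out_dir)) {
    write_voltage_trace(tr, file.path(out_dir, "trace.csv"))
    utils::write.csv(as.data.frame(mk), file.path(out_dir, "markers.csv"),
                     row.names = FALSE)
    utils::write.csv(windows, file.path(out_dir, "windowed_cl.csv"),
                     row.names = FALSE)
    yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  }
  list(trace = tr, markers = mk, summary = summary, windows = windows)
}

.run_min_acs_experiment <- function(cfg, out_dir, verbose) {
  .ensure_dir(out_dir)
  res <- min_acs_to_drive(max_n = cfg$max_n, duration_ms = cfg$duration_ms,
                          dh = cfg$dh, D = cfg$D, ac_gk1 = cfg$ac_gk1,
                          vm_type = cfg$vm_type, dt = cfg$dt,
                          threshold_mv = cfg$threshold_mv,
                          sample_dt = cfg$sample_dt, verbose = verbose)
  if (!is.null(out_dir)) {
    utils::write.csv(res$tried, file.path(out_dir, "tried.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(n_min = if (is.na(res$n_min)) "none" else res$n_min,
                          first_pacing_ms = res$first_pacing_ms,
                          duration_ms = res$duration_ms),
                     file.path(out_dir, "summary.yaml"))
  }
  res
}

.sheet_grid <- function(cfg) {
  args <- list(dh = cfg$dh, D = cfg$D, ac_gk1 = cfg$ac_gk1,
               vm_type = cfg$vm_type)
  if (!is.null(cfg$vm_rows)) args$vm_rows <- cfg$vm_rows
  if (!is.null(cfg$vm_cols)) args$vm_cols <- cfg$vm_cols
  switch(cfg$layout,
    fig2 = do.call(build_fig2_layout, args),
    fig9 = do.call(build_fig9_layout, args),
    direct = do.call(build_direct_block, c(list(n_ac = cfg$n_ac), args)),
    custom = read_tissue_grid(cfg$grid_file))
}

.run_sheet_experiment <- function(cfg, out_dir, verbose) {
  .ensure_dir(out_dir)
  grid <- .sheet_grid(cfg)
  ckpt_path <- if (!is.null(out_dir)) file.path(out_dir, "checkpoint.rds")

  state <- NULL
  if (isTRUE(cfg$resume) && !is.null(ckpt_path) && file.exists(ckpt_path)) {
    state <- readRDS(ckpt_path)
    if (verbose) message("resuming from checkpoint at t = ", state$time, " ms")
  }
  t_start <- if (is.null(state)) 0 else state$time

  chunk <- if (cfg$checkpoint_every_ms > 0) cfg$checkpoint_every_ms
           else cfg$duration_ms
  traces <- NULL
  snapshots <- NULL; snap_times <- numeric(0)
  t_now <- t_start
  while (t_now < cfg$duration_ms) {
    step_ms <- min(chunk, cfg$duration_ms - t_now)
    run <- run_tissue(grid, step_ms, sample_dt = cfg$sample_dt,
                      snapshot_dt = cfg$snapshot_dt, dt = cfg$dt,
                      init = state)
    state <- run$final
    piece <- run$traces
    if (!is.null(traces)) piece <- piece[-1L, , drop = FALSE] # drop shared sample
    traces <- if (is.null(traces)) piece else rbind(traces, piece)
    if (cfg$snapshot_dt > 0) {
      snapshots <- if (is.null(snapshots)) run$snapshots
                   else {
                     s <- run$snapshots[, , -1L, drop = FALSE]
                     array(c(snapshots, s),
                           dim = c(dim(snapshots)[1:2],
                                   dim(snapshots)[3] + dim(s)[3]))
                   }
      snap_times <- c(snap_times, setdiff(run$snapshot_times, snap_times))
    }
    t_now <- state$time
    if (!is.null(ckpt_path) && cfg$checkpoint_every_ms > 0)
      saveRDS(state, ckpt_path)
    if (verbose && !is.null(cfg$period_window_ms)) {
      pr <- intersect(cfg$probe, names(traces))
      if (length(pr)) {
        mk <- detect_upstrokes(
          data.frame(time = traces$time, vm = traces[[pr[1L]]]),
          threshold_mv = cfg$threshold_mv)
        cl <- mean_cycle_length(mk, max(0, t_now - cfg$period_window_ms), t_now)
        message(sprintf("t = %.0f ms, windowed CL at %s: %s ms", t_now, pr[1L],
                        if (is.na(cl)) "undefined" else format(cl, digits = 7)))
      }
    }
  }

  probe <- if (cfg$probe %in% names(traces)) cfg$probe else
    setdiff(names(traces), "time")[1L]
  mk <- detect_upstrokes(data.frame(time = traces$time, vm = traces[[probe]]),
                         threshold_mv = cfg$threshold_mv)
  periods <- .windowed_periods(mk, 0, cfg$duration_ms, cfg$period_window_ms)
  ecg <- NULL
  if (cfg$snapshot_dt > 0 && !is.null(snapshots))
    ecg <- ecg_trace(snapshots, electrode = as.numeric(cfg$electrode),
                     sigma = cfg$sigma, times = snap_times)
  summary <- list(layout = cfg$layout, probe = probe,
                  n_upstrokes = length(mk$upstroke_times),
                  last_window_cl_ms =
                    periods$mean_cl_ms[nrow(periods)])
  if (!is.null(out_dir)) {
    utils::write.csv(traces, file.path(out_dir, "traces.csv"),
                     row.names = FALSE)
    utils::write.csv(periods, file.path(out_dir, "periods.csv"),
                     row.names = FALSE)
    if (!is.null(ecg))
      utils::write.csv(as.data.frame(ecg), file.path(out_dir, "ecg.csv"),
                       row.names = FALSE)
    yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  }
  list(grid = grid, traces = traces, markers = mk, periods = periods,
       ecg = ecg, snapshots = snapshots, snapshot_times = snap_times,
       final = state, summary = summary)
}

.run_threshold_experiment <- function(cfg, out_dir) {
  .ensure_dir(out_dir)
  est <- find_automaticity_threshold(g_lo = cfg$g_lo, g_hi = cfg$g_hi,
                                     tol = cfg$tol, window_ms = cfg$window_ms,
                                     cell_type = cfg$cell_type, dt = cfg$dt)
  if (!is.null(out_dir))
    yaml::write_yaml(list(threshold_nspf = as.numeric(est),
                          tol = cfg$tol, window_ms = cfg$window_ms,
                          evals = attr(est, "evals")),
                     file.path(out_dir, "summary.yaml"))
  est
}
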