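# 2D monodomain solver driver: compacts a labelled grid into a cell list and
# hands it to the compiled stepping loop.

#' Initial state of every cell in a grid
#'
#' Builds the per-cell state matrix (one column per non-VOID pixel, in
#' column-major pixel order) from the published initial conditions of each
#' pixel's cell model.
#'
#' @param grid A [tissue_grid()].
#' @return A `tissue_state` object: list with the 20 x ncell `state` matrix,
#'   the simulation `time` (ms) and the source `grid` dimensions.
#' @export
init_tissue_state <- function(grid) {
  cg <- .compile_grid(grid)
  st <- matrix(0, length(.state_names), cg$ncell)
  for (ct in unique(cg$ct)) {
    sel <- cg$ct == ct
    st[, sel] <- cpp_init_state(ct)
  }
  structure(list(state = st, time = 0, dim = dim(grid$labels)),
            class = "tissue_state")
}

#' @export
print.tissue_state <- function(x, ...) {
  cat("<tissue_state> ", ncol(x$state), " cells at t = ", x$time, " ms\n",
      sep = "")
  invisible(x)
}

.resolve_probes <- function(grid, probes, cg) {
  if (is.null(probes)) probes <- grid$probes
  if (is.null(probes)) {
    # fall back: first pixel of each tissue class present
    idx1 <- vapply(setdiff(sort(unique(as.integer(grid$labels))), 0L),
                   function(l) which(grid$labels == l)[1L], integer(1))
    rc <- arrayInd(idx1, dim(grid$labels))
    probes <- data.frame(name = names(.LAB)[match(grid$labels[idx1], .LAB)],
                         row = rc[, 1L], col = rc[, 2L])
  }
  stopifnot(all(c("name", "row", "col") %in% names(probes)))
  lin <- cbind(probes$row, probes$col)
  if (any(probes$row < 1 | probes$row > nrow(grid$labels) |
          probes$col < 1 | probes$col > ncol(grid$labels)))
    stop("probe outside the grid")
  ids <- cg$id[lin]
  if (any(ids == 0L)) stop("probe on a VOID pixel: ",
                           paste(probes$name[ids == 0L], collapse = ", "))
  list(names = as.character(probes$name), id0 = ids - 1L)
}

#' Run a 2D monodomain tissue simulation
#'
#' Advances the whole grid with operator splitting (per-step diffusion of the
#' membrane potential through coupled edges, then the ionic update of every
#' cell), records voltage traces at the probe pixels and, optionally,
#' full-field voltage snapshots at a fixed cadence. The run is deterministic:
#' identical inputs give bit-identical outputs, and a run resumed from the
#' returned final state continues exactly as an uninterrupted run (used for
#' checkpointing).
#'
#' The stability precondition `D*dt/dh^2 < 0.25` is checked before any
#' stepping.
#'
#' @param grid A [tissue_grid()].
#' @param duration_ms Simulated duration in ms (> 0).
#' @param probes Data frame `name`, `row`, `col`; defaults to the builder's
#'   probes.
#' @param sample_dt Trace sampling interval in ms.
#' @param snapshot_dt Snapshot cadence in ms; 0 disables snapshots.
#' @param dt Time step in ms (default 0.02).
#' @param init Optional `tissue_state` to resume from (see
#'   [init_tissue_state()]); its `time` is used as the start time.
#' @return A `tissue_run` object: `traces` (data frame, `time` plus one column
#'   per probe), `snapshots` (nrow x ncol x nsnap array with `NA` on VOID
#'   pixels, or `NULL`), `snapshot_times`, `final` (a `tissue_state` for
#'   resuming), and the `grid`.
#' @export
run_tissue <- function(grid, duration_ms, probes = NULL, sample_dt = 1,
                       snapshot_dt = 0, dt = .DT_DEFAULT, init = NULL) {
  stopifnot(inherits(grid, "tissue_grid"))
  if (!(duration_ms > 0)) stop("duration_ms must be positive")
  cg <- .compile_grid(grid)
  dcoef <- .dcoef(grid)
  if (!(dcoef * dt < 0.25))
    stop("stability violated: D*dt/dh^2 = ", format(dcoef * dt, digits = 4),
         " must be < 0.25; reduce dt")
  if (is.null(init)) init <- init_tissue_state(grid)
  stopifnot(inherits(init, "tissue_state"))
  if (ncol(init$state) != cg$ncell)
    stop("init state has ", ncol(init$state), " cells; grid has ", cg$ncell)
  pr <- .resolve_probes(grid, probes, cg)

  res <- cpp_run_tissue(init$state, cg$ct, cg$gk1, cg$nbr, dcoef, dt,
                        init$time, duration_ms, pr$id0, sample_dt, snapshot_dt)

  traces <- data.frame(time = res$times)
  for (p in seq_along(pr$names)) traces[[pr$names[p]]] <- res$traces[, p]

  snapshots <- NULL
  if (snapshot_dt > 0) {
    nr <- nrow(grid$labels); nc <- ncol(grid$labels)
    nsnap <- length(res$snap_times)
    snapshots <- array(NA_real_, c(nr, nc, nsnap))
    for (k in seq_len(nsnap)) {
      f <- matrix(NA_real_, nr, nc)
      f[cg$idx] <- res$snapshots[, k]
      snapshots[, , k] <- f
    }
  }
  structure(list(
    traces = traces,
    snapshots = snapshots,
    snapshot_times = if (snapshot_dt > 0) res$snap_times else numeric(0),
    final = structure(list(state = res$final_state, time = res$t_end,
                           dim = dim(grid$labels)), class = "tissue_state"),
    grid = grid, dt = dt), class = "tissue_run")
}

#' @export
print.tissue_run <- function(x, ...) {
  cat("<tissue_run> ", ncol(x$final$state), " cells, t in [",
      format(x$traces$time[1]), ", ", format(x$final$time), "] ms, ",
      length(x$snapshot_times), " snapshots\n", sep = "")
  invisible(x)
}

#' Advance a tissue state by a fixed number of steps
#'
#' One (or a few) operator-split monodomain steps; a thin wrapper over the
#' same compiled loop as [run_tissue()], mainly for tests and for inspecting
#' short-time behaviour.
#'
#' @param state A `tissue_state` (see [init_tissue_state()]).
#' @param grid The matching [tissue_grid()].
#' @param dt Time step in ms.
#' @param n_steps Number of steps.
#' @return The advanced `tissue_state`.
#' @export
step_tissue <- function(state, grid, dt = .DT_DEFAULT, n_steps = 1L) {
  stopifnot(inherits(state, "tissue_state"), inherits(grid, "tissue_grid"))
  cg <- .compile_grid(grid)
  dcoef <- .dcoef(grid)
  if (!(dcoef * dt < 0.25))
    stop("stability violated: D*dt/dh^2 = ", format(dcoef * dt, digits = 4),
         " must be < 0.25; reduce dt")
  if (ncol(state$state) != cg$ncell)
    stop("state has ", ncol(state$state), " cells; grid has ", cg$ncell)
  res <- cpp_run_tissue(state$state, cg$ct, cg$gk1, cg$nbr, dcoef, dt,
                        state$time, n_steps * dt, integer(0),
                        n_steps * dt, 0)
  structure(list(state = res$final_state, time = res$t_end,
                 dim = dim(grid$labels)), class = "tissue_state")
}

#' Extract the voltage field of a tissue state
#'
#' @param state A `tissue_state`.
#' @param grid The matching [tissue_grid()].
#' @return Matrix of membrane potentials (mV) with `NA` on VOID pixels.
#' @export
voltage_field <- function(state, grid) {
  stopifnot(inherits(state, "tissue_state"), inherits(grid, "tissue_grid"))
  cg <- .compile_grid(grid)
  f <- matrix(NA_real_, nrow(grid$labels), ncol(grid$labels))
  f[cg$idx] <- state$state[1L, ]
  f
}

#' Minimum number of chained automatic cells that drives a myocyte
#'
#' For n = 1, 2, ... builds the 1D chain of n automatic cells plus one
#' ventricular myocyte ([build_chain()]), simulates it stimulus-free for
#' `duration_ms`, and reports the smallest n whose myocyte fires a full
#' action potential (membrane potential crossing `threshold_mv`, default
#' 0 mV). The search stops at the first success; if no n up to `max_n`
#' succeeds the minimum is reported as `NA` ("none").
#'
#' @param max_n Largest chain length to try (>= 1).
#' @param duration_ms Simulated duration per chain in ms.
#' @param dh,D,ac_gk1,vm_type Chain construction parameters, see
#'   [build_chain()].
#' @param dt Time step in ms.
#' @param threshold_mv Full-AP criterion for the driven myocyte.
#' @param sample_dt Trace sampling interval in ms.
#' @param verbose Print one line per chain length.
#' @return A `min_acs` object: `n_min` (integer or `NA`), `first_pacing_ms`
#'   (time of the myocyte's first upstroke in the minimal successful chain,
#'   or `NA`), and `tried`, a data frame with one row per examined n.
#' @export
min_acs_to_drive <- function(max_n = 8, duration_ms = 900000,
                             dh = .DH_DEFAULT, D = .D_DEFAULT,
                             ac_gk1 = .GK1_AC, vm_type = "ENDO",
                             dt = .DT_DEFAULT, threshold_mv = 0,
                             sample_dt = 1, verbose = FALSE) {
  stopifnot(max_n >= 1)
  tried <- data.frame(n_ac = integer(0), paced = logical(0),
                      first_pacing_ms = numeric(0))
  n_min <- NA_integer_; first_ms <- NA_real_
  for (n in seq_len(max_n)) {
    g <- build_chain(n, 1L, dh = dh, D = D, ac_gk1 = ac_gk1, vm_type = vm_type)
    run <- run_tissue(g, duration_ms, sample_dt = sample_dt, dt = dt)
    tr <- data.frame(time = run$traces$time, vm = run$traces$vm1)
    fp <- first_pacing_time(tr, threshold_mv = threshold_mv)
    tried <- rbind(tried, data.frame(n_ac = n, paced = !is.na(fp),
                                     first_pacing_ms = fp))
    if (verbose)
      message("n_ac = ", n, ": ",
              if (is.na(fp)) "VM not paced" else paste0("first pacing at ", fp, " ms"))
    if (!is.na(fp)) {
      n_min <- n; first_ms <- fp
      break
    }
  }
  structure(list(n_min = n_min, first_pacing_ms = first_ms, tried = tried,
                 duration_ms = duration_ms, threshold_mv = threshold_mv),
            class = "min_acs")
}

#' @export
print.min_acs <- function(x, ...) {
  if (is.na(x$n_min)) {
    cat("<min_acs> no chain up to n =", max(x$tried$n_ac),
        "paced the myocyte within", x$duration_ms, "ms\n")
  } else {
    cat("<min_acs> minimum ACs to drive one VM:", x$n_min,
        "(first pacing at", format(x$first_pacing_ms), "ms)\n")
  }
  invisible(x)
}
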