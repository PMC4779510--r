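#' Cell model parameters
#'
#' Bundles the cell model variant and the tunable maximal IK1 conductance.
#' The ventricular variants (`"ENDO"`, `"MID"`, `"EPI"`) are the ten
#' Tusscher-Panfilov (2006) human ventricular myocyte; `"PURKINJE"` is the
#' Stewart et al. (2009) Purkinje fibre cell. All other maximal conductances
#' and kinetic parameters are fixed at their published values; only `g_k1` is
#' exposed, because suppressing IK1 is how automatic (pacemaking) cells are
#' engineered from endocardial myocytes. An automatic cell (AC) is
#' `cell_params("ENDO", g_k1 = 0.05)`.
#'
#' @param cell_type One of `"ENDO"`, `"MID"`, `"EPI"`, `"PURKINJE"`.
#' @param g_k1 Maximal IK1 conductance in nS/pF (non-negative). Defaults to
#'   the published value of the chosen model: 5.405 for the ventricular
#'   variants, 0.065 for the Purkinje cell.
#' @return An object of class `cell_params`.
#' @export
#' @examples
#' cell_params("ENDO")              # quiescent ventricular myocyte
#' cell_params("ENDO", g_k1 = 0.05) # automatic cell (biopacemaker phenotype)
cell_params <- function(cell_type = c("ENDO", "MID", "EPI", "PURKINJE"),
                        g_k1 = NULL) {
  cell_type <- match.arg(cell_type)
  ct <- .CT[[cell_type]]
  if (is.null(g_k1)) g_k1 <- if (ct == .CT[["PURKINJE"]]) .GK1_PURKINJE else .GK1_VM
  stopifnot(is.numeric(g_k1), length(g_k1) == 1L, is.finite(g_k1))
  if (g_k1 < 0) stop("g_k1 must be >= 0 (got ", g_k1, ")")
  structure(list(cell_type = cell_type, ct = ct, g_k1 = as.numeric(g_k1),
                 c_m = 1), # pA/pF current normalization; dV/dt = -I_tot/c_m
            class = "cell_params")
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> ", x$cell_type, ", g_k1 = ", x$g_k1, " nS/pF\n", sep = "")
  invisible(x)
}

.state_names <- c("vm", "ki", "nai", "cai", "ca_ss", "ca_sr", "r_bar",
                  "m", "h", "j", "xr1", "xr2", "xs", "r", "s",
                  "d", "f", "f2", "f_cass", "y")
.gate_names <- c("r_bar", "m", "h", "j", "xr1", "xr2", "xs", "r", "s",
                 "d", "f", "f2", "f_cass", "y")
.conc_names <- c("ki", "nai", "cai", "ca_ss", "ca_sr")

.as_state <- function(x, cell_type) {
  x <- as.numeric(x)
  names(x) <- .state_names
  structure(x, cell_type = cell_type, class = "ionic_state")
}

.check_state <- function(state) {
  if (!is.numeric(state) || length(state) != length(.state_names))
    stop("state must be a numeric vector of length ", length(.state_names),
         " (see init_state())")
  if (any(!is.finite(state))) stop("non-finite state variable(s): ",
                                   paste(.state_names[!is.finite(state)], collapse = ", "))
  invisible(state)
}

#' Published initial state of a cell model
#'
#' Returns the published resting/initial conditions of the chosen model: the
#' membrane potential, gating variables and intracellular / dyadic subspace /
#' sarcoplasmic-reticulum ion concentrations.
#'
#' @param cell_type One of `"ENDO"`, `"MID"`, `"EPI"`, `"PURKINJE"`.
#' @return A named numeric vector of class `ionic_state` (20 variables; the
#'   funny-current gate `y` is only used by the Purkinje model and is 0 for
#'   ventricular cells).
#' @export
#' @examples
#' s <- init_state("ENDO")
#' s["vm"]   # -86.2 mV, published resting potential
init_state <- function(cell_type = c("ENDO", "MID", "EPI", "PURKINJE")) {
  cell_type <- match.arg(cell_type)
  .as_state(cpp_init_state(.CT[[cell_type]]), cell_type)
}

#' @export
print.ionic_state <- function(x, ...) {
  cat("<ionic_state> ", attr(x, "cell_type"), ", vm = ",
      format(x[["vm"]], digits = 6), " mV\n", sep = "")
  print(unclass(x))
  invisible(x)
}

#' Gating variables and concentrations of a state
#'
#' Accessors for the two invariant-bearing parts of an [init_state()] vector:
#' gating variables must lie in \[0, 1\] and concentrations must stay strictly
#' positive under any admissible integration.
#'
#' @param state An `ionic_state` vector.
#' @return A named numeric vector.
#' @export
gating_variables <- function(state) {
  .check_state(state)
  unclass(state)[.gate_names]
}

#' @rdname gating_variables
#' @export
concentrations <- function(state) {
  .check_state(state)
  unclass(state)[.conc_names]
}

#' Membrane currents at a given state
#'
#' Evaluates all transmembrane currents of the governing model at the given
#' state (in pA/pF) and their sum `i_ion`. For the ventricular model these are
#' the 12 currents INa, IK1, Ito, IKr, IKs, ICaL, INaCa, INaK, IpK, IpCa,
#' IbCa, IbNa; the Purkinje model additionally carries the funny current
#' (reported as its sodium and potassium components `i_f_na`, `i_f_k`) and the
#' sustained outward current `i_sus`, which are exactly zero for ventricular
#' cells. `i_ion` is the exact sum of all reported component currents.
#'
#' @param state An `ionic_state` vector (see [init_state()]).
#' @param params A [cell_params()] object.
#' @return A named numeric vector of class `ionic_currents`.
#' @export
#' @examples
#' cur <- compute_currents(init_state("ENDO"), cell_params("ENDO"))
#' cur[["i_ion"]] - sum(cur[names(cur) != "i_ion"])  # 0 by construction
compute_currents <- function(state, params) {
  stopifnot(inherits(params, "cell_params"))
  .check_state(state)
  out <- cpp_compute_currents(as.numeric(state), params$ct, params$g_k1)
  structure(out, class = "ionic_currents", cell_type = params$cell_type)
}

#' Advance a single cell by one or more time steps
#'
#' Integrates the cell model: Rush-Larsen exponential updates for the gating
#' variables and forward Euler for the membrane potential and ion
#' concentrations. Under the stimulus-free convention used throughout the
#' package `i_stim = 0`; a depolarizing stimulus is a *negative* current in
#' pA/pF (e.g. -52 for 1 ms), since dV/dt = -(I_ion + I_stim)/C_m.
#'
#' @param state An `ionic_state` vector.
#' @param params A [cell_params()] object.
#' @param dt Time step in ms (default 0.02).
#' @param i_stim External stimulus current in pA/pF applied during every step.
#' @param n_steps Number of steps to take.
#' @param exact If `TRUE`, evaluate the voltage-dependent rate expressions in
#'   closed form instead of by table lookup (slower; used for verification).
#' @return The advanced `ionic_state`.
#' @export
step_cell <- function(state, params, dt = .DT_DEFAULT, i_stim = 0,
                      n_steps = 1L, exact = FALSE) {
  stopifnot(inherits(params, "cell_params"))
  .check_state(state)
  if (!(dt > 0)) stop("dt must be positive")
  out <- cpp_step_cell(as.numeric(state), params$ct, params$g_k1, dt,
                       as.integer(n_steps), i_stim, isTRUE(exact))
  .as_state(out, params$cell_type)
}

#' Run a single cell and record its membrane potential
#'
#' Integrates one cell for `duration_ms` with no external stimulus (or an
#' optional square pulse) and samples the membrane potential every
#' `sample_dt` ms. With suppressed IK1 (e.g. `g_k1 = 0.05` nS/pF on the
#' endocardial variant) the cell depolarizes spontaneously and fires automatic
#' action potentials; at the published ventricular `g_k1` it stays quiescent.
#'
#' @param params A [cell_params()] object.
#' @param duration_ms Simulated duration in ms (> 0).
#' @param sample_dt Sampling interval of the returned trace in ms.
#' @param dt Integration step in ms (default 0.02).
#' @param init Optional `ionic_state` to start from (defaults to the published
#'   initial state of `params$cell_type`).
#' @param i_stim_amp,i_stim_start,i_stim_duration Optional square stimulus
#'   pulse (pA/pF, ms, ms); negative amplitude depolarizes. Default: none.
#' @param exact Use the closed-form rate evaluation instead of table lookup.
#' @return A data frame of class `voltage_trace` with columns `time` (ms) and
#'   `vm` (mV), carrying the final state in `attr(, "final_state")`.
#' @export
#' @examples
#' \donttest{
#' ac <- run_single_cell(cell_params("ENDO", g_k1 = 0.05), 5000)
#' detect_upstrokes(ac)
#' }
run_single_cell <- function(params, duration_ms, sample_dt = 1, dt = .DT_DEFAULT,
                            init = NULL,
                            i_stim_amp = 0, i_stim_start = 0, i_stim_duration = 0,
                            exact = FALSE) {
  stopifnot(inherits(params, "cell_params"))
  if (!(duration_ms > 0)) stop("duration_ms must be positive")
  if (is.null(init)) init <- init_state(params$cell_type)
  .check_state(init)
  res <- cpp_run_cell(as.numeric(init), params$ct, params$g_k1, dt,
                      duration_ms, sample_dt,
                      i_stim_amp, i_stim_start, i_stim_duration, isTRUE(exact))
  tr <- data.frame(time = res$time, vm = res$vm)
  class(tr) <- c("voltage_trace", "data.frame")
  attr(tr, "params") <- params
  attr(tr, "final_state") <- .as_state(res$final_state, params$cell_type)
  tr
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat("<voltage_trace> ", nrow(x), " samples over [",
      format(x$time[1]), ", ", format(x$time[nrow(x)]), "] ms, vm in [",
      format(min(x$vm), digits = 4), ", ", format(max(x$vm), digits = 4),
      "] mV\n", sep = "")
  invisible(x)
}

#' @export
plot.voltage_trace <- function(x, ...) {
  plot(x$time, x$vm, type = "l", xlab = "time (ms)", ylab = "Vm (mV)", ...)
  invisible(x)
}

#' Write / read a voltage trace as CSV
#'
#' @param trace A `voltage_trace` (or any data frame with `time` and `vm`).
#' @param path File path.
#' @return `read_voltage_trace()` returns a `voltage_trace`;
#'   `write_voltage_trace()` returns `path` invisibly.
#' @export
write_voltage_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("time", "vm")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_voltage_trace
#' @export
read_voltage_trace <- function(path) {
  tr <- utils::read.csv(path)
  stopifnot(all(c("time", "vm") %in% names(tr)))
  class(tr) <- c("voltage_trace", "data.frame")
  tr
}
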