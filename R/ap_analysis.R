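#' Detect action-potential upstrokes in a voltage trace
#'
#' An upstroke is a positive-going crossing of `threshold_mv`, with the
#' crossing time refined by linear interpolation between the bracketing
#' samples. A refractory guard discards crossings closer than
#' `refractory_ms` to the previous accepted upstroke, so threshold chatter
#' cannot be double-counted. The default threshold of -20 mV sits above the
#' diastolic drift of IK1-suppressed cells and well below the overshoot.
#'
#' @param trace A `voltage_trace` (or data frame with `time` and `vm`),
#'   uniformly sampled.
#' @param threshold_mv Crossing threshold in mV.
#' @param refractory_ms Minimum separation between accepted upstrokes in ms.
#' @return An object of class `ap_markers`: list with `upstroke_times` (ms,
#'   strictly increasing) and `cycle_lengths` (ms, successive differences).
#' @export
#' @examples
#' tr <- data.frame(time = 0:30 * 10,
#'                  vm = rep(c(-80, 20, -80), c(10, 3, 18)))
#' detect_upstrokes(tr)
detect_upstrokes <- function(trace, threshold_mv = -20, refractory_ms = 50) {
  tr <- as.data.frame(trace)
  if (nrow(tr) == 0L) stop("empty trace")
  stopifnot(all(c("time", "vm") %in% names(tr)))
  t <- tr$time; v <- tr$vm
  n <- length(v)
  ups <- numeric(0)
  if (n >= 2L) {
    i <- which(v[-n] < threshold_mv & v[-1L] >= threshold_mv)
    if (length(i)) {
      # linear interpolation of the crossing instant
      frac <- (threshold_mv - v[i]) / (v[i + 1L] - v[i])
      tc <- t[i] + frac * (t[i + 1L] - t[i])
      last <- -Inf
      keep <- logical(length(tc))
      for (k in seq_along(tc)) {
        if (tc[k] - last >= refractory_ms) {
          keep[k] <- TRUE
          last <- tc[k]
        }
      }
      ups <- tc[keep]
    }
  }
  structure(list(upstroke_times = ups,
                 cycle_lengths = if (length(ups) > 1L) diff(ups) else numeric(0)),
            class = "ap_markers")
}

#' @export
print.ap_markers <- function(x, ...) {
  cat("<ap_markers> ", length(x$upstroke_times), " upstrokes",
      if (length(x$cycle_lengths))
        paste0(", mean CL ", format(mean(x$cycle_lengths), digits = 6), " ms"),
      "\n", sep = "")
  invisible(x)
}

#' Markers as a tabular record
#'
#' @param x An `ap_markers` object.
#' @param ... Unused.
#' @return Data frame with one row per upstroke: `upstroke_time` and the
#'   `cycle_length` ending at that upstroke (NA for the first).
#' @export
as.data.frame.ap_markers <- function(x, ...) {
  n <- length(x$upstroke_times)
  data.frame(upstroke_time = x$upstroke_times,
             cycle_length = if (n) c(NA_real_, x$cycle_lengths) else numeric(0))
}

#' Mean cycle length within a time window
#'
#' Averages the cycle lengths whose two defining upstrokes both fall inside
#' `[t_start, t_end]`.
#'
#' @param markers An `ap_markers` object (see [detect_upstrokes()]).
#' @param t_start,t_end Window bounds in ms.
#' @return Mean cycle length in ms, or `NA_real_` if fewer than two upstrokes
#'   fall inside the window (undefined).
#' @export
mean_cycle_length <- function(markers, t_start, t_end) {
  stopifnot(inherits(markers, "ap_markers"), t_end > t_start)
  u <- markers$upstroke_times
  u <- u[u >= t_start & u <= t_end]
  if (length(u) < 2L) return(NA_real_)
  mean(diff(u))
}

#' Is a trace automatic?
#'
#' A stimulus-free trace is classified automatic if it contains at least two
#' spontaneous upstrokes within the observation window, i.e. the cell fires
#' repetitively rather than at most a single escape beat.
#'
#' @param trace A `voltage_trace`.
#' @param window_ms Observation window `[0, window_ms]`; defaults to the whole
#'   trace.
#' @param threshold_mv Upstroke threshold in mV (see [detect_upstrokes()]).
#' @return Logical flag.
#' @export
is_automatic <- function(trace, window_ms = NULL, threshold_mv = -20) {
  m <- detect_upstrokes(trace, threshold_mv = threshold_mv)
  u <- m$upstroke_times
  if (!is.null(window_ms)) u <- u[u <= window_ms]
  length(u) >= 2L
}

# bisection for the largest x in [lo, hi] with pred(x) TRUE, assuming pred is
# TRUE at lo, FALSE at hi and monotone in between; returns the last TRUE point
.bisect_largest_true <- function(pred, lo, hi, tol) {
  stopifnot(hi > lo, tol > 0)
  if (!isTRUE(pred(lo))) stop("invalid bracket: predicate is FALSE at the lower endpoint")
  if (isTRUE(pred(hi))) stop("invalid bracket: predicate is TRUE at the upper endpoint")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (isTRUE(pred(mid))) lo <- mid else hi <- mid
  }
  lo
}

#' Largest IK1 conductance that still supports automaticity
#'
#' Bisects the maximal IK1 conductance between a known-automatic lower
#' endpoint and a known-quiescent upper endpoint. At each candidate the cell
#' is integrated stimulus-free over `window_ms` and classified with
#' [is_automatic()]. Returns the largest conductance observed to be automatic,
#' to within `tol`.
#'
#' @param g_lo Lower bracket endpoint in nS/pF (must be automatic).
#' @param g_hi Upper bracket endpoint in nS/pF (must not be automatic).
#' @param tol Bisection tolerance in nS/pF.
#' @param window_ms Observation window per candidate in ms.
#' @param cell_type Cell model variant (default endocardial).
#' @param dt Integration step in ms.
#' @return The threshold estimate in nS/pF, with the number of model runs in
#'   `attr(, "evals")`.
#' @export
find_automaticity_threshold <- function(g_lo = 0.05, g_hi = 3.0, tol = 0.05,
                                        window_ms = 30000,
                                        cell_type = "ENDO", dt = .DT_DEFAULT) {
  evals <- 0L
  pred <- function(g) {
    evals <<- evals + 1L
    tr <- run_single_cell(cell_params(cell_type, g_k1 = g), window_ms,
                          sample_dt = 1, dt = dt)
    is_automatic(tr, window_ms = window_ms)
  }
  est <- .bisect_largest_true(pred, g_lo, g_hi, tol)
  structure(est, evals = evals)
}

#' Time of the first successful pacing of a driven cell
#'
#' For a quiescent (non-automatic) target cell coupled to a pacemaker, the
#' first pacing is the first time its membrane potential makes a
#' positive-going crossing of `threshold_mv`. The default of 0 mV demands a
#' full action potential (overshoot), not a subthreshold depolarization.
#'
#' @param trace A `voltage_trace` of the driven cell.
#' @param threshold_mv Crossing threshold in mV.
#' @return Time of the first upstroke in ms, or `NA_real_` if the cell is
#'   never paced within the trace.
#' @export
first_pacing_time <- function(trace, threshold_mv = 0) {
  m <- detect_upstrokes(trace, threshold_mv = threshold_mv)
  if (length(m$upstroke_times) == 0L) return(NA_real_)
  m$upstroke_times[1L]
}
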