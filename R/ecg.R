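# Pseudo-ECG: far-field potential proxy computed as the dipole integral of
# the membrane-potential gradient over the tissue,
#   ECG = -sigma * sum_xy [ (x-x0) dVm/dx + (y-y0) dVm/dy ] / r^3 * dx*dy,
# discretized with central differences in the interior and one-sided
# differences on the borders. Distances are in pixel units (dx = dy = 1) and
# the electrode position is given in pixel coordinates, x along columns and
# y along rows; sigma is an arbitrary conductivity scale, so the trace is in
# arbitrary units.

# finite-difference gradient along one index with NA-aware fallbacks:
# central where both neighbours exist, one-sided where only one does,
# zero where the pixel itself or both neighbours are missing
.grad_na <- function(f, along = c("col", "row")) {
  along <- match.arg(along)
  if (along == "row") return(t(.grad_na(t(f), "col")))
  nr <- nrow(f); nc <- ncol(f)
  fr <- cbind(f[, -1L, drop = FALSE], rep(NA_real_, nr))   # f(x+1)
  fl <- cbind(rep(NA_real_, nr), f[, -nc, drop = FALSE])   # f(x-1)
  ok <- !is.na(f); okr <- !is.na(fr); okl <- !is.na(fl)
  g <- matrix(0, nr, nc)
  c2 <- ok & okr & okl
  g[c2] <- (fr[c2] - fl[c2]) / 2
  cr <- ok & okr & !okl
  g[cr] <- fr[cr] - f[cr]
  cl <- ok & !okr & okl
  g[cl] <- f[cl] - fl[cl]
  g
}

#' Pseudo-ECG value for one voltage field
#'
#' Evaluates the discretized dipole integral of the transmembrane-potential
#' gradient for a single 2D voltage field, as seen by a unipolar electrode at
#' `electrode` (the reference electrode is at infinity). VOID pixels (`NA`)
#' contribute nothing; gradients next to them fall back to one-sided
#' differences.
#'
#' @param vm_field Numeric matrix of membrane potentials (mV), `NA` on VOID
#'   pixels.
#' @param electrode Electrode position `c(x0, y0)` in pixel coordinates
#'   (x = column index, y = row index); may lie outside the tissue but not on
#'   a tissue pixel.
#' @param sigma Conductivity constant (arbitrary units; the result is linear
#'   in `sigma`).
#' @param grid Optional [tissue_grid()]; if supplied, `NA` is imposed on its
#'   VOID pixels and dimensions are checked.
#' @return A single numeric value (arbitrary units).
#' @export
#' @examples
#' f <- matrix(-85, 8, 8); f[, 1:4] <- 20   # half-depolarized sheet
#' pseudo_ecg_at(f, electrode = c(12, 4.5))
pseudo_ecg_at <- function(vm_field, electrode, sigma = 1, grid = NULL) {
  stopifnot(is.matrix(vm_field), length(electrode) == 2L,
            all(is.finite(electrode)))
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "tissue_grid"))
    if (!identical(dim(vm_field), dim(grid$labels)))
      stop("vm_field dimensions must match the grid")
    vm_field[grid$labels == .LAB[["VOID"]]] <- NA_real_
  }
  nr <- nrow(vm_field); nc <- ncol(vm_field)
  x0 <- electrode[1L]; y0 <- electrode[2L]
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)  # column index
  y <- matrix(rep(seq_len(nr), times = nc), nr, nc) # row index
  r2 <- (x - x0)^2 + (y - y0)^2
  tissue <- !is.na(vm_field)
  if (any(tissue & r2 == 0))
    stop("electrode coincides with a tissue pixel (r = 0)")
  gx <- .grad_na(vm_field, "col")
  gy <- .grad_na(vm_field, "row")
  integrand <- ((x - x0) * gx + (y - y0) * gy) / r2^1.5
  -sigma * sum(integrand[tissue])
}

#' Pseudo-ECG trace from a sequence of voltage snapshots
#'
#' Applies [pseudo_ecg_at()] to every snapshot of a tissue run (or to a plain
#' 3D array of fields), giving the pseudo-ECG time course of the simulated
#' activity.
#'
#' @param snapshots A `tissue_run` (from [run_tissue()] with
#'   `snapshot_dt > 0`), or a 3D array (nrow x ncol x ntime).
#' @param electrode,sigma See [pseudo_ecg_at()].
#' @param times Snapshot times in ms; taken from the run when `snapshots` is a
#'   `tissue_run`.
#' @return A data frame of class `ecg_trace` with columns `time` (ms) and
#'   `ecg` (arbitrary units).
#' @export
ecg_trace <- function(snapshots, electrode, sigma = 1, times = NULL) {
  if (inherits(snapshots, "tissue_run")) {
    if (is.null(snapshots$snapshots))
      stop("run has no snapshots; call run_tissue() with snapshot_dt > 0")
    times <- snapshots$snapshot_times
    snapshots <- snapshots$snapshots
  }
  stopifnot(is.array(snapshots), length(dim(snapshots)) == 3L)
  nt <- dim(snapshots)[3L]
  if (is.null(times)) times <- seq_len(nt)
  if (is.unsorted(times)) stop("snapshots must be time-ordered")
  stopifnot(length(times) == nt)
  vals <- vapply(seq_len(nt), function(k)
    pseudo_ecg_at(snapshots[, , k], electrode = electrode, sigma = sigma),
    numeric(1))
  structure(data.frame(time = times, ecg = vals),
            class = c("ecg_trace", "data.frame"))
}

#' @export
plot.ecg_trace <- function(x, ...) {
  plot(x$time, x$ecg, type = "l", xlab = "time (ms)",
       ylab = "pseudo-ECG (a.u.)", ...)
  invisible(x)
}
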