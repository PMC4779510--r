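# Shared helpers: synthetic traces, brute-force oracles, and cached long runs.

# piecewise-constant "square AP" trace: vm_rest except vm_peak on
# [t_up, t_up + width) for each upstroke time
square_trace <- function(up_times, t_max, dt = 1, vm_rest = -86, vm_peak = 20,
                         width = 200) {
  time <- seq(0, t_max, by = dt)
  vm <- rep(vm_rest, length(time))
  for (tu in up_times) vm[time >= tu & time < tu + width] <- vm_peak
  data.frame(time = time, vm = vm)
}

# brute-force per-pixel 5-point stencil sum honouring the coupling masks;
# independent of the vectorized implementation
laplacian_bruteforce <- function(vm, grid) {
  nr <- nrow(vm); nc <- ncol(vm)
  coupled <- function(r1, c1, r2, c2) {
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) return(FALSE)
    if (r1 == r2) grid$h_couple[r1, min(c1, c2)]
    else grid$v_couple[min(r1, r2), c1]
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    acc <- 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (coupled(r, cc, r2, c2)) acc <- acc + vm[r2, c2] - vm[r, cc]
    }
    out[r, cc] <- acc
  }
  grid$D * 100 / grid$dh^2 * out
}

# brute-force double-sum pseudo-ECG with central differences in the interior
# and one-sided differences at the borders (NA pixels contribute nothing and
# are skipped as gradient neighbours)
pseudo_ecg_bruteforce <- function(vm, electrode, sigma = 1) {
  nr <- nrow(vm); nc <- ncol(vm)
  x0 <- electrode[1]; y0 <- electrode[2]
  val <- function(r, cc) if (r < 1 || r > nr || cc < 1 || cc > nc) NA_real_
                         else vm[r, cc]
  deriv <- function(f0, fm, fp) {
    if (!is.na(fm) && !is.na(fp)) (fp - fm) / 2
    else if (!is.na(fp)) fp - f0
    else if (!is.na(fm)) f0 - fm
    else 0
  }
  total <- 0
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    f0 <- vm[r, cc]
    if (is.na(f0)) next
    gx <- deriv(f0, val(r, cc - 1), val(r, cc + 1))
    gy <- deriv(f0, val(r - 1, cc), val(r + 1, cc))
    rr <- sqrt((cc - x0)^2 + (r - y0)^2)
    total <- total + ((cc - x0) * gx + (r - y0) * gy) / rr^3
  }
  -sigma * total
}

# long automatic-cell run shared by the acceptance tests (computed once)
.ac_cache <- new.env(parent = emptyenv())
ac_markers_long <- function() {
  if (is.null(.ac_cache$markers)) {
    tr <- run_single_cell(cell_params("ENDO", g_k1 = 0.05), 510000)
    .ac_cache$markers <- detect_upstrokes(tr)
  }
  .ac_cache$markers
}
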