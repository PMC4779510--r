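# Single-cell models: initial conditions, currents, stepping, automaticity.

test_that("published initial states satisfy the state invariants", {
  for (ct in c("ENDO", "MID", "EPI", "PURKINJE")) {
    s <- init_state(ct)
    g <- gating_variables(s)
    expect_true(all(g >= 0 & g <= 1), label = paste(ct, "gates in [0,1]"))
    expect_true(all(concentrations(s) > 0), label = paste(ct, "concentrations"))
    expect_true(abs(s[["vm"]]) < 200)
  }
  expect_error(init_state("ATRIAL"))
})

test_that("i_ion is the exact sum of the component currents", {
  for (ct in c("ENDO", "MID", "EPI", "PURKINJE")) {
    p <- cell_params(ct)
    # probe at rest and mid-upstroke-like depolarized states
    for (dv in c(0, 40, 80)) {
      s <- init_state(ct)
      s[1] <- s[1] + dv
      cur <- compute_currents(s, p)
      expect_equal(cur[["i_ion"]], sum(cur[names(cur) != "i_ion"]),
                   tolerance = 1e-14)
    }
  }
})

test_that("Purkinje-only currents are zero for ventricular cells", {
  cur <- compute_currents(init_state("ENDO"), cell_params("ENDO"))
  expect_identical(unname(cur[c("i_f_na", "i_f_k", "i_sus")]), c(0, 0, 0))
  curp <- compute_currents(init_state("PURKINJE"), cell_params("PURKINJE"))
  expect_true(any(curp[c("i_f_na", "i_f_k", "i_sus")] != 0))
})

test_that("IK1 vanishes when g_k1 = 0 and at the K+ reversal potential", {
  s <- init_state("ENDO")
  cur0 <- compute_currents(s, cell_params("ENDO", g_k1 = 0))
  expect_identical(cur0[["i_k1"]], 0)
  # zero driving force: vm set exactly to EK for the stored [K+]i
  rtonf <- 8314.472 * 310 / 96485.3415
  s[1] <- rtonf * log(5.4 / s[["ki"]])
  cur <- compute_currents(s, cell_params("ENDO"))
  expect_equal(cur[["i_k1"]], 0, tolerance = 1e-12)
})

test_that("non-finite states are rejected", {
  s <- init_state("ENDO")
  s[3] <- NaN
  expect_error(compute_currents(s, cell_params("ENDO")), "non-finite")
})

test_that("unmodified ventricular cells are quiescent", {
  # drift < 1 mV over 5,000 ms of stimulus-free integration, all variants
  for (ct in c("ENDO", "MID", "EPI")) {
    tr <- run_single_cell(cell_params(ct), 5000)
    expect_lt(max(abs(tr$vm - tr$vm[1])), 1, label = paste(ct, "drift"))
    expect_equal(length(detect_upstrokes(tr)$upstroke_times), 0L)
  }
})

test_that("the Purkinje cell is intrinsically automatic", {
  tr <- run_single_cell(cell_params("PURKINJE"), 5000)
  m <- detect_upstrokes(tr)
  expect_gte(length(m$upstroke_times), 2L)
})

test_that("suppressing IK1 induces automaticity; nominal IK1 does not", {
  tr <- run_single_cell(cell_params("ENDO", g_k1 = 0.05), 30000)
  expect_gte(length(detect_upstrokes(tr)$upstroke_times), 2L)
  tr3 <- run_single_cell(cell_params("ENDO", g_k1 = 3.0), 30000)
  expect_identical(length(detect_upstrokes(tr3)$upstroke_times), 0L)
})

test_that("spontaneous cycle length shortens as g_k1 decreases", {
  cl <- vapply(c(0, 0.05, 0.1), function(g) {
    tr <- run_single_cell(cell_params("ENDO", g_k1 = g), 30000)
    mean(detect_upstrokes(tr)$cycle_lengths)
  }, numeric(1))
  expect_true(all(diff(cl) > 0)) # CL(0) < CL(0.05) < CL(0.1)
})

test_that("a strong depolarizing stimulus fires an action potential", {
  tr <- run_single_cell(cell_params("ENDO"), 50, sample_dt = 0.1,
                        i_stim_amp = -52, i_stim_start = 5,
                        i_stim_duration = 1)
  expect_gt(max(tr$vm), 0)
})

test_that("stepping is consistent: halving dt shrinks the one-step error", {
  s <- init_state("ENDO")
  p <- cell_params("ENDO", g_k1 = 0.05)
  err <- vapply(c(0.2, 0.1, 0.05), function(dt) {
    one <- step_cell(s, p, dt = dt, exact = TRUE)
    two <- step_cell(s, p, dt = dt / 2, n_steps = 2L, exact = TRUE)
    abs(one[["vm"]] - two[["vm"]])
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 1e-3)
})

test_that("table lookup agrees with closed-form rate evaluation", {
  s <- init_state("ENDO")
  p <- cell_params("ENDO", g_k1 = 0.05)
  a <- step_cell(s, p, dt = 0.02, n_steps = 50000L)            # 1,000 ms
  b <- step_cell(s, p, dt = 0.02, n_steps = 50000L, exact = TRUE)
  expect_equal(a[["vm"]], b[["vm"]], tolerance = 1e-4)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-4)
})

test_that("gating variables stay in [0,1] through long firing runs", {
  p <- cell_params("ENDO", g_k1 = 0.05)
  s <- init_state("ENDO")
  for (k in 1:5) {                      # 5 x 50,000 steps with checks between
    s <- step_cell(s, p, dt = 0.02, n_steps = 50000L)
    g <- gating_variables(s)
    expect_true(all(g >= 0 & g <= 1))
    expect_true(all(concentrations(s) > 0))
  }
})

test_that("an unstable time step is reported as an error", {
  s <- init_state("ENDO")
  expect_error(step_cell(s, cell_params("ENDO"), dt = 50, n_steps = 1000L),
               "instability")
})

test_that("voltage traces round-trip through CSV", {
  tr <- run_single_cell(cell_params("ENDO"), 100)
  path <- tempfile(fileext = ".csv")
  write_voltage_trace(tr, path)
  back <- read_voltage_trace(path)
  expect_equal(back$vm, tr$vm)
  expect_equal(back$time, tr$time)
})
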