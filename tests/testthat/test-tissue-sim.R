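# Monodomain solver: quiescence, insulation, stability, determinism,
# checkpoint-resume, mesh refinement.

LAB <- grid_labels()

test_that("a resting myocyte sheet stays quiescent", {
  g <- tissue_grid(matrix(LAB[["VM_ENDO"]], 5, 5))
  run <- run_tissue(g, 1000, probes = data.frame(name = "c", row = 3, col = 3))
  expect_lt(max(abs(run$traces$c - run$traces$c[1])), 1)
})

test_that("an insulated AC block with no exit window cannot reach the VMs", {
  # 2x2 AC block inside a VM sheet, every AC-VM edge uncoupled, no exit
  lab <- matrix(LAB[["VM_ENDO"]], 6, 6)
  lab[3:4, 3:4] <- LAB[["AC"]]
  nv <- lab != LAB[["VOID"]]
  h <- nv[, -6] & nv[, -1]
  v <- nv[-6, ] & nv[-1, ]
  ac <- lab == LAB[["AC"]]
  a_h <- ac[, -6]; b_h <- ac[, -1]
  h <- h & !xor(a_h, b_h)          # cut mixed AC-VM horizontal edges
  a_v <- ac[-6, ]; b_v <- ac[-1, ]
  v <- v & !xor(a_v, b_v)
  g <- tissue_grid(lab, couple = list(h = h, v = v),
                   layout = list(insulated = TRUE))
  run <- run_tissue(g, 5000, probes = data.frame(
    name = c("ac", "vm_adj", "vm_far"), row = c(3, 3, 1), col = c(3, 5, 1)))
  expect_gt(max(run$traces$ac), 0)               # the block fires...
  expect_lt(max(run$traces$vm_adj), -80)         # ...but no flux reaches VMs
  expect_lt(max(run$traces$vm_far), -80)
  expect_lt(max(run$traces$vm_adj) - run$traces$vm_adj[1], 1)
})

test_that("a violated stability bound is an error before any stepping", {
  g <- build_chain(2, 1)
  expect_error(run_tissue(g, 10, dt = 0.2), "stability")
  st <- init_tissue_state(g)
  expect_error(step_tissue(st, g, dt = 0.2), "stability")
})

test_that("runs are deterministic and resumable bit-for-bit", {
  g <- build_chain(2, 1)
  r1 <- run_tissue(g, 200)
  r2 <- run_tissue(g, 200)
  expect_identical(r1$traces, r2$traces)
  expect_identical(r1$final$state, r2$final$state)
  # checkpoint at 100 ms and resume: identical to the uninterrupted run
  ra <- run_tissue(g, 100)
  rb <- run_tissue(g, 100, init = ra$final)
  expect_identical(rb$final$state, r1$final$state)
  expect_identical(rb$final$time, r1$final$time)
  expect_identical(c(ra$traces$vm1, rb$traces$vm1[-1]), r1$traces$vm1)
})

test_that("step_tissue agrees with run_tissue over the same interval", {
  g <- build_chain(3, 1)
  st <- init_tissue_state(g)
  st2 <- step_tissue(st, g, n_steps = 500L)
  run <- run_tissue(g, 500 * 0.02)
  expect_identical(st2$state, run$final$state)
  f <- voltage_field(st2, g)
  expect_identical(dim(f), dim(g$labels))
  expect_false(anyNA(f))
})

test_that("conduction arrival converges under mesh refinement", {
  arrival <- function(dh, ncell, nkick, probe_cell, dt) {
    g <- tissue_grid(matrix(LAB[["VM_ENDO"]], 1, ncell), dh = dh)
    st <- init_tissue_state(g)
    st$state[1, 1:nkick] <- 20
    run <- run_tissue(g, 60, probes = data.frame(name = "p", row = 1,
                                                 col = probe_cell),
                      sample_dt = dt, dt = dt, init = st)
    first_pacing_time(data.frame(time = run$traces$time, vm = run$traces$p))
  }
  # same physical domain (13.2 mm), kick (1 mm) and probe position (9.8 mm)
  a1 <- arrival(0.165, 80, 6, 60, 0.005)
  a2 <- arrival(0.0825, 160, 12, 120, 0.005)
  expect_lt(abs(a1 - a2) / a2, 0.05)
})

test_that("chains below the source-sink threshold never pace the myocyte", {
  # desk-scale version: short horizon, so even the minimal chain stays silent
  res <- min_acs_to_drive(max_n = 2, duration_ms = 2000)
  expect_true(is.na(res$n_min))
  expect_true(is.na(res$first_pacing_ms))
  expect_identical(nrow(res$tried), 2L)
  expect_false(any(res$tried$paced))
})
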