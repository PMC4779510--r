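# Pseudo-ECG: oracle equality, linearity, border handling, qualitative shape.

test_that("a uniform field produces zero pseudo-ECG", {
  f <- matrix(-86.2, 10, 10)
  expect_identical(pseudo_ecg_at(f, electrode = c(15, 5)), 0)
})

test_that("the discretized dipole sum matches a brute-force double loop", {
  set.seed(11)
  f <- matrix(rnorm(64, -40, 35), 8, 8)
  for (el in list(c(12, 4.5), c(-3, -2), c(4.2, 20))) {
    expect_equal(pseudo_ecg_at(f, electrode = el),
                 pseudo_ecg_bruteforce(f, el), tolerance = 1e-13)
  }
  # with VOID holes: NA pixels contribute nothing, one-sided fallbacks kick in
  f2 <- f; f2[3, 4] <- NA; f2[1, 1] <- NA
  expect_equal(pseudo_ecg_at(f2, electrode = c(12, 4.5)),
               pseudo_ecg_bruteforce(f2, c(12, 4.5)), tolerance = 1e-13)
})

test_that("the pseudo-ECG is linear in sigma and in the voltage field", {
  set.seed(3)
  f <- matrix(rnorm(36, 0, 30), 6, 6)
  g <- matrix(rnorm(36, 0, 30), 6, 6)
  el <- c(9, 3)
  expect_equal(pseudo_ecg_at(f, el, sigma = 2), 2 * pseudo_ecg_at(f, el))
  expect_equal(pseudo_ecg_at(f + g, el),
               pseudo_ecg_at(f, el) + pseudo_ecg_at(g, el), tolerance = 1e-12)
})

test_that("an electrode on a tissue pixel is rejected", {
  f <- matrix(-80, 5, 5)
  expect_error(pseudo_ecg_at(f, electrode = c(3, 2)), "r = 0")
  # on a VOID pixel the distance never vanishes for tissue pixels
  f[2, 3] <- NA
  expect_silent(pseudo_ecg_at(f, electrode = c(3, 2)))
})

test_that("resting snapshots give a flat trace near zero", {
  snaps <- array(-86.2, c(6, 6, 5))
  e <- ecg_trace(snaps, electrode = c(10, 3), times = seq(0, 400, by = 100))
  expect_identical(nrow(e), 5L)
  expect_true(all(abs(e$ecg) < 1e-12))
  expect_error(ecg_trace(snaps, electrode = c(10, 3), times = c(3, 2, 1, 4, 5)),
               "time-ordered")
})

test_that("a front sweeping past a lateral electrode is biphasic", {
  # depolarization front travelling along a 1 x 100 cable; the electrode sits
  # beside the cable at x = 50. The dipole integrand changes sign when the
  # front passes the electrode position, so the deflection is biphasic.
  centers <- seq(10, 90, by = 2)
  vals <- vapply(centers, function(mu) {
    vm <- matrix(-85 + 105 / (1 + exp(-(mu - seq_len(100)) / 1.5)), nrow = 1)
    pseudo_ecg_at(vm, electrode = c(50, 6))
  }, numeric(1))
  expect_lt(vals[1], 0)                       # front approaching
  expect_gt(vals[length(vals)], 0)            # front receding
  # near-odd symmetry about the electrode position (exact symmetry is broken
  # only by the one-sided differences at the cable ends)
  expect_equal(vals[1], -vals[length(vals)], tolerance = 1e-3)
})

test_that("the scaled pacemaker sheet produces a pacing-locked ECG", {
  g <- build_fig9_layout(vm_rows = 10, vm_cols = 16)
  run <- run_tissue(g, 1200, sample_dt = 1, snapshot_dt = 5)
  e <- ecg_trace(run, electrode = c(ncol(g$labels) + 15, 5))
  expect_identical(nrow(e), length(run$snapshot_times))
  expect_true(all(is.finite(e$ecg)))
  # deflection present once the sheet is captured, quiet before the first beat
  m <- detect_upstrokes(data.frame(time = run$traces$time,
                                   vm = run$traces$vm_mid))
  expect_gte(length(m$upstroke_times), 1L)
  t_first <- m$upstroke_times[1]
  before <- abs(e$ecg[e$time < t_first - 50])
  after <- abs(e$ecg[e$time >= t_first - 50])
  expect_gt(max(after), 10 * max(before))
})
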