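# Upstroke detection, cycle lengths, automaticity classification, bisection.

test_that("upstrokes of a constructed square wave are found exactly", {
  tr <- square_trace(c(100, 600, 1100), t_max = 1500)
  m <- detect_upstrokes(tr)
  # crossing interpolated between the -86 sample and the 20 mV sample
  expect_equal(length(m$upstroke_times), 3L)
  expect_equal(diff(m$upstroke_times), c(500, 500))
  expect_equal(m$cycle_lengths, c(500, 500))
})

test_that("flat and single-AP traces give zero / one upstroke", {
  flat <- data.frame(time = 0:100, vm = rep(-86, 101))
  expect_identical(length(detect_upstrokes(flat)$upstroke_times), 0L)
  one <- square_trace(300, t_max = 1000)
  m <- detect_upstrokes(one)
  expect_identical(length(m$upstroke_times), 1L)
  expect_identical(m$cycle_lengths, numeric(0))
  expect_error(detect_upstrokes(data.frame(time = numeric(0), vm = numeric(0))),
               "empty")
})

test_that("marker invariants hold and the tabular export matches", {
  m <- detect_upstrokes(square_trace(c(50, 400, 900, 1600), t_max = 2000))
  expect_true(all(diff(m$upstroke_times) > 0))
  expect_true(all(m$cycle_lengths > 0))
  expect_identical(length(m$cycle_lengths), length(m$upstroke_times) - 1L)
  df <- as.data.frame(m)
  expect_identical(nrow(df), 4L)
  expect_true(is.na(df$cycle_length[1]))
  expect_equal(df$cycle_length[-1], m$cycle_lengths)
})

test_that("detection is invariant to time shifts and subthreshold offsets", {
  base <- square_trace(c(200, 700, 1200), t_max = 1500)
  m0 <- detect_upstrokes(base)
  shifted <- base; shifted$time <- shifted$time + 12345
  m1 <- detect_upstrokes(shifted)
  expect_equal(m1$upstroke_times, m0$upstroke_times + 12345)
  expect_equal(m1$cycle_lengths, m0$cycle_lengths)
  # +10 mV offset never crosses the -20 mV threshold from rest (-86 -> -76)
  offset <- base; offset$vm <- offset$vm + 10
  m2 <- detect_upstrokes(offset)
  expect_identical(length(m2$upstroke_times), length(m0$upstroke_times))
  expect_equal(m2$cycle_lengths, m0$cycle_lengths)
})

test_that("the refractory guard rejects rapid re-crossings", {
  t <- seq(0, 400, by = 1)
  vm <- rep(-86, length(t))
  vm[t >= 100 & t < 120] <- 20
  vm[t >= 125 & t < 145] <- 20   # chatter 25 ms after the first crossing
  vm[t >= 300 & t < 320] <- 20   # genuine second upstroke
  m <- detect_upstrokes(data.frame(time = t, vm = vm))
  expect_identical(length(m$upstroke_times), 2L)
  expect_gt(diff(m$upstroke_times), 150)
})

test_that("mean cycle length uses only upstroke pairs inside the window", {
  m <- detect_upstrokes(square_trace(seq(100, 4100, by = 500), t_max = 4500))
  expect_equal(mean_cycle_length(m, 0, 4500), 500)
  expect_equal(mean_cycle_length(m, 550, 1700), 500)   # two pairs inside
  expect_true(is.na(mean_cycle_length(m, 0, 150)))     # one upstroke only
  expect_error(mean_cycle_length(m, 100, 100))
})

test_that("mean CL of two concatenated periodic segments lies between them", {
  ups <- c(seq(0, 3000, by = 300), seq(3500, 6500, by = 500))
  m <- detect_upstrokes(square_trace(ups, t_max = 7000, width = 100))
  cl <- mean_cycle_length(m, 0, 7000)
  expect_gt(cl, 300)
  expect_lt(cl, 500)
})

test_that("automaticity classification needs two upstrokes in the window", {
  expect_true(is_automatic(square_trace(c(500, 1300), t_max = 2000)))
  expect_false(is_automatic(square_trace(500, t_max = 2000)))
  expect_false(is_automatic(square_trace(c(500, 1300), t_max = 2000),
                            window_ms = 1000))
  flat <- data.frame(time = 0:1000, vm = rep(-86, 1001))
  expect_false(is_automatic(flat))
})

test_that("bisection returns the largest point satisfying the predicate", {
  pred <- function(x) x <= 1.23
  est <- ventpace:::.bisect_largest_true(pred, 0, 3, tol = 0.01)
  expect_true(pred(est))
  expect_false(pred(est + 0.01))
  expect_lt(abs(est - 1.23), 0.01)
  expect_error(ventpace:::.bisect_largest_true(function(x) FALSE, 0, 3, 0.01),
               "bracket")
  expect_error(ventpace:::.bisect_largest_true(function(x) TRUE, 0, 3, 0.01),
               "bracket")
})

test_that("first pacing time reports the first threshold crossing", {
  tr <- square_trace(c(820000, 820900), t_max = 900000, dt = 10)
  fp <- first_pacing_time(tr)
  expect_equal(fp, 820000, tolerance = 1e-3)
  quiet <- data.frame(time = 0:1000, vm = rep(-86, 1001))
  expect_true(is.na(first_pacing_time(quiet)))
})
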