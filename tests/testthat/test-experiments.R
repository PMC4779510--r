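# Config handling and experiment drivers.

test_that("configs are validated: unknown keys and bad values are rejected", {
  cfg <- default_config("single_cell")
  expect_identical(validate_config(cfg)$g_k1, 0.05)
  cfg$typo_key <- 1
  expect_error(validate_config(cfg), "typo_key")
  expect_error(validate_config(list(experiment = "nope")), "experiment")
  bad <- default_config("min_acs"); bad$duration_ms <- -5
  expect_error(validate_config(bad), "duration_ms")
  bad2 <- default_config("single_cell"); bad2$cell_type <- "FOO"
  expect_error(validate_config(bad2), "cell_type")
  bad3 <- default_config("sheet"); bad3$layout <- "custom"
  expect_error(validate_config(bad3), "grid_file")
})

test_that("configs round-trip through YAML", {
  cfg <- default_config("threshold")
  cfg$tol <- 0.1
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  back <- load_config(path)
  expect_identical(back$tol, 0.1)
  expect_identical(back$experiment, "threshold")
})

test_that("the single-cell experiment writes a reproducible summary", {
  cfg <- default_config("single_cell")
  cfg$duration_ms <- 30000
  cfg$stable_after_ms <- 20000
  cfg$window_ms <- 5000
  out1 <- tempfile(); out2 <- tempfile()
  run_experiment(cfg, out_dir = out1)
  run_experiment(cfg, out_dir = out2)
  for (f in c("trace.csv", "markers.csv", "summary.yaml", "manifest.yaml",
              "config.yaml"))
    expect_true(file.exists(file.path(out1, f)), label = f)
  s1 <- yaml::read_yaml(file.path(out1, "summary.yaml"))
  s2 <- yaml::read_yaml(file.path(out2, "summary.yaml"))
  expect_identical(s1, s2)              # deterministic and idempotent
  expect_gt(s1$n_upstrokes, 2)
  # a duration too short for the averaging window is a clear error
  bad <- cfg; bad$duration_ms <- 10000
  expect_error(run_experiment(bad), "must cover")
})

test_that("the min-ACs experiment reports 'none' below the search horizon", {
  cfg <- default_config("min_acs")
  cfg$max_n <- 2L
  cfg$duration_ms <- 1500
  out <- tempfile()
  res <- run_experiment(cfg, out_dir = out)
  expect_true(is.na(res$n_min))
  s <- yaml::read_yaml(file.path(out, "summary.yaml"))
  expect_identical(s$n_min, "none")
  tried <- utils::read.csv(file.path(out, "tried.csv"))
  expect_identical(nrow(tried), 2L)
})

test_that("the sheet experiment runs all layouts and supports checkpoints", {
  cfg <- default_config("sheet")
  cfg$layout <- "direct"; cfg$n_ac <- 9
  cfg$vm_rows <- 12; cfg$vm_cols <- 12
  cfg$duration_ms <- 300
  cfg$period_window_ms <- 150
  res <- run_experiment(cfg)
  expect_s3_class(res$traces, "data.frame")
  expect_null(res$snapshots)            # snapshot cadence 0: traces only
  # custom layout via the serialized grid container
  gf <- tempfile(fileext = ".txt")
  write_tissue_grid(build_chain(2, 1), gf)
  cfg2 <- default_config("sheet")
  cfg2$layout <- "custom"; cfg2$grid_file <- gf
  # probes are not serialized; the run falls back to one probe per cell class
  cfg2$duration_ms <- 100; cfg2$period_window_ms <- 50; cfg2$probe <- "VM_ENDO"
  res2 <- run_experiment(cfg2)
  expect_true(all(c("time", "AC", "VM_ENDO") %in% names(res2$traces)))
  # checkpointed run equals the uninterrupted one
  out <- tempfile()
  cfg3 <- cfg; cfg3$checkpoint_every_ms <- 100; cfg3$snapshot_dt <- 50
  res3 <- run_experiment(cfg3, out_dir = out)
  expect_true(file.exists(file.path(out, "checkpoint.rds")))
  cfg_snap <- cfg; cfg_snap$snapshot_dt <- 50
  res0 <- run_experiment(cfg_snap)
  expect_identical(res3$traces$time, res0$traces$time)
  expect_identical(res3$traces[[2]], res0$traces[[2]])
  expect_identical(res3$final$state, res0$final$state)
  expect_identical(dim(res3$snapshots), dim(res0$snapshots))
  expect_identical(res3$snapshots[, , dim(res3$snapshots)[3]],
                   res0$snapshots[, , dim(res0$snapshots)[3]])
})

test_that("the command-line entry point drives an experiment end to end", {
  cli <- system.file("cli", "ventpace.R", package = "ventpace")
  expect_true(nzchar(cli))
  out <- tempfile()
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli, "min-acs", "--out", out,
                   "--set", "max_n=1", "--set", "duration_ms=500"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "summary.yaml")))
  s <- yaml::read_yaml(file.path(out, "summary.yaml"))
  expect_identical(s$n_min, "none")
})
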