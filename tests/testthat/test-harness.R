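strip_log <- function(log) {
  x <- as.data.frame(log)
  attributes(x)[c("state", "config", "seed")] <- NULL
  x
}

small_config <- function(...) {
  experiment_config(design = "copy_spelling", n_channels = 8, noise_sd = 8,
                    calibration_trials = 16, n_runs = 1, trials_per_run = 16,
                    batch_size = 2, ...)
}

test_that("experiment runs are fully determined by (config, seed)", {
  cfg <- small_config()
  l1 <- run_experiment(cfg, seed = 11)
  l2 <- run_experiment(cfg, seed = 11)
  expect_identical(strip_log(l1), strip_log(l2))
  l3 <- run_experiment(cfg, seed = 12)
  expect_false(identical(strip_log(l1), strip_log(l3)))
  expect_identical(nrow(l1), 32L)
  expect_setequal(unique(l1$phase), c("calibration", "test"))
  expect_true(all(l1$duration_s == 1.9))
})

test_that("configurations round-trip losslessly through YAML", {
  cfg <- small_config(regime = "errp_gated",
                      detector = errp_oracle(0.7, 0.98),
                      latency_drift_ms = 25)
  cfg2 <- config_from_yaml(config_to_yaml(cfg))
  expect_identical(unclass(cfg), unclass(cfg2))
  path <- withr::local_tempfile(fileext = ".yaml")
  config_to_yaml(cfg, path)
  expect_identical(unclass(config_from_yaml(path)), unclass(cfg))
})

test_that("a high-SNR session decodes the copy-spelling phase perfectly", {
  cfg <- experiment_config(design = "copy_spelling", n_channels = 10,
                           noise_sd = 1, calibration_trials = 32,
                           n_runs = 1, trials_per_run = 32,
                           regime = "unsupervised", batch_size = 2)
  log <- run_experiment(cfg, seed = 5)
  expect_equal(mean(log$correct[log$phase == "test"]), 1)
  expect_equal(session_accuracy(dplyr::rename(log[log$phase == "test", ],
                                              true_target = intent)), 1)
})

test_that("the two-target calibration design alternates J and W intents", {
  cfg <- experiment_config(design = "errp_calibration", n_channels = 8,
                           noise_sd = 6, calibration_trials = 8)
  log <- run_experiment(cfg, seed = 2)
  expect_identical(log$intent, rep(c(9L, 22L), 4))
  lay <- target_layout()
  expect_identical(target_char(lay, 9), "J")
  expect_identical(target_char(lay, 22), "W")
  expect_true(all(log$predicted %in% c(9L, 22L)))
})

test_that("free-spelling corrections cost two extra trials per error", {
  cfg <- experiment_config(design = "free_spelling", n_channels = 8,
                           noise_sd = 1, calibration_trials = 32,
                           regime = "unsupervised")
  clean <- run_free_spelling(cfg, "HELLO", seed = 3)
  expect_identical(clean$transcript, "HELLO")
  expect_equal(clean$summary$trials, 5)
  expect_equal(clean$summary$deleted, 0)
  expect_equal(clean$summary$letters_per_min, 5 / (5 * 1.9 / 60))

  oops <- run_free_spelling(cfg, "HELLO", seed = 3, force_error_at = 2L)
  expect_identical(oops$transcript, "HELLO")
  expect_equal(oops$summary$trials, 7)
  expect_equal(oops$summary$deleted, 1)
  expect_equal(oops$summary$trials,
               oops$summary$written + 2 * oops$summary$deleted)
  expect_error(run_free_spelling(cfg, "HEL@O", seed = 1), "not in layout")
})

test_that("regime comparisons replay the identical trial stream per seed", {
  cfg <- small_config()
  res <- adaptation_comparison_study(cfg, regimes = c("none", "supervised"),
                                     seeds = c(3, 4))
  expect_identical(nrow(res), 4L)
  means <- attr(res, "means")
  expect_setequal(means$regime, c("none", "supervised"))
  # calibration phases under both regimes are bit-identical replays
  cfg_a <- cfg; cfg_a$regime <- "none"
  cfg_b <- cfg; cfg_b$regime <- "supervised"
  la <- run_experiment(cfg_a, seed = 3)
  lb <- run_experiment(cfg_b, seed = 3)
  expect_identical(strip_log(la[la$phase == "calibration", ]),
                   strip_log(lb[lb$phase == "calibration", ]))
})

test_that("session logs persist to CSV and JSON-lines", {
  log <- run_experiment(small_config(), seed = 8)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_session_log(log, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(log))
  expect_equal(back$predicted, log$predicted)
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(log, jl)
  lines <- readLines(jl)
  expect_length(lines, nrow(log))
  expect_equal(jsonlite::fromJSON(lines[3])$intent, log$intent[3])
})
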