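test_that("the one-class template behaves like a robust mean", {
  lay <- test_layout()
  # single trial: template is that trial
  v <- sin(2 * pi * (1:630) / 30)
  ts1 <- fit_template(v, layout = lay)
  expect_equal(ts1$base_template, v)

  # clean Gaussian cloud: template close to the arithmetic mean
  mu <- sin(2 * pi * (1:630) / 21) * 4
  X <- withr::with_seed(11, matrix(rnorm(50 * 630), 50, 630) +
                          rep(mu, each = 50))
  ts <- fit_template(X, nu = 0.5, layout = lay)
  rms_dev <- sqrt(mean((ts$base_template - colMeans(X))^2))
  expect_lt(rms_dev, 0.5)  # well under the unit noise sd

  # 20% large-offset outliers: template much closer to the clean mean
  clean <- X[1:40, ]
  outl <- withr::with_seed(12, matrix(rnorm(10 * 630), 10, 630) + 25)
  Xo <- rbind(clean, outl)
  tso <- fit_template(Xo, nu = 0.5, layout = lay)
  cm <- colMeans(clean)
  expect_lt(sqrt(sum((tso$base_template - cm)^2)),
            sqrt(sum((colMeans(Xo) - cm)^2)))
  expect_error(fit_template(matrix(1, 1, 10), nu = 0), "nu")
})

test_that("the fitted template solves the one-class SVM optimization", {
  # cross-check against an independent projected-gradient solver of the
  # same dual, over several nu values and instances
  for (nu in c(0.1, 0.5, 0.9)) {
    for (s in 1:2) {
      X <- withr::with_seed(100 * s + nu * 10,
                            matrix(rnorm(12 * 80), 12, 80) +
                              rep(sin(2 * pi * (1:80) / 16) * 3 + 2,
                                  each = 12))
      lay4 <- target_layout(n_targets = 4, code_length = 63)
      got <- fit_template(X, nu = nu, layout = lay4,
                          samples_per_bit = 1)$base_template
      want <- ocsvm_oracle(X, nu)
      cs <- sum(got * want) / sqrt(sum(got^2) * sum(want^2))
      expect_gt(cs, 0.9999)
    }
  }
})

test_that("templates form the circulant family defined by the code shifts", {
  lay <- test_layout()
  base <- withr::with_seed(5, rnorm(630))
  ts <- template_set(base, layout = lay)
  expect_equal(shift_template(ts, 0), base)
  # target 1: delayed by 2 bits = 20 samples
  expect_equal(shift_template(ts, 1), rotate_delay(base, 20))
  expect_equal(shift_template(ts, 17), rotate_delay(base, 2 * 17 * 10))
  # circular shifting preserves energy
  norms <- apply(ts$templates, 1, function(t) sum(t^2))
  expect_equal(norms, rep(sum(base^2), 32))
  expect_error(shift_template(ts, 32), "target index")
  # round trip: every template classifies as its own target
  for (k in c(0L, 1L, 13L, 31L)) {
    expect_identical(classify_trial(shift_template(ts, k), ts)$target, k)
  }
})

test_that("Euclidean classification breaks ties low and guards shapes", {
  lay <- test_layout()
  ts <- template_set(withr::with_seed(6, rnorm(630)), layout = lay)
  res <- classify_trial(shift_template(ts, 9), ts)
  expect_identical(res$target, 9L)
  expect_equal(unname(res$distances["9"]), 0)
  expect_length(res$distances, 32)
  # constant trial vs constant-free templates: all equidistant -> target 0
  ts_const <- template_set(rep(1, 630), layout = lay)
  expect_identical(classify_trial(rep(0, 630), ts_const)$target, 0L)
  expect_error(classify_trial(rnorm(100), ts), "samples")
  # candidate restriction
  res2 <- classify_trial(shift_template(ts, 22), ts, candidates = c(9, 22))
  expect_identical(res2$target, 22L)
  expect_length(res2$distances, 2)
})

classify_state_like <- function(pipe, trial) {
  classify_trial(apply_filter(pipe$filter, trial), pipe$templates)$target
}

test_that("shift-equivariance: delaying a trial by one lag advances the label", {
  m0 <- test_model(noise_sd = 0)
  lay <- test_layout()
  pipe <- fit_pipeline(make_aligned_trials(m0, 4, seed = 1), lay)
  for (k in c(0L, 7L, 30L)) {
    tr <- simulate_trial(m0, k, seed = 1)
    expect_identical(classify_state_like(pipe, tr), k)
    tr2 <- tr
    tr2$data <- cvep:::rotate_rows(tr$data, 20)
    expect_identical(classify_state_like(pipe, tr2), k + 1L)
  }
})

test_that("correlation classifier is affine-invariant and rejects flat input", {
  m0 <- test_model(noise_sd = 0)
  lay <- test_layout()
  trials <- make_aligned_trials(m0, 4, seed = 2)
  avg <- Reduce(`+`, lapply(trials, function(t) t$data["P4", ])) / 4
  tr <- simulate_trial(m0, 11, seed = 3)
  r <- classify_correlation(tr$data["P4", ], avg, lay)
  expect_identical(r$target, 11L)
  expect_equal(max(r$correlations), 1, tolerance = 1e-9)
  r2 <- classify_correlation(5 * tr$data["P4", ] - 2, avg, lay)
  expect_identical(r2$target, 11L)
  expect_equal(r2$correlations, r$correlations, tolerance = 1e-12)
  expect_error(classify_correlation(rep(1, 630), avg, lay), "zero-variance")
})

test_that("filtered-template decoding outperforms the single-channel baseline
           and degrades monotonically with noise", {
  lay <- test_layout()
  run_seed <- function(seed, noise) {
    model <- test_model(noise_sd = noise)
    seeds <- cvep:::derive_seeds(seed, 48)
    train <- lapply(1:16, function(i)
      align_trial(simulate_trial(model, (i - 1) %% 32, seed = seeds[i]),
                  layout = lay))
    pipe <- fit_pipeline(train, lay)
    avg <- Reduce(`+`, lapply(train, function(t)
      t$data[pipe$best$channel, ])) / 16
    hits <- vapply(1:32, function(i) {
      k <- (i - 1) %% 32
      tt <- simulate_trial(model, k, seed = seeds[16 + i])
      c(classify_trial(apply_filter(pipe$filter, tt),
                       pipe$templates)$target == k,
        classify_correlation(tt$data[pipe$best$channel, ], avg,
                             lay)$target == k)
    }, logical(2))
    rowMeans(hits)
  }
  res <- vapply(1:20, run_seed, numeric(2), noise = 8)
  expect_gt(mean(res[1, ]), mean(res[2, ]))  # OCSVM+CCA above correlation

  acc_at <- function(noise) mean(vapply(1:20, function(s)
    run_seed(s, noise)[1], numeric(1)))
  accs <- vapply(c(4, 8, 12, 16), acc_at, numeric(1))
  expect_true(all(diff(accs) <= 0.02))  # non-increasing up to simulation noise
})
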