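test_that("preprocessing geometry: 110 features, constants annihilate", {
  ch <- cvep_montage(10)
  ep <- simulate_errp_epoch(TRUE, seed = 1, channel_names = ch)
  f <- preprocess_feedback_epoch(ep)
  expect_length(f, 110)
  expect_identical(attr(f, "n_per_channel"), 22L)

  const <- feedback_epoch(matrix(7, 10, 600), 600, ch)
  expect_equal(max(abs(preprocess_feedback_epoch(const))), 0)

  no_cz <- feedback_epoch(matrix(rnorm(9 * 600), 9, 600), 600,
                          setdiff(ch, "Cz"))
  expect_error(preprocess_feedback_epoch(no_cz), "Cz")
  expect_error(feedback_epoch(matrix(0, 10, 300), 600, ch), "1000 ms")
})

test_that("the 1-16 Hz bandpass stops a 25 Hz carrier; CAR+detrend idempotent", {
  ch <- cvep_montage(10)
  t <- (0:599) / 600
  amp <- c(2, rep(1, 9))
  ep25 <- feedback_epoch(outer(amp, sin(2 * pi * 25 * t)), 600, ch)
  f25 <- preprocess_feedback_epoch(ep25)
  # input power in the window, after CAR, for the largest channel
  in_power <- sum((outer(amp - mean(amp), sin(2 * pi * 25 * t))[1, ])^2)
  expect_lt(sum(f25^2) / in_power, 0.01)

  x <- matrix(rnorm(10 * 600), 10, 600) + outer(1:10, t)
  once <- cvep:::car_detrend(x)
  expect_equal(cvep:::car_detrend(once), once, tolerance = 1e-9)
})

test_that("detector separates planted error potentials and degrades to chance
           under label permutation", {
  train <- make_epochs(60, 60, amplitude = 2, seed_base = 0)
  det <- train_errp_detector(train)
  expect_false(det$degenerate)
  expect_gte(det$summary$cv_sensitivity, 0.95)
  expect_gte(det$summary$cv_specificity, 0.95)
  test <- make_epochs(30, 30, amplitude = 2, seed_base = 5000)
  truth <- vapply(test, function(e) isTRUE(e$is_error), logical(1))
  m <- evaluate_detector(predict_errp(det, test), truth)
  expect_gte(m$sensitivity, 0.95)
  expect_gte(m$specificity, 0.95)

  # permuted labels: cross-validated accuracy within chance bounds
  perm <- withr::with_seed(3, sample(c(rep(TRUE, 60), rep(FALSE, 60))))
  detp <- train_errp_detector(train, labels = perm)
  bounds <- qbinom(c(0.0005, 0.9995), 120, 0.5) / 120
  expect_gte(detp$summary$cv_accuracy, bounds[1])
  expect_lte(detp$summary$cv_accuracy, bounds[2])
})

test_that("single-class training yields a degenerate no-error detector", {
  only_correct <- make_epochs(0, 25, seed_base = 100)
  expect_warning(det <- train_errp_detector(only_correct), "single class")
  expect_true(det$degenerate)
  test <- make_epochs(10, 10, seed_base = 7000)
  pred <- predict_errp(det, test)
  expect_false(any(pred))
  m <- evaluate_detector(pred, rep(c(TRUE, FALSE), each = 10))
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
})

test_that("detector metrics count true/false positives as defined", {
  pred <- c(rep(TRUE, 7), rep(FALSE, 3), rep(TRUE, 2), rep(FALSE, 88))
  truth <- c(rep(TRUE, 10), rep(FALSE, 90))
  m <- evaluate_detector(pred, truth)
  expect_equal(m$sensitivity, 0.70)
  expect_equal(m$specificity, 88 / 90)
  expect_equal(m$accuracy, 95 / 100)
  # no positive truths: sensitivity absent, accuracy equals specificity
  m2 <- evaluate_detector(c(FALSE, TRUE, FALSE), rep(FALSE, 3))
  expect_true(is.na(m2$sensitivity))
  expect_equal(m2$accuracy, m2$specificity)
  m3 <- evaluate_detector(truth, truth)
  expect_equal(unlist(m3), c(sensitivity = 1, specificity = 1, accuracy = 1))
  expect_error(evaluate_detector(pred, truth[-1]), "equal length")
})

test_that("subject-wise cross-validation transfers across matched subjects but
           suffers under a planted latency shift", {
  subj <- function(seed_base) make_epochs(20, 20, amplitude = 2,
                                          seed_base = seed_base)
  shift_epochs <- function(epochs, samples) {
    lapply(epochs, function(e) {
      if (isTRUE(e$is_error)) e$data <- cvep:::rotate_rows(e$data, samples)
      e
    })
  }
  sets <- list(A = subj(0), B = subj(300), C = subj(600),
               D = shift_epochs(subj(900), 150))  # ErrP 250 ms late
  res <- subjectwise_cross_validation(sets, cv_folds = 0)
  expect_identical(res$subject, c("A", "B", "C", "D"))
  expect_true(all(res$accuracy[1:3] > 0.85))
  expect_lt(res$sensitivity[4], min(res$sensitivity[1:3]))

  # smallest valid input runs and returns degenerate metrics
  tiny <- list(A = make_epochs(0, 1, seed_base = 1),
               B = make_epochs(0, 1, seed_base = 2))
  res2 <- suppressWarnings(subjectwise_cross_validation(tiny, cv_folds = 0))
  expect_equal(nrow(res2), 2)
  expect_error(subjectwise_cross_validation(tiny[1]), "2 subjects")
})
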