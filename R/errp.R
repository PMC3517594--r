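#' Detection of error-related potentials
#'
#' Feedback-locked epochs are re-referenced to the common average,
#' linearly detrended, bandpass-filtered between 1 and 16 Hz, resampled to
#' 32 Hz, and the 300-990 ms window of five midline channels (Fz, Cz, CPz,
#' Pz, POz) is concatenated into a feature vector.  A binary SVM with an
#' RBF kernel (historical LibSVM defaults: `gamma = 1/n_features`,
#' `cost = 1`) separates error from correct feedback.
#'
#' @name errp
NULL

ERRP_CHANNELS <- c("Fz", "Cz", "CPz", "Pz", "POz")

# CAR + linear detrend, the filter-free part of the chain (idempotent).
car_detrend <- function(data) {
  data <- sweep(data, 2, colMeans(data))
  t_idx <- seq_len(ncol(data))
  xm <- cbind(1, t_idx)
  coef <- t(solve(crossprod(xm), crossprod(xm, t(data))))
  data - coef %*% t(xm)
}

#' Preprocess a feedback-locked epoch into an ErrP feature vector
#'
#' Applies, in order: common-average reference over all channels, linear
#' detrend per channel, zero-phase 4th-order Butterworth bandpass, polyphase
#' resampling to `out_fs`, extraction of the `[window_s[1], window_s[2])`
#' half-open window, channel selection and concatenation.  With the default
#' geometry (five channels, 300-990 ms at 32 Hz) the feature vector has
#' `5 * 22 = 110` entries.
#'
#' @param epoch A [feedback_epoch()].
#' @param channels Channels to keep, in feature order.
#' @param band Bandpass edges in Hz.
#' @param out_fs Resampled rate in Hz.
#' @param window_s Analysis window (seconds after feedback onset),
#'   half-open.
#' @return Numeric feature vector with attribute `n_per_channel`.
#' @export
preprocess_feedback_epoch <- function(epoch, channels = ERRP_CHANNELS,
                                      band = c(1, 16), out_fs = 32,
                                      window_s = c(0.3, 0.99)) {
  stopifnot(inherits(epoch, "feedback_epoch"))
  if (epoch$fs < 64) stop("epoch sampling rate must be at least 64 Hz")
  if (ncol(epoch$data) / epoch$fs < window_s[2]) {
    stop("epoch too short for the analysis window")
  }
  missing <- setdiff(channels, epoch$channel_names)
  if (length(missing)) {
    stop(sprintf("missing channel(s): %s", paste(missing, collapse = ", ")))
  }
  x <- car_detrend(epoch$data)
  bf <- signal::butter(4, band / (epoch$fs / 2), type = "pass")
  x <- t(apply(x, 1, function(r) signal::filtfilt(bf, r)))
  rat <- ratio_pq(out_fs, epoch$fs)
  x <- t(apply(x, 1, function(r) signal::resample(r, rat[1], rat[2])))
  t_res <- (seq_len(ncol(x)) - 1L) / out_fs
  keep <- which(t_res >= window_s[1] & t_res < window_s[2])
  rows <- match(channels, epoch$channel_names)
  feat <- as.numeric(t(x[rows, keep, drop = FALSE]))
  attr(feat, "n_per_channel") <- length(keep)
  feat
}

ratio_pq <- function(p, q) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(p, q)
  c(p / d, q / d)
}

#' Build an ErrP feature matrix from epochs
#'
#' @param epochs List of [feedback_epoch()] objects.
#' @param ... Passed to [preprocess_feedback_epoch()].
#' @return Numeric matrix, one row per epoch.
#' @export
errp_features <- function(epochs, ...) {
  stopifnot(length(epochs) >= 1)
  do.call(rbind, lapply(epochs, preprocess_feedback_epoch, ...))
}

#' Train the ErrP detector
#'
#' Fits an RBF-kernel SVM on the preprocessed feature vectors and reports
#' stratified cross-validated sensitivity, specificity and accuracy.  When
#' the training data contain no error epochs (high-performing users may
#' produce none), a degenerate detector that never reports an error is
#' returned with a warning.
#'
#' @param epochs List of [feedback_epoch()] objects.
#' @param labels Logical error labels; defaults to the epochs' `is_error`.
#' @param gamma RBF width; default `1/n_features`.
#' @param cost Soft-margin cost.
#' @param cv_folds Stratified cross-validation folds for the training
#'   summary (skipped when a class has fewer epochs than folds).
#' @param seed Seed for the fold assignment.
#' @param ... Passed to [preprocess_feedback_epoch()].
#' @return An object of class `errp_detector`.
#' @export
train_errp_detector <- function(epochs, labels = NULL, gamma = NULL,
                                cost = 1, cv_folds = 5, seed = 1, ...) {
  if (length(epochs) == 0) stop("no training epochs")
  labels <- labels %||% vapply(epochs, function(e) isTRUE(e$is_error),
                               logical(1))
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(epochs), !anyNA(labels))
  feats <- errp_features(epochs, ...)
  gamma <- gamma %||% (1 / ncol(feats))

  if (length(unique(labels)) < 2L) {
    warning("training data contain a single class; returning a degenerate ",
            "detector that always predicts 'no error'")
    det <- structure(
      list(model = NULL, degenerate = TRUE, gamma = gamma, cost = cost,
           n_features = ncol(feats),
           summary = tibble::tibble(n_error = sum(labels),
                                    n_correct = sum(!labels),
                                    cv_sensitivity = NA_real_,
                                    cv_specificity = NA_real_,
                                    cv_accuracy = NA_real_)),
      class = "errp_detector")
    return(det)
  }

  y <- factor(labels, levels = c(FALSE, TRUE))
  fit <- e1071::svm(x = feats, y = y, kernel = "radial", gamma = gamma,
                    cost = cost, scale = FALSE)
  cv <- cross_validate_errp(feats, labels, gamma, cost, cv_folds, seed)
  structure(
    list(model = fit, degenerate = FALSE, gamma = gamma, cost = cost,
         n_features = ncol(feats),
         summary = tibble::tibble(n_error = sum(labels),
                                  n_correct = sum(!labels),
                                  cv_sensitivity = cv$sensitivity,
                                  cv_specificity = cv$specificity,
                                  cv_accuracy = cv$accuracy)),
    class = "errp_detector")
}

cross_validate_errp <- function(feats, labels, gamma, cost, folds, seed) {
  per_class_min <- min(table(labels))
  if (folds < 2 || per_class_min < folds) {
    return(list(sensitivity = NA_real_, specificity = NA_real_,
                accuracy = NA_real_))
  }
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (cl in c(TRUE, FALSE)) {
      idx <- which(labels == cl)
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  preds <- logical(length(labels))
  for (f in seq_len(folds)) {
    tr <- fold_of != f
    fit <- e1071::svm(x = feats[tr, , drop = FALSE],
                      y = factor(labels[tr], levels = c(FALSE, TRUE)),
                      kernel = "radial", gamma = gamma, cost = cost,
                      scale = FALSE)
    preds[!tr] <- predict(fit, feats[!tr, , drop = FALSE]) == "TRUE"
  }
  as.list(evaluate_detector(preds, labels))
}

#' @export
print.errp_detector <- function(x, ...) {
  if (x$degenerate) {
    cat("<errp_detector> degenerate (always 'no error')\n")
  } else {
    cat(sprintf("<errp_detector> RBF SVM, %d features, gamma = %.4g\n",
                x$n_features, x$gamma))
  }
  invisible(x)
}

#' Predict error labels for feedback epochs
#'
#' @param detector An [train_errp_detector()] result.
#' @param epochs List of [feedback_epoch()] objects (or a precomputed
#'   feature matrix).
#' @param ... Passed to [preprocess_feedback_epoch()].
#' @return Logical vector: `TRUE` where an ErrP is detected.
#' @export
predict_errp <- function(detector, epochs, ...) {
  stopifnot(inherits(detector, "errp_detector"))
  feats <- if (is.matrix(epochs)) epochs else errp_features(epochs, ...)
  if (detector$degenerate) return(rep(FALSE, nrow(feats)))
  as.logical(predict(detector$model, feats) == "TRUE")
}

#' Sensitivity, specificity and accuracy of a detector
#'
#' Sensitivity is the fraction of true error trials detected; specificity
#' the fraction of correct trials not flagged.  With no error trials in the
#' truth, sensitivity is undefined and reported as `NA` (accuracy then
#' equals specificity).
#'
#' @param predictions,truths Equal-length logical vectors.
#' @return A one-row tibble with `sensitivity`, `specificity`, `accuracy`.
#' @export
evaluate_detector <- function(predictions, truths) {
  predictions <- as.logical(predictions)
  truths <- as.logical(truths)
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length")
  }
  tp <- sum(predictions & truths)
  tn <- sum(!predictions & !truths)
  fp <- sum(predictions & !truths)
  fn <- sum(!predictions & truths)
  tibble::tibble(
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp),
    accuracy = (tp + tn) / length(truths))
}

#' Leave-one-subject-out evaluation of the ErrP detector
#'
#' For each subject the detector is trained on the pooled epochs of all
#' other subjects and evaluated on the held-out subject.
#'
#' @param per_subject_epochs Named list; each element is a list of labelled
#'   [feedback_epoch()] objects for one subject.
#' @param ... Passed to [train_errp_detector()].
#' @return Tibble with one row per subject (sensitivity, specificity,
#'   accuracy).
#' @export
subjectwise_cross_validation <- function(per_subject_epochs, ...) {
  if (length(per_subject_epochs) < 2) stop("need at least 2 subjects")
  subjects <- names(per_subject_epochs) %||%
    as.character(seq_along(per_subject_epochs))
  rows <- lapply(seq_along(per_subject_epochs), function(i) {
    train <- unlist(per_subject_epochs[-i], recursive = FALSE)
    test <- per_subject_epochs[[i]]
    det <- suppressWarnings(train_errp_detector(train, ...))
    truth <- vapply(test, function(e) isTRUE(e$is_error), logical(1))
    pred <- predict_errp(det, test)
    cbind(tibble::tibble(subject = subjects[i]),
          evaluate_detector(pred, truth))
  })
  dplyr::bind_rows(rows)
}
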