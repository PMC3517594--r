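#' Online adaptation of the c-VEP classifier
#'
#' A classifier state bundles the training buffer (label-aligned trials),
#' the spatial filter and the template set.  Retraining re-runs the whole
#' calibration chain on the buffer: best-channel estimation, CCA filter,
#' one-class SVM template, shifted templates for all targets.  Four regimes
#' feed the buffer:
#'
#' * supervised — the true label is known (co-adaptive calibration);
#' * unsupervised — the predicted label is assumed correct (self-training);
#' * ErrP-gated — self-training, but trials on which an error potential is
#'   detected are discarded because their label is suspect;
#' * two-target ErrP calibration — classification is restricted to a target
#'   pair and a detected error flips the label to the other pair member.
#'
#' Retraining is synchronous by default (after every accepted trial);
#' setting `batch_size > 1` defers retraining, emulating an adaptation loop
#' running in parallel with classification: trials accepted mid-batch wait
#' for the next retrain and their waiting time is logged in trials.
#'
#' @name adaptation
NULL

#' Initialize a classifier state with random templates
#'
#' The starting point of co-adaptive and ErrP-based calibration: the base
#' template is standard-normal noise (so initial classification is at
#' chance) and the spatial filter is a uniform channel average.
#'
#' @param layout A [target_layout()].
#' @param ns Samples per trial (one code period).
#' @param seed Seed for the random base template.
#' @param channel_names Montage labels.
#' @param fs Sampling rate in Hz.
#' @param nu One-class SVM parameter used at every retrain.
#' @param batch_size Retrain after this many accepted trials (1 =
#'   synchronous).
#' @param freeze_channel If `TRUE`, the best channel is estimated once and
#'   reused by later retrains.
#' @param ridge Ridge passed to the CCA solver.
#' @return An object of class `classifier_state`.
#' @export
init_random_templates <- function(layout = target_layout(), ns = 630,
                                  seed = 1,
                                  channel_names = cvep_montage(),
                                  fs = 600, nu = 0.5, batch_size = 1,
                                  freeze_channel = FALSE, ridge = 1e-8) {
  nc <- length(channel_names)
  base <- with_seed(seed, stats::rnorm(ns))
  w <- rep(1 / sqrt(nc), nc)
  names(w) <- channel_names
  spb <- as.integer(fs / 60)
  structure(
    list(layout = layout, ns = as.integer(ns), fs = fs,
         samples_per_bit = spb,
         lags = layout$table$shift_bits * spb,
         channel_names = channel_names, nu = nu,
         batch_size = as.integer(batch_size),
         freeze_channel = freeze_channel, ridge = ridge,
         filter = structure(list(weights = w, best_channel = NA_integer_,
                                 best_channel_accuracy = NA_real_,
                                 canonical_correlation = NA_real_),
                            class = "spatial_filter"),
         templates = template_set(base, nu = nu, layout = layout,
                                  samples_per_bit = spb),
         buffer = list(), pending = 0L, pending_events = integer(0),
         events = list(), generation = 0L, frozen = FALSE),
    class = "classifier_state"
  )
}

#' @export
print.classifier_state <- function(x, ...) {
  cat(sprintf(paste0("<classifier_state> generation %d, %d buffered trials",
                     ", best channel %s%s\n"),
              x$generation, length(x$buffer),
              ifelse(is.na(x$filter$best_channel), "?",
                     x$channel_names[x$filter$best_channel]),
              if (x$frozen) " [frozen]" else ""))
  invisible(x)
}

#' Classify a raw trial with the current classifier state
#'
#' @param state A `classifier_state`.
#' @param trial A [trial_eeg()].
#' @param candidates Optional target subset (two-target calibration).
#' @return As [classify_trial()].
#' @export
classify_state <- function(state, trial, candidates = NULL) {
  classify_trial(apply_filter(state$filter, trial), state$templates,
                 candidates = candidates)
}

# Append an aligned trial (with caches) to the buffer and retrain when the
# batch is full.
state_add <- function(state, trial, label_used, label_true, predicted,
                      errp_detected, action) {
  idx <- trial$trial_index
  if (is.na(idx)) idx <- length(state$events) + 1L
  ev <- list(trial_index = idx, predicted_label = predicted,
             true_label = if (is.null(label_true)) NA_integer_ else
               as.integer(label_true),
             errp_detected = errp_detected, action = action,
             generation = state$generation,
             retrain_latency_trials = NA_integer_)
  state$events <- c(state$events, list(ev))
  if (action == "rejected" || state$frozen) {
    state$events[[length(state$events)]]$retrain_latency_trials <- NA_integer_
    return(state)
  }
  aligned <- align_trial(trial, label_used, state$layout)
  entry <- list(raw = aligned$data,
                cache = trial_loo_cache(aligned$data, state$lags),
                gram = tcrossprod(aligned$data),
                rsum = rowSums(aligned$data),
                label_used = as.integer(label_used),
                label_true = if (is.null(label_true)) NA_integer_ else
                  as.integer(label_true))
  state$buffer <- c(state$buffer, list(entry))
  state$pending <- state$pending + 1L
  state$pending_events <- c(state$pending_events, length(state$events))
  if (state$pending >= state$batch_size) state <- retrain_state(state)
  state
}

#' Retrain the classifier on the full training buffer
#'
#' Runs best-channel estimation, CCA and template fitting on every buffered
#' trial; increments the generation counter.  Called automatically when a
#' batch fills; call it directly to flush a partial batch at session end.
#'
#' @param state A `classifier_state`.
#' @return The retrained state.
#' @export
retrain_state <- function(state) {
  n <- length(state$buffer)
  if (n == 0L) return(state)
  nc <- length(state$channel_names)
  ns <- state$ns
  if (n >= 2L) {
    if (!state$freeze_channel || is.na(state$filter$best_channel)) {
      acc <- loo_channel_accuracies(lapply(state$buffer, `[[`, "cache"),
                                    state$lags)
      best <- which.max(acc)
      best_acc <- acc[best]
    } else {
      best <- state$filter$best_channel
      best_acc <- state$filter$best_channel_accuracy
    }
    msum <- Reduce(`+`, lapply(state$buffer, `[[`, "raw"))
    ybar <- msum[best, ] / n
    nn <- n * ns
    sgram <- Reduce(`+`, lapply(state$buffer, `[[`, "gram"))
    srow <- Reduce(`+`, lapply(state$buffer, `[[`, "rsum"))
    mu <- srow / nn
    cxx <- sgram / nn - tcrossprod(mu)
    cxy <- (msum %*% ybar) / nn - mu * mean(ybar)
    cyy <- mean(ybar^2) - mean(ybar)^2
    if (cyy == 0) stop("reference Y is constant")
    state$filter <- cca_from_cov(cxx, cxy, cyy, best_channel = best,
                                 best_channel_accuracy = best_acc,
                                 channel_names = state$channel_names,
                                 ridge = state$ridge)
  }
  filt <- t(vapply(state$buffer,
                   function(e) as.numeric(state$filter$weights %*% e$raw),
                   numeric(ns)))
  state$templates <- fit_template(filt, nu = state$nu, layout = state$layout,
                                  samples_per_bit = state$samples_per_bit)
  state$generation <- state$generation + 1L
  npend <- length(state$pending_events)
  for (j in seq_along(state$pending_events)) {
    k <- state$pending_events[j]
    state$events[[k]]$retrain_latency_trials <- npend - j
  }
  state$pending <- 0L
  state$pending_events <- integer(0)
  state
}

#' Supervised adaptation step
#'
#' The trial is classified (for the co-adaptive feedback log), re-shifted
#' to the target-0 frame under its true label, appended to the buffer, and
#' the classifier is retrained.
#'
#' @param state A `classifier_state`.
#' @param trial A [trial_eeg()].
#' @param true_label The attended target index (0-based).
#' @return The updated state.
#' @export
supervised_adapt <- function(state, trial, true_label) {
  stopifnot(true_label >= 0, true_label < state$layout$n_targets)
  pred <- classify_state(state, trial)$target
  state_add(state, trial, label_used = true_label, label_true = true_label,
            predicted = pred, errp_detected = NA, action = "supervised_add")
}

#' Unsupervised (self-training) adaptation step
#'
#' The predicted label is assumed correct and the trial is added under it.
#'
#' @inheritParams supervised_adapt
#' @return The updated state.
#' @export
unsupervised_adapt <- function(state, trial) {
  pred <- classify_state(state, trial)$target
  state_add(state, trial, label_used = pred,
            label_true = trial$attended_target, predicted = pred,
            errp_detected = NA, action = "added_as_predicted")
}

#' ErrP-gated adaptation step
#'
#' Behaves like [unsupervised_adapt()] unless an error potential was
#' detected after the feedback, in which case the trial is discarded (its
#' label is suspect) and the state is unchanged.
#'
#' @inheritParams supervised_adapt
#' @param errp_detected Logical: did the error detector fire?
#' @return The updated state.
#' @export
errp_gated_adapt <- function(state, trial, errp_detected) {
  pred <- classify_state(state, trial)$target
  if (isTRUE(errp_detected)) {
    return(state_add(state, trial, label_used = NA, predicted = pred,
                     label_true = trial$attended_target,
                     errp_detected = TRUE, action = "rejected"))
  }
  state_add(state, trial, label_used = pred,
            label_true = trial$attended_target, predicted = pred,
            errp_detected = FALSE, action = "added_as_predicted")
}

#' Two-target ErrP-based calibration step
#'
#' Classification is restricted to the two targets of `pair`.  Without a
#' detected error the trial is added under the predicted label; with one it
#' is added under the other pair member (label flipping).
#'
#' @inheritParams errp_gated_adapt
#' @param pair Integer vector of two distinct target indices.
#' @return The updated state.
#' @export
errp_calibrate_2target <- function(state, trial, errp_detected, pair) {
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[1] == pair[2] ||
      any(pair < 0) || any(pair >= state$layout$n_targets)) {
    stop("pair must be two distinct valid target indices")
  }
  pred <- classify_state(state, trial, candidates = pair)$target
  if (isTRUE(errp_detected)) {
    label <- setdiff(pair, pred)
    action <- "added_as_flipped"
  } else {
    label <- pred
    action <- "added_as_predicted"
  }
  state_add(state, trial, label_used = label,
            label_true = trial$attended_target, predicted = pred,
            errp_detected = isTRUE(errp_detected), action = action)
}

#' Adaptation events as a tibble
#'
#' One row per processed trial: predicted and true labels, ErrP flag, the
#' action taken, the classifier generation used for the prediction, and the
#' retrain latency in trials (0 in synchronous mode).
#'
#' @param state A `classifier_state`.
#' @return A tibble.
#' @export
adaptation_events <- function(state) {
  if (length(state$events) == 0) {
    return(tibble::tibble(trial_index = integer(), predicted_label = integer(),
                          true_label = integer(), errp_detected = logical(),
                          action = character(), generation = integer(),
                          retrain_latency_trials = integer()))
  }
  dplyr::bind_rows(lapply(state$events, function(e)
    tibble::as_tibble(lapply(e, function(v) if (is.null(v)) NA else v))))
}

#' Label contamination of the training buffer
#'
#' Fraction of buffered trials whose assumed label differs from the true
#' label, among trials with a known truth.  Exactly 0 under supervised
#' adaptation; equals the online error rate on accepted trials under
#' self-training.
#'
#' @param state A `classifier_state`.
#' @return A fraction in `[0, 1]` (NaN if no truth is known).
#' @export
buffer_contamination <- function(state) {
  truth <- vapply(state$buffer, `[[`, integer(1), "label_true")
  used <- vapply(state$buffer, `[[`, integer(1), "label_used")
  known <- !is.na(truth)
  mean(used[known] != truth[known])
}
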