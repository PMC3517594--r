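#' Closed-loop experiment harness
#'
#' Reproduces the study designs end-to-end on synthetic EEG: supervised
#' co-adaptive calibration, copy-spelling runs under a chosen adaptation
#' regime, two-target ErrP-based calibration with label flipping, and
#' free-spelling with a correcting user model.  Every stochastic element is
#' driven by sub-seeds derived from one master seed, so a (config, seed)
#' pair determines every output exactly.
#'
#' @name harness
NULL

#' Oracle error detector
#'
#' Replaces the trained ErrP detector with stated operating
#' characteristics, isolating adaptation behaviour from detector quality.
#'
#' @param sensitivity Probability a true error is flagged.
#' @param specificity Probability a correct trial is not flagged.
#' @return A detector specification list.
#' @export
errp_oracle <- function(sensitivity = 1, specificity = 1) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  list(type = "oracle", sensitivity = sensitivity, specificity = specificity)
}

# One oracle decision given the (perceived) error status and a uniform draw.
oracle_decision <- function(oracle, is_error, u) {
  if (is_error) u < oracle$sensitivity else u < 1 - oracle$specificity
}

#' User model for free-spelling
#'
#' @param perception_reliability Probability the user notices an erroneous
#'   selection (and therefore corrects it with a backspace).
#' @return A user model list.
#' @export
user_model <- function(perception_reliability = 1) {
  stopifnot(perception_reliability >= 0, perception_reliability <= 1)
  list(perception_reliability = perception_reliability)
}

#' Experiment configuration
#'
#' Collects everything a closed-loop run needs: the experimental design,
#' forward-model parameters, the adaptation regime, detector
#' specification, batching and timing.  All fields are plain values, so a
#' config round-trips losslessly through YAML.
#'
#' @param design One of `"calibration"`, `"copy_spelling"`,
#'   `"errp_calibration"`, `"free_spelling"`.
#' @param n_channels Montage size (prefix of [cvep_montage()]).
#' @param noise_sd,kernel_amplitude,latency_s Forward-model parameters.
#' @param calibration_trials Supervised calibration length (64 covers each
#'   of 32 targets twice).
#' @param n_runs,trials_per_run Copy-spelling test phase geometry.
#' @param regime Adaptation during the test phase: `"none"`,
#'   `"unsupervised"`, `"errp_gated"` or `"supervised"`.
#' @param detector Detector spec: [errp_oracle()] or
#'   `list(type = "trained")` (supply the trained detector to
#'   [run_experiment()]).
#' @param nu,batch_size,freeze_channel Classifier-state parameters.
#' @param latency_drift_ms,amp_drift Linear drift endpoints over the whole
#'   session (see [linear_drift()]).
#' @param errp_amplitude,errp_noise_sd Feedback-epoch generation.
#' @param pair Two-target calibration pair (defaults to the targets of the
#'   letters J and W).
#' @param perception_reliability See [user_model()].
#' @param stimulation_s,pause_s Trial timing (selection period is their
#'   sum).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(design = "copy_spelling",
                              n_channels = 30,
                              noise_sd = 8,
                              kernel_amplitude = 4,
                              latency_s = 0.036,
                              calibration_trials = 64,
                              n_runs = 9,
                              trials_per_run = 64,
                              regime = "unsupervised",
                              detector = errp_oracle(1, 1),
                              nu = 0.5,
                              batch_size = 1,
                              freeze_channel = FALSE,
                              latency_drift_ms = 0,
                              amp_drift = 0,
                              errp_amplitude = 1,
                              errp_noise_sd = 6,
                              pair = c(9, 22),
                              perception_reliability = 1,
                              stimulation_s = 63 / 60,
                              pause_s = 0.85) {
  design <- match.arg(design, c("calibration", "copy_spelling",
                                "errp_calibration", "free_spelling"))
  regime <- match.arg(regime, c("none", "unsupervised", "errp_gated",
                                "supervised"))
  structure(
    list(design = design, n_channels = as.integer(n_channels),
         noise_sd = noise_sd, kernel_amplitude = kernel_amplitude,
         latency_s = latency_s,
         calibration_trials = as.integer(calibration_trials),
         n_runs = as.integer(n_runs),
         trials_per_run = as.integer(trials_per_run),
         regime = regime, detector = detector, nu = nu,
         batch_size = as.integer(batch_size),
         freeze_channel = freeze_channel,
         latency_drift_ms = latency_drift_ms, amp_drift = amp_drift,
         errp_amplitude = errp_amplitude, errp_noise_sd = errp_noise_sd,
         pair = as.integer(pair),
         perception_reliability = perception_reliability,
         stimulation_s = stimulation_s, pause_s = pause_s),
    class = "experiment_config"
  )
}

#' Serialize a configuration to YAML (and back, losslessly)
#'
#' @param config An [experiment_config()].
#' @param path Optional file path.
#' @return YAML string.
#' @export
config_to_yaml <- function(config, path = NULL) {
  y <- yaml::as.yaml(unclass(config))
  if (!is.null(path)) {
    writeLines(y, path)
    return(invisible(y))
  }
  y
}

#' @rdname config_to_yaml
#' @param yaml_text YAML string or file path.
#' @export
config_from_yaml <- function(yaml_text) {
  obj <- if (file.exists(yaml_text)) yaml::read_yaml(yaml_text) else
    yaml::yaml.load(yaml_text)
  do.call(experiment_config, obj[setdiff(names(obj), "design_extra")])
}

# Forward model + layout for a config.
config_model <- function(config, backspace = FALSE) {
  layout <- target_layout(backspace = backspace)
  code <- generate_msequence()
  channels <- cvep_montage(config$n_channels)
  forward_model(code = code, layout = layout,
                channel_names = channels,
                kernel = default_cvep_kernel(code,
                                             amplitude =
                                               config$kernel_amplitude),
                mixing = cvep_mixing(channels),
                latency_s = config$latency_s,
                noise_sd = config$noise_sd)
}

config_drift <- function(config) {
  if (config$latency_drift_ms == 0 && config$amp_drift == 0) return(no_drift())
  linear_drift(latency_drift_ms = config$latency_drift_ms,
               amp_drift = config$amp_drift)
}

config_state <- function(config, model, seed) {
  init_random_templates(layout = model$layout, ns = model$n_samples,
                        seed = seed, channel_names = model$channel_names,
                        fs = model$fs, nu = config$nu,
                        batch_size = config$batch_size,
                        freeze_channel = config$freeze_channel)
}

# Intent sequences for the designs.
calibration_intents <- function(n_targets, n_trials) {
  rep(rep(0:(n_targets - 1L), 2), length.out = n_trials)
}

copy_intents <- function(n_targets, n_trials) {
  rep(0:(n_targets - 1L), length.out = n_trials)
}

#' Run a closed-loop experiment
#'
#' Executes the configured design and returns the per-trial session log as
#' a tibble (attributes: the final `classifier_state` and the config).
#' Columns: `phase`, `trial`, `intent`, `predicted`, `correct`, `error`
#' (selection differed from intent), `errp_true` (the user perceived an
#' error), `errp_detected`, `action`, `generation`, `duration_s`.
#'
#' @param config An [experiment_config()].
#' @param seed Master seed.
#' @param errp_detector A trained [train_errp_detector()] object, required
#'   when `config$detector$type == "trained"`.
#' @return A session-log tibble.
#' @export
run_experiment <- function(config, seed = 1, errp_detector = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (identical(config$detector$type, "trained") && is.null(errp_detector)) {
    stop("config requests a trained detector; pass `errp_detector`")
  }
  model <- config_model(config)
  lay <- model$layout
  timing <- trial_timing(config$stimulation_s, config$pause_s)

  n_cal <- config$calibration_trials
  n_test <- config$n_runs * config$trials_per_run
  intents <- switch(config$design,
    calibration = calibration_intents(lay$n_targets, n_cal),
    copy_spelling = c(calibration_intents(lay$n_targets, n_cal),
                      copy_intents(lay$n_targets, n_test)),
    errp_calibration = rep(config$pair, length.out = n_cal),
    stop("run_experiment does not handle design '", config$design, "'"))
  phases <- switch(config$design,
    calibration = rep("calibration", n_cal),
    copy_spelling = c(rep("calibration", n_cal), rep("test", n_test)),
    errp_calibration = rep("errp_calibration", n_cal))

  seeds <- derive_seeds(seed, 3L)
  stream <- simulate_session_stream(model, intents, seed = seeds[1],
                                    drift = config_drift(config),
                                    errp_amplitude = config$errp_amplitude,
                                    errp_noise_sd = config$errp_noise_sd)
  state <- config_state(config, model, seeds[2])
  u <- with_seed(seeds[3], stats::runif(2L * length(intents)))

  n <- length(intents)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    trial <- stream$trial(i)
    phase <- phases[i]
    two_target <- config$design == "errp_calibration"
    cand <- if (two_target) config$pair else NULL
    pred <- classify_state(state, trial, candidates = cand)$target
    err <- pred != intents[i]
    perceived <- err && (u[2 * i - 1] <= config$perception_reliability)
    det <- NA
    action <- "none"

    if (phase == "calibration") {
      state <- supervised_adapt(state, trial, intents[i])
      action <- "supervised_add"
    } else if (two_target) {
      det <- detect_feedback_error(config, errp_detector, stream, i,
                                   perceived, u[2 * i])
      state <- errp_calibrate_2target(state, trial, det, config$pair)
      action <- if (det) "added_as_flipped" else "added_as_predicted"
    } else if (phase == "test") {
      if (config$regime == "none") {
        action <- "none"
      } else if (config$regime == "supervised") {
        state <- supervised_adapt(state, trial, intents[i])
        action <- "supervised_add"
      } else if (config$regime == "unsupervised") {
        state <- unsupervised_adapt(state, trial)
        action <- "added_as_predicted"
      } else {
        det <- detect_feedback_error(config, errp_detector, stream, i,
                                     perceived, u[2 * i])
        state <- errp_gated_adapt(state, trial, det)
        action <- if (det) "rejected" else "added_as_predicted"
      }
    }
    rows[[i]] <- tibble::tibble(
      phase = phase, trial = i, intent = intents[i], predicted = pred,
      correct = !err, error = err, errp_true = perceived,
      errp_detected = det, action = action,
      generation = state$generation, duration_s = timing$trial_s)
  }
  if (state$pending > 0L) state <- retrain_state(state)
  log <- dplyr::bind_rows(rows)
  attr(log, "state") <- state
  attr(log, "config") <- config
  attr(log, "seed") <- seed
  log
}

# Detector decision for trial i (oracle or trained on the simulated epoch).
detect_feedback_error <- function(config, errp_detector, stream, i,
                                  perceived, u) {
  if (identical(config$detector$type, "oracle")) {
    return(oracle_decision(config$detector, perceived, u))
  }
  epoch <- stream$epoch(i, is_error = perceived)
  predict_errp(errp_detector, list(epoch))[1]
}

#' Run a free-spelling session
#'
#' Calibrates supervised, then simulates spelling `text`: the user intends
#' the next needed character, or the backspace after a perceived mistake;
#' each trial is classified and (under the configured regime) used for
#' adaptation.  The session ends when the text is complete or the trial
#' budget is exhausted.
#'
#' @param config An [experiment_config()].
#' @param text Character string to spell (letters A-Z, underscore, digits).
#' @param seed Master seed.
#' @param user A [user_model()].
#' @param max_trials Trial budget (default: generous multiple of the text
#'   length).
#' @param force_error_at Trial indices (within the spelling phase) whose
#'   classification is forced to a wrong target — a deterministic way to
#'   exercise the correction loop.
#' @param errp_detector Optional trained detector (for `errp_gated`).
#' @return A list: `summary` (tibble, see [free_spelling_row()]), `log`
#'   (per-trial tibble), `transcript`, `state`.
#' @export
run_free_spelling <- function(config, text, seed = 1, user = user_model(),
                              max_trials = 4L * nchar(text) + 40L,
                              force_error_at = integer(0),
                              errp_detector = NULL) {
  stopifnot(inherits(config, "experiment_config"), nchar(text) > 0)
  model <- config_model(config, backspace = TRUE)
  lay <- model$layout
  bs <- backspace_target(lay)
  goal <- strsplit(toupper(text), "")[[1]]
  bad <- setdiff(goal, lay$table$char[-(bs + 1L)])
  if (length(bad)) {
    stop(sprintf("character(s) not in layout: %s", paste(bad, collapse = ", ")))
  }
  timing <- trial_timing(config$stimulation_s, config$pause_s)
  seeds <- derive_seeds(seed, 4L)

  # supervised calibration
  cal_int <- calibration_intents(lay$n_targets, config$calibration_trials)
  cal_stream <- simulate_session_stream(model, cal_int, seed = seeds[1])
  state <- config_state(config, model, seeds[2])
  for (i in seq_along(cal_int)) {
    state <- supervised_adapt(state, cal_stream$trial(i), cal_int[i])
  }
  if (state$pending > 0L) state <- retrain_state(state)

  trial_seeds <- derive_seeds(seeds[3], max_trials)
  u <- with_seed(seeds[4], stats::runif(2L * max_trials))

  transcript <- character(0)
  rows <- list()
  i <- 0L
  while (i < max_trials) {
    if (length(transcript) == length(goal) &&
        all(transcript == goal)) break
    i <- i + 1L
    # intent: backspace after a perceived mistake, else the next character
    mismatch <- length(transcript) > 0 &&
      !all(transcript == goal[seq_along(transcript)])
    intent <- if (mismatch) bs else char_target(lay, goal[length(transcript) + 1L])
    trial <- simulate_trial(model, intent, seed = trial_seeds[i],
                            trial_index = i)
    pred <- classify_state(state, trial)$target
    if (i %in% force_error_at) {
      pred <- (intent + 1L) %% lay$n_targets
    }
    err <- pred != intent
    perceived <- err && (u[2 * i - 1] <= user$perception_reliability)
    det <- NA
    if (pred == bs) {
      if (length(transcript) > 0) transcript <- transcript[-length(transcript)]
    } else {
      transcript <- c(transcript, target_char(lay, pred))
    }
    if (config$regime == "unsupervised") {
      state <- unsupervised_adapt(state, trial)
    } else if (config$regime == "supervised") {
      state <- supervised_adapt(state, trial, intent)
    } else if (config$regime == "errp_gated") {
      det <- detect_feedback_error(config, errp_detector,
                                   simulate_session_stream(model, intent,
                                                           seed = trial_seeds[i]),
                                   1L, perceived, u[2 * i])
      state <- errp_gated_adapt(state, trial, det)
    }
    rows[[i]] <- tibble::tibble(
      trial = i, intent = intent, predicted = pred, error = err,
      is_backspace = pred == bs, errp_true = perceived, errp_detected = det,
      duration_s = timing$trial_s)
  }
  if (state$pending > 0L) state <- retrain_state(state)
  log <- dplyr::bind_rows(rows)
  list(summary = free_spelling_summary(log), log = log,
       transcript = paste(transcript, collapse = ""), state = state)
}

#' Compare adaptation regimes on identical synthetic sessions
#'
#' For each seed, the exact same trial stream (same calibration, same test
#' trials, same drift) is replayed under each regime; only the adaptation
#' rule differs.  Returns per-(regime, seed) test accuracies plus per-regime
#' means.
#'
#' @param config An [experiment_config()] with `design = "copy_spelling"`.
#' @param regimes Character vector of regimes to compare.
#' @param seeds Integer vector of session seeds.
#' @param errp_detector Optional trained detector for `errp_gated`.
#' @return A tibble (`regime`, `seed`, `accuracy`); per-regime means in
#'   attribute `"means"`.
#' @export
adaptation_comparison_study <- function(config,
                                        regimes = c("none", "unsupervised",
                                                    "errp_gated",
                                                    "supervised"),
                                        seeds = 1:20,
                                        errp_detector = NULL) {
  stopifnot(length(seeds) >= 1)
  rows <- list()
  for (s in seeds) {
    for (rg in regimes) {
      cfg <- config
      cfg$regime <- rg
      log <- run_experiment(cfg, seed = s, errp_detector = errp_detector)
      test <- log[log$phase == "test", ]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        regime = rg, seed = s, accuracy = mean(test$correct))
    }
  }
  out <- dplyr::bind_rows(rows)
  means <- dplyr::summarise(dplyr::group_by(out, .data$regime),
                            mean_accuracy = mean(.data$accuracy),
                            .groups = "drop")
  attr(out, "means") <- means
  out
}

#' Write a session log to CSV / JSON-lines
#'
#' @param log A session-log tibble.
#' @param path Output path; format chosen by extension (`.csv` or
#'   `.jsonl`).
#' @return `path`, invisibly.
#' @export
write_session_log <- function(log, path) {
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(log))) {
      writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"), con)
    }
  } else {
    utils::write.csv(log, path, row.names = FALSE)
  }
  invisible(path)
}
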