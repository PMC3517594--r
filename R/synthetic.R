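#' Synthetic multichannel EEG with code-locked c-VEP responses
#'
#' The generator plants the signal structure a c-VEP speller relies on: a
#' latent source waveform locked to the binary modulation code, mixed into
#' the scalp channels with a fixed spatial pattern concentrated over
#' parieto-occipital electrodes, delayed by a visual-system latency, and
#' buried in broadband noise.  Per-target responses are circular shifts of
#' one waveform — precisely the assumption the template classifier exploits.
#' Feedback-locked epochs optionally carry an error-related potential: a
#' small fronto-central negativity near 310 ms followed by a positivity near
#' 420 ms on error trials.
#'
#' @name synthetic
NULL

#' Electrode montage used by the simulator
#'
#' Channels are ordered so that any prefix contains the electrodes the
#' decoding and error-detection stages require (Fz, Cz, CPz, Pz, POz, P4,
#' PO3).  The full montage has 30 EEG channels.
#'
#' @param n_channels Number of channels (7 to 30).
#' @return Character vector of 10-20 channel labels.
#' @export
cvep_montage <- function(n_channels = 30) {
  full <- c("Fz", "Cz", "CPz", "Pz", "POz", "P4", "PO3",
            "PO4", "O1", "P3", "C3", "C4", "F3", "F4", "CP1", "CP2",
            "FC1", "FC2", "P7", "P8", "F7", "F8", "FC5", "FC6",
            "CP5", "CP6", "T7", "T8", "Fp1", "Fp2")
  stopifnot(n_channels >= 7, n_channels <= length(full))
  full[seq_len(n_channels)]
}

#' Default code-locked source waveform (one code period)
#'
#' The +/-1 stimulus sequence, upsampled to the EEG rate, is circularly
#' convolved with a short damped-oscillation impulse response (two damped
#' sinusoids), giving a periodic waveform qualitatively like an average
#' c-VEP: broadband, code-locked, a few microvolts in amplitude.
#'
#' @param code A [binary_code()].
#' @param fs EEG sampling rate in Hz.
#' @param amplitude Peak amplitude scale in microvolts.
#' @return Numeric vector of length `bits_to_samples(length(code), fs,
#'   code$refresh_rate)`.
#' @export
default_cvep_kernel <- function(code, fs = 600, amplitude = 4) {
  spb <- fs / code$refresh_rate
  stim <- rep(2 * code$bits - 1, each = spb)
  n <- length(stim)
  t <- seq(0, 0.12, by = 1 / fs)
  h <- exp(-t / 0.015) * sin(2 * pi * 13 * t) +
    0.6 * exp(-t / 0.045) * sin(2 * pi * 6 * t)
  hpad <- c(h, numeric(n - length(h)))
  resp <- Re(stats::fft(stats::fft(stim) * stats::fft(hpad), inverse = TRUE)) / n
  amplitude * resp / max(abs(resp))
}

#' Spatial mixing pattern of the c-VEP source
#'
#' Unit-norm channel weights, maximal at P4 and large over the
#' parieto-occipital row, near zero frontally.
#'
#' @param channel_names Montage labels.
#' @return Named unit-norm numeric vector.
#' @export
cvep_mixing <- function(channel_names = cvep_montage()) {
  w <- c(P4 = 1, PO3 = 0.92, POz = 0.88, PO4 = 0.84, O1 = 0.8,
         Pz = 0.7, P3 = 0.62, P7 = 0.4, P8 = 0.4,
         CPz = 0.32, CP1 = 0.25, CP2 = 0.25, CP5 = 0.2, CP6 = 0.2,
         Cz = 0.18, C3 = 0.12, C4 = 0.12)
  v <- ifelse(channel_names %in% names(w), w[channel_names], 0.05)
  names(v) <- channel_names
  v / sqrt(sum(v^2))
}

# Fronto-central topography of the error-related potential.
errp_topography <- function(channel_names) {
  w <- c(Fz = 0.9, Cz = 1, FC1 = 0.85, FC2 = 0.85, F3 = 0.6, F4 = 0.6,
         CPz = 0.55, C3 = 0.45, C4 = 0.45, Pz = 0.3, POz = 0.15)
  v <- ifelse(channel_names %in% names(w), w[channel_names], 0.05)
  names(v) <- channel_names
  v
}

#' Forward model for synthetic c-VEP trials
#'
#' @param code A [binary_code()].
#' @param layout A [target_layout()].
#' @param fs EEG sampling rate in Hz (must be a multiple of the refresh rate).
#' @param channel_names Montage labels (see [cvep_montage()]).
#' @param kernel Source waveform of one code period; defaults to
#'   [default_cvep_kernel()].
#' @param mixing Unit-norm channel weights; defaults to [cvep_mixing()].
#' @param latency_s Response latency in seconds (rounded to whole samples;
#'   the default 0.036 matches a typical c-VEP delay).
#' @param noise_sd Additive white-noise standard deviation in microvolts.
#' @param pink_noise_sd Optional additional 1/f noise standard deviation.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(code = generate_msequence(),
                          layout = target_layout(),
                          fs = 600,
                          channel_names = cvep_montage(),
                          kernel = NULL,
                          mixing = NULL,
                          latency_s = 0.036,
                          noise_sd = 8,
                          pink_noise_sd = 0) {
  stopifnot(fs %% code$refresh_rate == 0, noise_sd >= 0, pink_noise_sd >= 0)
  kernel <- kernel %||% default_cvep_kernel(code, fs)
  mixing <- mixing %||% cvep_mixing(channel_names)
  ns <- bits_to_samples(length(code), fs, code$refresh_rate)
  stopifnot(length(kernel) == ns, length(mixing) == length(channel_names))
  structure(
    list(code = code, layout = layout, fs = fs,
         channel_names = channel_names, kernel = kernel, mixing = mixing,
         latency_s = latency_s,
         latency_samples = as.integer(round(latency_s * fs)),
         noise_sd = noise_sd, pink_noise_sd = pink_noise_sd,
         samples_per_bit = as.integer(fs / code$refresh_rate),
         n_samples = ns),
    class = "forward_model"
  )
}

#' @export
print.forward_model <- function(x, ...) {
  cat(sprintf(paste0("<forward_model> %d ch x %d samples @ %g Hz, ",
                     "latency %.0f ms, noise sd %.2g uV\n"),
              length(x$channel_names), x$n_samples, x$fs,
              1000 * x$latency_s, x$noise_sd))
  invisible(x)
}

#' Construct a single EEG trial object
#'
#' @param data Channels x samples matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_names Channel labels (row names).
#' @param attended_target Attended target index (0-based) or `NA`.
#' @param trial_index Ordinal position in the session, or `NA`.
#' @return An object of class `trial_eeg`.
#' @export
trial_eeg <- function(data, fs, channel_names, attended_target = NA,
                      trial_index = NA) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_names))
  rownames(data) <- channel_names
  structure(
    list(data = data, fs = fs, channel_names = channel_names,
         attended_target = attended_target, trial_index = trial_index),
    class = "trial_eeg"
  )
}

#' @export
print.trial_eeg <- function(x, ...) {
  cat(sprintf("<trial_eeg> %d ch x %d samples @ %g Hz, target %s\n",
              nrow(x$data), ncol(x$data), x$fs,
              ifelse(is.na(x$attended_target), "?", x$attended_target)))
  invisible(x)
}

#' Simulate one stimulation trial
#'
#' The planted response for target `k` is the model kernel circularly
#' delayed by `k * bit_lag` bits plus the response latency, scaled by
#' `amp_scale`, mixed into the channels, plus additive noise.  Deterministic
#' given `seed`.
#'
#' @param model A [forward_model()].
#' @param target Attended target index (0-based).
#' @param seed Integer seed for the noise.
#' @param amp_scale Multiplier on the response amplitude (drift hook).
#' @param latency_shift Additional latency in samples (drift hook).
#' @param trial_index Ordinal recorded on the trial.
#' @return A [trial_eeg()].
#' @export
simulate_trial <- function(model, target, seed = 1, amp_scale = 1,
                           latency_shift = 0, trial_index = NA) {
  lay <- model$layout
  if (target < 0 || target >= lay$n_targets || target != round(target)) {
    stop(sprintf("target must be in 0..%d", lay$n_targets - 1L))
  }
  shift <- lay$bit_lag * as.integer(target) * model$samples_per_bit +
    model$latency_samples + as.integer(round(latency_shift))
  src <- amp_scale * rotate_delay(model$kernel, shift)
  clean <- outer(model$mixing, src)
  noise <- 0
  if (model$noise_sd > 0 || model$pink_noise_sd > 0) {
    noise <- with_seed(seed, {
      w <- matrix(stats::rnorm(length(clean), sd = max(model$noise_sd, 1e-12)),
                  nrow = nrow(clean))
      if (model$pink_noise_sd > 0) {
        p <- matrix(stats::rnorm(length(clean)), nrow = nrow(clean))
        p <- t(apply(p, 1, function(r) stats::filter(r, 0.95, "recursive")))
        p <- p / stats::sd(p) * model$pink_noise_sd
        w + p
      } else w
    })
  }
  trial_eeg(clean + noise, model$fs, model$channel_names,
            attended_target = as.integer(target), trial_index = trial_index)
}

#' Construct a feedback-locked epoch object
#'
#' @param data Channels x samples matrix starting at feedback onset.
#' @param fs Sampling rate in Hz.
#' @param channel_names Channel labels.
#' @param is_error Logical error label or `NA`.
#' @return An object of class `feedback_epoch`.
#' @export
feedback_epoch <- function(data, fs, channel_names, is_error = NA) {
  stopifnot(is.matrix(data), nrow(data) == length(channel_names))
  if (ncol(data) / fs < 1) stop("epoch must cover at least 0-1000 ms")
  rownames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 is_error = is_error),
            class = "feedback_epoch")
}

#' Simulate a feedback-locked epoch
#'
#' Error epochs contain a negative deflection near 310 ms and a positive
#' deflection near 420 ms after feedback onset, largest over fronto-central
#' channels; correct epochs contain noise only.
#'
#' @param is_error Whether the trial feedback was erroneous.
#' @param amplitude_scale Multiplier on the planted deflections (0 removes
#'   them entirely).
#' @param seed Integer seed.
#' @param fs Sampling rate in Hz.
#' @param channel_names Montage labels.
#' @param duration_s Epoch length in seconds (must cover the 300-990 ms
#'   analysis window).
#' @param noise_sd Additive white-noise standard deviation in microvolts.
#' @return A [feedback_epoch()].
#' @export
simulate_errp_epoch <- function(is_error, amplitude_scale = 1, seed = 1,
                                fs = 600, channel_names = cvep_montage(),
                                duration_s = 1, noise_sd = 6) {
  stopifnot(amplitude_scale >= 0, duration_s >= 1)
  ns <- as.integer(round(duration_s * fs))
  t <- (seq_len(ns) - 1L) / fs
  data <- matrix(0, nrow = length(channel_names), ncol = ns)
  if (isTRUE(is_error) && amplitude_scale > 0) {
    wave <- -3 * exp(-((t - 0.31) / 0.025)^2) + 5 * exp(-((t - 0.42) / 0.035)^2)
    data <- outer(errp_topography(channel_names), amplitude_scale * wave)
  }
  if (noise_sd > 0) {
    data <- data + with_seed(seed, matrix(stats::rnorm(length(data),
                                                       sd = noise_sd),
                                          nrow = nrow(data)))
  }
  feedback_epoch(data, fs, channel_names, is_error = is_error)
}

#' Drift schedules
#'
#' A drift schedule maps the trial index `i` (1-based) and session length
#' `n` to slow perturbations of the forward model: an amplitude scale and an
#' extra response latency.  [no_drift()] is the identity;
#' [linear_drift()] interpolates linearly from zero to the stated endpoint
#' over the session.
#'
#' @return A function `(i, n) -> list(amp_scale, latency_shift)` (samples).
#' @export
no_drift <- function() {
  function(i, n) list(amp_scale = 1, latency_shift = 0)
}

#' @rdname no_drift
#' @param latency_drift_ms Total latency increase over the session, ms.
#' @param amp_drift Total fractional amplitude change over the session
#'   (e.g. -0.3 ends at 70 percent amplitude).
#' @param fs Sampling rate used to convert ms to samples.
#' @export
linear_drift <- function(latency_drift_ms = 0, amp_drift = 0, fs = 600) {
  function(i, n) {
    frac <- if (n > 1) (i - 1) / (n - 1) else 0
    list(amp_scale = 1 + amp_drift * frac,
         latency_shift = round(latency_drift_ms / 1000 * fs * frac))
  }
}

#' Deterministic session stream of trials and feedback epochs
#'
#' Returns a generator for a closed-loop session: `trial(i)` yields the
#' i-th stimulation trial for the intended target under the drift schedule,
#' and `epoch(i, is_error)` yields the matching feedback-locked epoch.  The
#' error status of an epoch is decided by the caller (the harness), because
#' it depends on the classifier's outcome; `errp_amplitude` scales the
#' planted deflections.  Two streams built with the same arguments are
#' identical.
#'
#' @param model A [forward_model()].
#' @param intents Integer vector of intended targets (0-based), one per trial.
#' @param seed Master seed; per-trial sub-seeds are derived from it.
#' @param drift A drift schedule ([no_drift()], [linear_drift()]).
#' @param errp_amplitude Amplitude scale for planted error potentials.
#' @param errp_noise_sd Noise level of feedback epochs.
#' @return An object of class `session_stream` with elements `n`, `intents`,
#'   `trial(i)` and `epoch(i, is_error)`.
#' @export
simulate_session_stream <- function(model, intents, seed = 1,
                                    drift = no_drift(),
                                    errp_amplitude = 1,
                                    errp_noise_sd = 6) {
  intents <- as.integer(intents)
  stopifnot(all(intents >= 0), all(intents < model$layout$n_targets))
  n <- length(intents)
  seeds <- matrix(derive_seeds(seed, 2L * max(n, 1L)), ncol = 2)
  trial_fun <- function(i) {
    stopifnot(i >= 1, i <= n)
    d <- drift(i, n)
    simulate_trial(model, intents[i], seed = seeds[i, 1],
                   amp_scale = d$amp_scale, latency_shift = d$latency_shift,
                   trial_index = i)
  }
  epoch_fun <- function(i, is_error) {
    stopifnot(i >= 1, i <= n)
    simulate_errp_epoch(is_error, amplitude_scale = errp_amplitude,
                        seed = seeds[i, 2], fs = model$fs,
                        channel_names = model$channel_names,
                        noise_sd = errp_noise_sd)
  }
  structure(list(n = n, intents = intents, trial = trial_fun,
                 epoch = epoch_fun, seed = seed),
            class = "session_stream")
}

#' Write trials to a plain-text container (CSV + JSON sidecar)
#'
#' Each trial becomes a block of rows in one long CSV (trial, channel,
#' sample, value); metadata (sampling rate, montage, labels) goes to a JSON
#' sidecar next to it.
#'
#' @param trials List of [trial_eeg()] objects.
#' @param path CSV file path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  stopifnot(length(trials) > 0)
  long <- do.call(rbind, lapply(seq_along(trials), function(i) {
    tr <- trials[[i]]
    data.frame(trial = i,
               channel = rep(tr$channel_names, each = ncol(tr$data)),
               sample = rep(seq_len(ncol(tr$data)), nrow(tr$data)),
               value = as.vector(t(tr$data)))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  meta <- list(fs = trials[[1]]$fs, channel_names = trials[[1]]$channel_names,
               attended_target = vapply(trials, function(t)
                 as.integer(t$attended_target %||% NA), integer(1)))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, null = "null"),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  lapply(sort(unique(long$trial)), function(i) {
    b <- long[long$trial == i, ]
    ns <- max(b$sample)
    mat <- matrix(b$value, ncol = ns, byrow = TRUE)
    rownames(mat) <- b$channel[seq(1, nrow(b), by = ns)]
    mat <- mat[meta$channel_names, , drop = FALSE]
    trial_eeg(mat, meta$fs, meta$channel_names,
              attended_target = meta$attended_target[i], trial_index = i)
  })
}
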