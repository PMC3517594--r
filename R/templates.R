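#' One-class SVM templates and nearest-template classification
#'
#' After spatial filtering, all training trials (aligned to the target-0
#' frame) are summarized into one template by a one-class support vector
#' machine with a linear kernel.  The solution is a capped-simplex weighted
#' mean of the trials — an outlier-robust average: trials that would inflate
#' the enclosing region get zero or bounded weight.  Because every target
#' flashes the same code at a different circular shift, the templates of all
#' other targets are circular shifts of the base template, and a new trial
#' is classified by the smallest Euclidean distance to the shifted
#' templates.
#'
#' @name templates
NULL

#' Fit the base template with a one-class SVM
#'
#' @param filtered_trials A numeric matrix (trials x samples) or a list of
#'   equal-length numeric vectors of spatially filtered, label-aligned
#'   trials.
#' @param nu One-class SVM parameter in (0, 1]: an upper bound on the
#'   fraction of training trials treated as outliers.
#' @param layout A [target_layout()] (defines how many shifted templates to
#'   derive).
#' @param samples_per_bit EEG samples per stimulus bit (10 at 600 Hz/60 Hz).
#' @return An object of class `template_set`: `base_template`, `templates`
#'   (n_targets x Ns matrix, row k+1 = template of target k), `nu`,
#'   `samples_per_bit`.
#' @export
fit_template <- function(filtered_trials, nu = 0.5, layout = target_layout(),
                         samples_per_bit = 10) {
  if (is.list(filtered_trials)) {
    filtered_trials <- do.call(rbind, filtered_trials)
  }
  if (is.vector(filtered_trials)) {
    filtered_trials <- matrix(filtered_trials, nrow = 1)
  }
  stopifnot(is.matrix(filtered_trials), nrow(filtered_trials) >= 1)
  if (!(nu > 0 && nu <= 1)) stop("nu must be in (0, 1]")
  n <- nrow(filtered_trials)
  if (n == 1L) {
    base <- filtered_trials[1, ]
  } else {
    fit <- e1071::svm(x = filtered_trials, type = "one-classification",
                      kernel = "linear", nu = nu, scale = FALSE)
    alpha <- as.numeric(fit$coefs)
    base <- as.numeric(crossprod(fit$coefs, fit$SV)) / sum(alpha)
  }
  template_set(base, nu = nu, layout = layout,
               samples_per_bit = samples_per_bit)
}

#' Assemble a template set from a base template
#'
#' @param base_template Numeric vector (one code period, filtered space).
#' @param nu The OCSVM parameter recorded on the set.
#' @inheritParams fit_template
#' @return A `template_set`.
#' @export
template_set <- function(base_template, nu = 0.5, layout = target_layout(),
                         samples_per_bit = 10) {
  ns <- length(base_template)
  shifts <- layout$table$shift_bits * samples_per_bit
  tmpl <- t(vapply(shifts, function(s) rotate_delay(base_template, s),
                  numeric(ns)))
  structure(
    list(base_template = base_template, templates = tmpl,
         nu = nu, samples_per_bit = as.integer(samples_per_bit),
         n_targets = layout$n_targets, bit_lag = layout$bit_lag),
    class = "template_set"
  )
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d targets x %d samples, nu = %g\n",
              x$n_targets, length(x$base_template), x$nu))
  invisible(x)
}

#' Template of a single target
#'
#' Target `k`'s template is the base template circularly delayed by
#' `k * bit_lag` bits (in samples); shifting by target 0 is the identity.
#'
#' @param set A `template_set`.
#' @param k Target index (0-based).
#' @return Numeric vector.
#' @export
shift_template <- function(set, k) {
  if (length(k) != 1L || k < 0 || k >= set$n_targets || k != round(k)) {
    stop(sprintf("target index k must be in 0..%d", set$n_targets - 1L))
  }
  set$templates[k + 1L, ]
}

#' Classify a filtered trial by minimum Euclidean distance
#'
#' @param filtered_trial Numeric vector (one code period, filtered space).
#' @param set A `template_set`.
#' @param candidates Optional integer vector of target indices to restrict
#'   the decision to (used during two-target calibration).
#' @return List with `target` (0-based index of the nearest template) and
#'   `distances` (named numeric vector over the candidates).  Ties go to
#'   the lowest target index.
#' @export
classify_trial <- function(filtered_trial, set, candidates = NULL) {
  ns <- ncol(set$templates)
  if (length(filtered_trial) != ns) {
    stop(sprintf("trial has %d samples, templates have %d",
                 length(filtered_trial), ns))
  }
  cand <- if (is.null(candidates)) 0:(set$n_targets - 1L) else {
    stopifnot(all(candidates >= 0), all(candidates < set$n_targets))
    sort(as.integer(candidates))
  }
  diffs <- set$templates[cand + 1L, , drop = FALSE] -
    rep(filtered_trial, each = length(cand))
  d <- sqrt(rowSums(diffs^2))
  names(d) <- cand
  list(target = cand[which.min(d)], distances = d)
}

#' Classify by correlation against plain-average templates
#'
#' The baseline classifier (and the one used inside best-channel
#' selection): Pearson correlation between the trial and every circular
#' shift of an averaged template; the highest correlation wins.  Invariant
#' to affine scaling of the trial.
#'
#' @param trial_signal Numeric vector (single channel or filtered signal).
#' @param avg_template Numeric vector: plain across-trial average in the
#'   target-0 frame.
#' @param layout A [target_layout()].
#' @param samples_per_bit EEG samples per stimulus bit.
#' @return List with `target` and `correlations` (named over all targets).
#' @export
classify_correlation <- function(trial_signal, avg_template,
                                 layout = target_layout(),
                                 samples_per_bit = 10) {
  stopifnot(length(trial_signal) == length(avg_template))
  if (stats::sd(trial_signal) == 0 || stats::sd(avg_template) == 0) {
    stop("zero-variance input to correlation classifier")
  }
  shifts <- layout$table$shift_bits * samples_per_bit
  r <- vapply(shifts, function(s)
    stats::cor(trial_signal, rotate_delay(avg_template, s)), numeric(1))
  names(r) <- layout$table$target
  list(target = layout$table$target[which.max(r)], correlations = r)
}
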