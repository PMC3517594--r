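#' Performance evaluation: accuracy, Wolpaw ITR, letters per minute
#'
#' Copy-spelling performance is classification accuracy plus the Wolpaw
#' information transfer rate, which converts accuracy over N classes into
#' bits per selection.  Free-spelling performance is application-centred:
#' error-free letters written per minute, with every mistake corrected via
#' a backspace selection (so each error costs two extra trials — the wrong
#' letter and its deletion).
#'
#' @name evaluation
NULL

#' Classification accuracy of a session log
#'
#' For copy-spelling and calibration logs (true labels present) this is the
#' fraction of trials classified correctly.  For free-spelling logs it is
#' `(trials - errors) / trials`, where an error is a trial whose selection
#' was wrong.
#'
#' @param log A session log tibble with columns `predicted` and either
#'   `true_target` or a logical `error` column.
#' @return A fraction in `[0, 1]`.
#' @export
session_accuracy <- function(log) {
  stopifnot(is.data.frame(log), nrow(log) > 0)
  if ("true_target" %in% names(log) && any(!is.na(log$true_target))) {
    keep <- !is.na(log$true_target)
    return(mean(log$predicted[keep] == log$true_target[keep]))
  }
  if ("error" %in% names(log)) {
    return((nrow(log) - sum(log$error)) / nrow(log))
  }
  stop("log carries neither true labels nor error accounting")
}

#' Wolpaw information transfer rate
#'
#' Bits per selection
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))`
#' (with the `0 * log(0)` limits taken as 0), scaled to bits per minute by
#' the selection period.  At or below chance accuracy (`P <= 1/N`) the ITR
#' is reported as 0 — the convention used when printing below-chance runs.
#'
#' @param n_classes Number of selectable classes N (>= 2).
#' @param accuracy Classification accuracy P in `[0, 1]`; vectorized.
#' @param trial_duration_s Seconds per selection (> 0).
#' @return ITR in bits per minute.
#' @export
wolpaw_itr <- function(n_classes, accuracy, trial_duration_s) {
  if (any(n_classes < 2) || any(n_classes != round(n_classes))) {
    stop("n_classes must be an integer >= 2")
  }
  if (any(accuracy < 0) || any(accuracy > 1)) {
    stop("accuracy must lie in [0, 1]")
  }
  if (any(trial_duration_s <= 0)) stop("trial_duration_s must be positive")
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(n_classes) + xlx(accuracy) +
    ifelse(accuracy < 1,
           (1 - accuracy) * log2((1 - accuracy) / (n_classes - 1)), 0)
  bits <- ifelse(accuracy <= 1 / n_classes, 0, bits)
  bits * 60 / trial_duration_s
}

#' Free-spelling summary from explicit counts
#'
#' @param written Error-free letters in the final transcript.
#' @param deleted Number of backspace selections.
#' @param trials Total number of trials.
#' @param time_s Total time of all trials in seconds.
#' @param errors Number of wrongly classified trials; defaults to `deleted`
#'   (every error corrected exactly once, backspaces always correct).
#' @return A one-row tibble: `written`, `deleted`, `trials`, `time_s`,
#'   `letters_per_min`, `accuracy` (fraction).
#' @export
free_spelling_row <- function(written, deleted, trials, time_s,
                              errors = deleted) {
  if (time_s <= 0) stop("time_s must be positive")
  tibble::tibble(
    written = written, deleted = deleted, trials = trials, time_s = time_s,
    letters_per_min = written / (time_s / 60),
    accuracy = (trials - errors) / trials)
}

#' Free-spelling summary from a session log
#'
#' Expects one row per trial with a logical `error` column (the selection
#' differed from the intent), a logical `is_backspace` column (the
#' selection was the delete character), and per-trial `duration_s`.  Each
#' backspace selection removes one previously appended character, so the
#' transcript length — the error-free letters written — is the number of
#' non-backspace selections minus the number of backspace selections.
#'
#' @param log A free-spelling session log tibble.
#' @return As [free_spelling_row()].
#' @export
free_spelling_summary <- function(log) {
  stopifnot(all(c("error", "is_backspace", "duration_s") %in% names(log)))
  trials <- nrow(log)
  deleted <- sum(log$is_backspace)
  free_spelling_row(written = trials - 2L * deleted, deleted = deleted,
                    trials = trials, time_s = sum(log$duration_s),
                    errors = sum(log$error))
}

#' Aggregate per-session summaries into a table average row
#'
#' `column_mean` averages each metric across rows (how accuracy columns are
#' usually averaged); `pooled` recomputes rate metrics from summed counts
#' and times (how letters-per-minute totals are computed).
#'
#' @param summaries A tibble of per-session rows (numeric columns).
#' @param method `"column_mean"` or `"pooled"`.
#' @return A one-row tibble.
#' @export
aggregate_summaries <- function(summaries,
                                method = c("column_mean", "pooled")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  num <- vapply(summaries, is.numeric, logical(1))
  if (method == "column_mean") {
    return(tibble::as_tibble(lapply(summaries[num], mean)))
  }
  s <- summaries
  out <- tibble::as_tibble(lapply(s[num], sum))
  if (all(c("written", "time_s") %in% names(s))) {
    out$letters_per_min <- sum(s$written) / (sum(s$time_s) / 60)
  }
  if (all(c("trials", "deleted") %in% names(s))) {
    out$accuracy <- (sum(s$trials) - sum(s$deleted)) / sum(s$trials)
  }
  if (all(c("correct", "trials") %in% names(s))) {
    out$accuracy <- sum(s$correct) / sum(s$trials)
  }
  out
}

#' Format a fraction as a table percentage
#'
#' Percentages are printed with two decimals, rounding half away from zero.
#'
#' @param x Fraction(s) in `[0, 1]`.
#' @param digits Decimal places.
#' @return Numeric percentage(s).
#' @export
as_table_percent <- function(x, digits = 2) {
  round_half_up(100 * x, digits)
}
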