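#' Best-channel selection and CCA spatial filtering
#'
#' The decoding pipeline first estimates, by leave-one-out cross-validation
#' with a correlation classifier, the single channel on which the c-VEP is
#' classified best.  The average waveform of that channel then serves as the
#' reference signal for canonical correlation analysis: CCA finds the
#' channel weights whose linear combination correlates maximally with the
#' reference, and those weights are the spatial filter applied to every
#' trial before template matching.
#'
#' @name spatial
NULL

#' Align a trial to the target-0 frame
#'
#' A trial recorded while attending target `k` equals a target-0 trial
#' delayed by `k * bit_lag` bits; advancing it by the same amount puts all
#' trials in a common frame so they can be averaged.
#'
#' @param trial A [trial_eeg()].
#' @param label Target index under which to align (defaults to the trial's
#'   attended target).
#' @param layout A [target_layout()].
#' @return A [trial_eeg()] in the target-0 frame (attended_target set to 0).
#' @export
align_trial <- function(trial, label = trial$attended_target,
                        layout = target_layout()) {
  stopifnot(!is.na(label), label >= 0, label < layout$n_targets)
  spb <- as.integer(trial$fs / 60)
  shift <- layout$table$shift_bits[label + 1L] * spb
  out <- trial
  out$data <- rotate_rows(trial$data, -shift)
  out$attended_target <- 0L
  out
}

# Per-trial cache used by the LOO channel scorer: per-channel centered data
# and the circular autocorrelation of each channel at the target lags.
trial_loo_cache <- function(data, lags) {
  mu <- rowMeans(data)
  centered <- data - mu
  ns <- ncol(data)
  f <- stats::mvfft(t(centered))
  a <- Re(stats::mvfft(f * Conj(f), inverse = TRUE)) / ns
  # a[l + 1, c] = dot(x_c, advance(x_c, l)) = dot(x_c, delay(x_c, ns - l))
  idx <- ((ns - lags) %% ns) + 1L
  list(centered = centered, auto = t(a[idx, , drop = FALSE]))
}

# Core LOO accuracy computation shared by select_best_channel() and the
# adaptation retrain path.  `caches` is a list of trial_loo_cache() results
# for label-aligned trials; returns the per-channel LOO accuracy vector.
loo_channel_accuracies <- function(caches, lags) {
  n <- length(caches)
  stopifnot(n >= 2)
  nc <- nrow(caches[[1]]$centered)
  ns <- ncol(caches[[1]]$centered)
  nk <- length(lags)
  delay_idx <- outer(seq_len(ns), lags, function(i, s) ((i - 1 - s) %% ns) + 1L)
  acc <- numeric(nc)
  for (ch in seq_len(nc)) {
    tc <- vapply(caches, function(x) x$centered[ch, ], numeric(ns))  # ns x n
    auto <- vapply(caches, function(x) x$auto[ch, ], numeric(nk))    # nk x n
    g <- rowSums(tc)
    d <- matrix(g[delay_idx], nrow = ns)                             # ns x nk
    scores <- (crossprod(tc, d) - t(auto)) / (n - 1)                 # n x nk
    pred <- apply(scores, 1, which.max)
    acc[ch] <- mean(pred == 1L)
  }
  acc
}

#' Select the channel on which the c-VEP classifies best
#'
#' For every channel a leave-one-out cross-validation is run: each trial is
#' classified by correlating it against the circularly shifted averages of
#' the remaining trials, and the channel accuracy is the fraction of trials
#' whose best-correlating shift matches the true label.  Ties are broken by
#' the lowest channel index.
#'
#' @param trials List of label-aligned [trial_eeg()] objects (all in the
#'   target-0 frame; see [align_trial()]), at least two.
#' @param layout A [target_layout()].
#' @return A list with `channel` (index), `name`, `accuracy`, and
#'   `per_channel` (tibble of all channel accuracies).
#' @export
select_best_channel <- function(trials, layout = target_layout()) {
  if (length(trials) < 2) stop("need at least 2 labelled trials")
  spb <- as.integer(trials[[1]]$fs / 60)
  lags <- layout$table$shift_bits * spb
  caches <- lapply(trials, function(tr) trial_loo_cache(tr$data, lags))
  acc <- loo_channel_accuracies(caches, lags)
  best <- which.max(acc)
  list(channel = best,
       name = trials[[1]]$channel_names[best],
       accuracy = acc[best],
       per_channel = tibble::tibble(
         channel = seq_along(acc),
         name = trials[[1]]$channel_names,
         loo_accuracy = acc))
}

#' Build the CCA input matrices
#'
#' All label-aligned trials are concatenated horizontally into
#' `X` (channels x (Nt*Ns)); the reference `Y` is the across-trial average
#' waveform of the best channel, tiled `Nt` times (1 x (Nt*Ns)).
#'
#' @param trials List of label-aligned [trial_eeg()] objects.
#' @param best_channel Channel index from [select_best_channel()].
#' @return List with `X`, `Y`.
#' @export
build_cca_inputs <- function(trials, best_channel) {
  stopifnot(length(trials) >= 1)
  dims <- vapply(trials, function(t) dim(t$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all trials must have identical channel x sample shape")
  }
  x <- do.call(cbind, lapply(trials, function(t) t$data))
  ybar <- Reduce(`+`, lapply(trials, function(t) t$data[best_channel, ])) /
    length(trials)
  list(X = x, Y = matrix(rep(ybar, length(trials)), nrow = 1))
}

#' Compute the CCA spatial filter for a univariate reference
#'
#' With a single reference signal the canonical problem reduces to one
#' canonical pair: the weights are `Cxx^-1 Cxy` (ridge-stabilized), scaled
#' to unit norm with the sign fixed so the canonical correlation is
#' non-negative (Euclidean template matching downstream is sign-sensitive).
#'
#' @param X Channels x samples data matrix.
#' @param Y 1 x samples (or plain vector) reference signal.
#' @param best_channel,best_channel_accuracy Optional metadata carried on
#'   the filter.
#' @param channel_names Optional channel labels.
#' @param ridge Relative ridge added to the diagonal of `Cxx`.
#' @return An object of class `spatial_filter` with fields `weights`,
#'   `best_channel`, `best_channel_accuracy`, `canonical_correlation`.
#' @export
compute_cca_filter <- function(X, Y, best_channel = NA_integer_,
                               best_channel_accuracy = NA_real_,
                               channel_names = rownames(X),
                               ridge = 1e-8) {
  y <- as.numeric(Y)
  stopifnot(ncol(X) == length(y))
  if (stats::sd(y) == 0) stop("reference Y is constant")
  n <- length(y)
  xc <- X - rowMeans(X)
  yc <- y - mean(y)
  cxx <- tcrossprod(xc) / n
  cxy <- (xc %*% yc) / n
  cyy <- sum(yc^2) / n
  cca_from_cov(cxx, cxy, cyy, best_channel = best_channel,
               best_channel_accuracy = best_channel_accuracy,
               channel_names = channel_names, ridge = ridge)
}

# Solve the single-pair CCA from (co)variances; shared by
# compute_cca_filter() and the adaptation retrain path so both routes give
# identical numerics.
cca_from_cov <- function(cxx, cxy, cyy, best_channel = NA_integer_,
                         best_channel_accuracy = NA_real_,
                         channel_names = NULL, ridge = 1e-8) {
  cxy <- as.numeric(cxy)
  eps <- ridge * mean(diag(cxx))
  cxx_r <- cxx + diag(eps, nrow(cxx))
  if (rcond(cxx_r) < 1e-12) {
    warning("rank-deficient data; ridge regularization is doing real work")
    cxx_r <- cxx + diag(max(eps, 1e-6 * mean(diag(cxx))), nrow(cxx))
  }
  w <- solve(cxx_r, cxy)
  r <- sum(w * cxy) /
    sqrt(max(as.numeric(crossprod(w, cxx %*% w)), 1e-300) * cyy)
  if (r < 0) {
    w <- -w
    r <- -r
  }
  w <- w / sqrt(sum(w^2))
  if (!is.null(channel_names)) names(w) <- channel_names
  structure(
    list(weights = w, best_channel = best_channel,
         best_channel_accuracy = best_channel_accuracy,
         canonical_correlation = min(max(r, 0), 1)),
    class = "spatial_filter"
  )
}

#' @export
print.spatial_filter <- function(x, ...) {
  cat(sprintf("<spatial_filter> %d channels, canonical r = %.3f, best ch %s\n",
              length(x$weights), x$canonical_correlation,
              ifelse(is.na(x$best_channel), "?", x$best_channel)))
  invisible(x)
}

#' Apply a spatial filter to a trial
#'
#' @param filter A [compute_cca_filter()] result.
#' @param trial A [trial_eeg()] or a channels x samples matrix.
#' @return Numeric vector: the spatially filtered single-channel signal.
#' @export
apply_filter <- function(filter, trial) {
  data <- if (inherits(trial, "trial_eeg")) trial$data else trial
  stopifnot(nrow(data) == length(filter$weights))
  as.numeric(filter$weights %*% data)
}

#' Serialize a spatial filter to JSON (and back)
#' @param filter A `spatial_filter`.
#' @param path Optional file path.
#' @return JSON string.
#' @export
filter_to_json <- function(filter, path = NULL) {
  obj <- list(weights = unname(filter$weights),
              channel_names = names(filter$weights),
              best_channel = filter$best_channel,
              best_channel_accuracy = filter$best_channel_accuracy,
              canonical_correlation = filter$canonical_correlation)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname filter_to_json
#' @param json JSON string or file path from [filter_to_json()].
#' @export
filter_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  w <- obj$weights
  names(w) <- obj$channel_names
  structure(list(weights = w, best_channel = obj$best_channel,
                 best_channel_accuracy = obj$best_channel_accuracy,
                 canonical_correlation = obj$canonical_correlation),
            class = "spatial_filter")
}
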