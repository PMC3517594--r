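# Shared fixtures and independent oracles for the test suite.

test_layout <- function() target_layout()

# Small montage keeps the required decoding/ErrP electrodes and runs fast.
test_model <- function(noise_sd = 8, n_channels = 10, latency_s = 0.036,
                       mixing = NULL, kernel = NULL, amplitude = 4) {
  ch <- cvep_montage(n_channels)
  code <- generate_msequence()
  forward_model(code = code, channel_names = ch,
                kernel = kernel %||% default_cvep_kernel(code,
                                                         amplitude = amplitude),
                mixing = mixing %||% cvep_mixing(ch),
                latency_s = latency_s, noise_sd = noise_sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Aligned training trials cycling over targets.
make_aligned_trials <- function(model, n, seed = 1,
                                layout = test_layout()) {
  seeds <- cvep:::derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    align_trial(simulate_trial(model, (i - 1) %% layout$n_targets,
                               seed = seeds[i]),
                layout = layout)
  })
}

# Full calibration: best channel + CCA + OCSVM templates from aligned trials.
fit_pipeline <- function(trials, layout = test_layout(), nu = 0.5) {
  sel <- select_best_channel(trials, layout)
  cca <- build_cca_inputs(trials, sel$channel)
  filt <- compute_cca_filter(cca$X, cca$Y, sel$channel, sel$accuracy)
  feats <- t(vapply(trials, function(t) apply_filter(filt, t),
                    numeric(ncol(trials[[1]]$data))))
  list(filter = filt,
       templates = fit_template(feats, nu = nu, layout = layout),
       best = sel)
}

# Labelled feedback epochs for detector training/evaluation.
make_epochs <- function(n_error, n_correct, amplitude = 2, seed_base = 0,
                        n_channels = 10, noise_sd = 6) {
  ch <- cvep_montage(n_channels)
  c(lapply(seq_len(n_error), function(i)
      simulate_errp_epoch(TRUE, amplitude_scale = amplitude,
                          seed = seed_base + i, channel_names = ch,
                          noise_sd = noise_sd)),
    lapply(seq_len(n_correct), function(i)
      simulate_errp_epoch(FALSE, amplitude_scale = amplitude,
                          seed = seed_base + 10000 + i, channel_names = ch,
                          noise_sd = noise_sd)))
}

# --- Independent oracles -------------------------------------------------

# Euclidean projection onto {0 <= a_i <= cap, sum a = 1} by bisection.
proj_capped_simplex <- function(v, cap) {
  lo <- min(v) - cap - 1
  hi <- max(v)
  for (it in 1:200) {
    lam <- (lo + hi) / 2
    if (sum(pmin(pmax(v - lam, 0), cap)) > 1) lo <- lam else hi <- lam
  }
  pmin(pmax(v - (lo + hi) / 2, 0), cap)
}

# Projected-gradient solver for the linear one-class SVM dual:
# min 0.5 a' K a  s.t.  0 <= a_i <= 1/(nu n), sum a = 1.
# Returns the weighted mean w = sum a_i x_i (the template).
ocsvm_oracle <- function(X, nu, iters = 5000) {
  n <- nrow(X)
  cap <- 1 / (nu * n)
  K <- tcrossprod(X)
  L <- 2 * max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  a <- proj_capped_simplex(rep(1 / n, n), cap)
  for (i in seq_len(iters)) {
    a <- proj_capped_simplex(a - (K %*% a)[, 1] / L, cap)
  }
  as.numeric(crossprod(a, X))
}

# Coarse grid search over unit-norm 3-channel weight vectors.
cca_grid_oracle <- function(X, y, n_theta = 24, n_phi = 48) {
  best <- -1
  for (th in seq(0, pi, length.out = n_theta)) {
    for (ph in seq(0, 2 * pi, length.out = n_phi)) {
      w <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
      r <- suppressWarnings(stats::cor(as.numeric(w %*% X), y))
      if (!is.na(r)) best <- max(best, abs(r))
    }
  }
  best
}
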