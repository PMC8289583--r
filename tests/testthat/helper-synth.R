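# shared fixtures: small synthetic configurations and detection scoring

no_noise <- list(baseline_amp = 0, powerline_amp = 0, white_sd = 0)

quiet_config <- function(n_beats = 50, seed = 3, ...) {
  synth_config(n_beats = n_beats, seed = seed, noise = no_noise, ...)
}

# match detected to true R indices (one-to-one, within tol samples) and
# return precision/recall/F1
detection_score <- function(detected, true_r, tol = 5) {
  matched <- adabeat:::match_r_peaks(detected, true_r, tol)
  tp <- sum(!is.na(matched))
  fp <- length(detected) - tp
  fn <- length(true_r) - tp
  list(tp = tp, fp = fp, fn = fn, f1 = 2 * tp / (2 * tp + fp + fn))
}

# one balanced small config used by several classifier tests
balanced_config <- function(n_beats = 300, seed = 13) {
  synth_config(n_beats = n_beats, seed = seed,
               class_proportions = c(N = .2, S = .2, V = .2, F = .2, Q = .2))
}
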