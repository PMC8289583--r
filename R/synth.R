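# Synthetic two-lead ECG generator with known ground truth.
#
# Each beat is a sum of three Gaussian bumps (P, QRS, T). Gaussians give
# analytically known wave boundaries (center +/- 3 sigma), so the generator
# doubles as an exact oracle for detection, delineation, and the interval
# features, without a full dynamical ECG model.

#' Default per-class beat templates
#'
#' Morphology and rhythm parameters per AAMI class for the synthetic
#' generator. Waves are Gaussian bumps described by amplitude (mV), width
#' (seconds, the full extent, i.e. 6 sigma) and center offset from the R peak
#' (seconds; the QRS offset is 0 by definition). The class templates encode
#' the textbook contrasts: S beats are premature with an absent P wave, V
#' beats are wide, large, P-less complexes with a discordant T, F beats are
#' intermediate fusion morphology, and Q emulates wide low-slew paced beats.
#'
#' @return Named list (one entry per class) of template lists with fields
#'   `p`, `qrs`, `t` (each `c(amp, width, center)`), `rr_mean`, `rr_sd`
#'   (seconds), and `p_present`.
#' @export
default_beat_templates <- function() {
  tpl <- function(p, qrs, t, rr_mean, rr_sd, p_present) {
    list(p = p, qrs = qrs, t = t,
         rr_mean = rr_mean, rr_sd = rr_sd, p_present = p_present)
  }
  list(
    N = tpl(p = c(amp = 0.15, width = 0.09, center = -0.17),
            qrs = c(amp = 1.00, width = 0.08, center = 0),
            t = c(amp = 0.30, width = 0.16, center = 0.25),
            rr_mean = 0.80, rr_sd = 0.05, p_present = TRUE),
    S = tpl(p = c(amp = 0.15, width = 0.09, center = -0.17),
            qrs = c(amp = 0.95, width = 0.08, center = 0),
            t = c(amp = 0.28, width = 0.16, center = 0.24),
            rr_mean = 0.58, rr_sd = 0.05, p_present = FALSE),
    V = tpl(p = c(amp = 0.15, width = 0.09, center = -0.17),
            qrs = c(amp = 1.40, width = 0.14, center = 0),
            t = c(amp = -0.35, width = 0.18, center = 0.30),
            rr_mean = 0.75, rr_sd = 0.08, p_present = FALSE),
    F = tpl(p = c(amp = 0.08, width = 0.09, center = -0.17),
            qrs = c(amp = 1.20, width = 0.11, center = 0),
            t = c(amp = 0.15, width = 0.16, center = 0.27),
            rr_mean = 0.72, rr_sd = 0.06, p_present = TRUE),
    Q = tpl(p = c(amp = 0.15, width = 0.09, center = -0.17),
            qrs = c(amp = 0.80, width = 0.12, center = 0),
            t = c(amp = 0.20, width = 0.20, center = 0.30),
            rr_mean = 0.85, rr_sd = 0.07, p_present = FALSE)
  )
}

#' Class proportions of the MIT-BIH arrhythmia benchmark
#'
#' Relative beat frequencies of the five AAMI classes in the standard
#' MIT-BIH arrhythmia benchmark (N 90,595; S 2,781; V 7,235; F 802;
#' Q 8,041 beats). Used as the generator default so synthetic records carry
#' the same severe class imbalance as the real database.
#'
#' @return Named numeric vector over N, S, V, F, Q summing to 1.
#' @export
mitbih_class_proportions <- function() {
  counts <- c(N = 90595, S = 2781, V = 7235, F = 802, Q = 8041)
  counts / sum(counts)
}

#' Synthetic-record configuration
#'
#' @param n_beats Number of beats to generate.
#' @param sampling_rate Sampling rate in Hz (default 360, the MIT-BIH rate).
#' @param class_proportions Named simplex over N, S, V, F, Q; defaults to the
#'   MIT-BIH benchmark proportions.
#' @param noise List with `baseline_amp`/`baseline_freq` (mV, Hz; sinusoidal
#'   baseline wander), `powerline_amp`/`powerline_freq` (mV, Hz) and
#'   `white_sd` (mV). Set amplitudes to 0 for a noiseless record.
#' @param lead_b Per-wave amplitude scale/sign applied to lead B, emulating
#'   the II-vs-V1 morphology contrast; named numeric with `p`, `qrs`, `t`.
#' @param amp_jitter,width_jitter Relative SD of per-beat multiplicative
#'   jitter on wave amplitudes and widths.
#' @param rr_min Lower truncation of the RR distribution in seconds (avoids
#'   overlapping beats).
#' @param seed Integer seed; the whole record is a deterministic function of
#'   the configuration including the seed.
#' @return List of class `"synth_config"`.
#' @export
synth_config <- function(n_beats = 500,
                         sampling_rate = 360,
                         class_proportions = mitbih_class_proportions(),
                         noise = list(baseline_amp = 0.10, baseline_freq = 0.25,
                                      powerline_amp = 0.02, powerline_freq = 50,
                                      white_sd = 0.02),
                         lead_b = c(p = 0.5, qrs = -0.4, t = 0.6),
                         amp_jitter = 0.05,
                         width_jitter = 0.03,
                         rr_min = 0.3,
                         seed = 1L) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop("class_proportions must sum to 1")
  }
  if (!all(names(class_proportions) %in% aami_classes())) {
    stop("class_proportions must be named with AAMI classes")
  }
  structure(
    list(n_beats = as.integer(n_beats), sampling_rate = sampling_rate,
         class_proportions = class_proportions, noise = noise,
         lead_b = lead_b, amp_jitter = amp_jitter,
         width_jitter = width_jitter, rr_min = rr_min,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# truncated-normal RR draw (resample below the floor)
draw_rr <- function(n, mean, sd, rr_min) {
  rr <- rnorm(n, mean, sd)
  while (any(bad <- rr < rr_min)) rr[bad] <- rnorm(sum(bad), mean, sd)
  rr
}

#' Generate a labeled synthetic two-lead ECG record
#'
#' Builds a record of concatenated Gaussian-bump beats with per-class
#' morphology and rhythm, additive baseline wander, powerline interference
#' and white noise, and returns the exact ground truth (R sample, wave
#' onsets/offsets at the 3-sigma points, class label) for every beat.
#' Identical configuration (including seed) gives bit-identical output.
#'
#' @param config A [synth_config()].
#' @param templates Named list of beat templates per class; every class with
#'   nonzero proportion must have a template.
#' @return List with `record` (an `ecg_record`: `record_id`, `sampling_rate`,
#'   `signal` tibble with columns `sample`, `time`, `lead_a`, `lead_b`, and
#'   an `annotations` tibble of `(sample, symbol)`), and `truth` (tibble with
#'   one row per beat: `beat`, `r_sample`, `p_on`, `p_off`, `qrs_on`,
#'   `qrs_off`, `t_on`, `t_off`, `label`; absent P waves carry NA bounds).
#' @export
#' @examples
#' rec <- synth_ecg(synth_config(n_beats = 20, seed = 42))
#' rec$truth
synth_ecg <- function(config = synth_config(),
                      templates = default_beat_templates()) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$sampling_rate
  probs <- config$class_proportions[config$class_proportions > 0]
  missing_tpl <- setdiff(names(probs), names(templates))
  if (length(missing_tpl) > 0) {
    stop("no beat template for sampled class(es): ",
         paste(missing_tpl, collapse = ", "))
  }
  set.seed(config$seed)

  labels <- sample(names(probs), config$n_beats, replace = TRUE, prob = probs)
  rr <- numeric(config$n_beats)
  for (k in seq_len(config$n_beats)) {
    tp <- templates[[labels[k]]]
    rr[k] <- draw_rr(1, tp$rr_mean, tp$rr_sd, config$rr_min)
  }
  # beat k sits rr[k] after beat k-1; first beat 0.5 s into the record
  r_time <- 0.5 + cumsum(c(0, rr[-1]))
  r_sample <- as.integer(round(r_time * fs))
  r_time <- r_sample / fs  # snap centers onto the sample grid
  n_samples <- max(r_sample) + as.integer(round(0.6 * fs))

  lead_a <- numeric(n_samples)
  lead_b <- numeric(n_samples)
  fid_mat <- matrix(NA_integer_, nrow = config$n_beats, ncol = 6,
                    dimnames = list(NULL, c("p_on", "p_off", "qrs_on",
                                            "qrs_off", "t_on", "t_off")))

  for (k in seq_len(config$n_beats)) {
    tp <- templates[[labels[k]]]
    for (w in c("p", "qrs", "t")) {
      if (w == "p" && !tp$p_present) next
      pars <- tp[[w]]
      amp <- pars[["amp"]] * (1 + rnorm(1, 0, config$amp_jitter))
      width <- pars[["width"]] * (1 + rnorm(1, 0, config$width_jitter))
      sigma <- width / 6
      center <- r_time[k] + pars[["center"]]
      span <- 5 * sigma
      # vector position i holds 0-based sample i - 1 (time (i - 1) / fs)
      i0 <- max(1L, as.integer(floor((center - span) * fs)) + 1L)
      i1 <- min(n_samples, as.integer(ceiling((center + span) * fs)) + 1L)
      if (i0 > i1) next
      tt <- ((i0:i1) - 1L) / fs
      bump <- amp * exp(-((tt - center)^2) / (2 * sigma^2))
      lead_a[i0:i1] <- lead_a[i0:i1] + bump
      lead_b[i0:i1] <- lead_b[i0:i1] + config$lead_b[[w]] * bump
      on <- as.integer(round((center - 3 * sigma) * fs))
      off <- as.integer(round((center + 3 * sigma) * fs))
      fid_mat[k, paste0(w, "_on")] <- on
      fid_mat[k, paste0(w, "_off")] <- off
    }
  }
  truth <- tibble::as_tibble(as.data.frame(fid_mat))
  truth <- dplyr::mutate(truth,
                         beat = seq_len(config$n_beats),
                         r_sample = r_sample, label = labels,
                         .before = 1)
  truth <- dplyr::relocate(truth, "label", .after = "t_off")
  truth <- dplyr::relocate(truth, "r_sample", .after = "beat")

  nz <- config$noise
  tt <- seq_len(n_samples) / fs
  noise_common <- numeric(n_samples)
  if (!is.null(nz$baseline_amp) && nz$baseline_amp > 0) {
    phase <- runif(1, 0, 2 * pi)
    noise_common <- noise_common +
      nz$baseline_amp * sin(2 * pi * nz$baseline_freq * tt + phase)
  }
  if (!is.null(nz$powerline_amp) && nz$powerline_amp > 0) {
    phase <- runif(1, 0, 2 * pi)
    noise_common <- noise_common +
      nz$powerline_amp * sin(2 * pi * nz$powerline_freq * tt + phase)
  }
  lead_a <- lead_a + noise_common
  lead_b <- lead_b + noise_common
  if (!is.null(nz$white_sd) && nz$white_sd > 0) {
    lead_a <- lead_a + rnorm(n_samples, 0, nz$white_sd)
    lead_b <- lead_b + rnorm(n_samples, 0, nz$white_sd)
  }

  record <- ecg_record(
    record_id = sprintf("synth%06d", config$seed),
    sampling_rate = fs,
    signal = tibble::tibble(
      sample = seq_len(n_samples) - 1L, time = (seq_len(n_samples) - 1L) / fs,
      lead_a = lead_a, lead_b = lead_b
    ),
    annotations = tibble::tibble(
      sample = truth$r_sample, symbol = aami_to_symbol(truth$label)
    )
  )
  list(record = record, truth = truth)
}

#' Interval features from generator ground truth
#'
#' Computes the seven interval features (P, QRS and T wave intervals, PR
#' segment, ST-T interval, QT interval, RR interval, all in seconds) directly
#' from the true wave boundaries, bypassing detection. This is the oracle the
#' detected-fiducial features are compared against. Beats whose morphology
#' window (`pre` samples before R to `post` after) would cross the record
#' bounds are excluded, mirroring beat segmentation. The RR interval of the
#' final beat repeats the previous RR value; intervals involving an absent
#' wave get the per-record median of that interval (flagged in the
#' `imputed` attribute).
#'
#' @param truth Ground-truth tibble from [synth_ecg()].
#' @param sampling_rate Sampling rate in Hz.
#' @param n_samples Record length in samples (for the boundary exclusion);
#'   `Inf` disables the exclusion.
#' @param pre,post Morphology window extent in samples.
#' @return Tibble with columns `beat`, `label`, `p_wave`, `qrs_wave`,
#'   `t_wave`, `pr_segment`, `stt_interval`, `qt_interval`, `rr_interval`.
#' @export
ground_truth_features <- function(truth, sampling_rate,
                                  n_samples = Inf, pre = 90, post = 144) {
  if (nrow(truth) == 0) stop("ground truth is empty")
  keep <- truth$r_sample - pre >= 0 & truth$r_sample + post <= n_samples - 1
  tr <- truth[keep, ]
  fs <- sampling_rate
  rr_samp <- c(diff(tr$r_sample), NA_integer_)
  if (length(rr_samp) > 1) rr_samp[length(rr_samp)] <- rr_samp[length(rr_samp) - 1]
  out <- tibble::tibble(
    beat = tr$beat, label = tr$label,
    p_wave = (tr$p_off - tr$p_on) / fs,
    qrs_wave = (tr$qrs_off - tr$qrs_on) / fs,
    t_wave = (tr$t_off - tr$t_on) / fs,
    pr_segment = (tr$qrs_on - tr$p_off) / fs,
    stt_interval = (tr$t_off - tr$qrs_off) / fs,
    qt_interval = (tr$t_off - tr$qrs_on) / fs,
    rr_interval = rr_samp / fs
  )
  impute_intervals(out)
}

# replace NA interval entries by the column median (the rectangularity
# sentinel); record what was imputed in an attribute
impute_intervals <- function(df) {
  cols <- setdiff(names(df), c("beat", "label"))
  imputed <- list()
  for (cl in cols) {
    na <- is.na(df[[cl]])
    if (any(na)) {
      med <- median(df[[cl]], na.rm = TRUE)
      df[[cl]][na] <- med
      imputed[[cl]] <- which(na)
    }
  }
  attr(df, "imputed") <- imputed
  df
}
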