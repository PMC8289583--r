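# Wavelet-based ECG preprocessing: denoising, R-peak detection, and
# P/QRS/T delineation.

#' Estimate the baseline-wander component of an ECG
#'
#' Two-stage running median: a 200 ms window (suppresses P waves and QRS
#' complexes) followed by a 600 ms window (suppresses T waves). What remains
#' tracks sub-Hz drift while staying flat across the beats themselves.
#'
#' @param x Numeric signal in mV.
#' @param sampling_rate Sampling rate in Hz.
#' @return Baseline estimate, same length as `x`.
#' @export
baseline_wander <- function(x, sampling_rate) {
  odd_k <- function(sec) {
    k <- round(sec * sampling_rate)
    k <- min(k, length(x) - (1 - length(x) %% 2))
    max(1L, as.integer(k + (1 - k %% 2)))
  }
  if (length(x) < 3) return(rep(median(x), length(x)))
  b <- stats::runmed(x, odd_k(0.2), endrule = "median")
  stats::runmed(b, odd_k(0.6), endrule = "median")
}

#' Denoise an ECG signal
#'
#' Removes baseline wander by subtracting the two-stage running-median
#' baseline estimate ([baseline_wander()]), then suppresses high-frequency
#' noise by soft-thresholding the two finest detail bands of a db6 wavelet
#' decomposition. The baseline is only subtracted when it is material (its
#' RMS exceeds 5% of the signal RMS), so records that are already flat pass
#' through unchanged.
#'
#' The high-frequency thresholding targets (at 360 Hz) everything above
#' roughly 45 Hz, covering white noise and 50/60 Hz powerline pickup, using
#' the universal threshold `sigma * sqrt(2 log n)` with the noise scale
#' `sigma` estimated from the finest details via MAD/0.6745. The band
#' carrying the P-QRS-T morphology passes through untouched, so the
#' operation is idempotent up to the re-estimated (near-zero) threshold.
#'
#' @param x Numeric signal in mV, or an `ecg_record` (all leads denoised).
#' @param sampling_rate Sampling rate in Hz (ignored for records).
#' @return Same-length signal, or the record with denoised leads.
#' @export
denoise_ecg <- function(x, sampling_rate = 360) {
  if (inherits(x, "ecg_record")) {
    for (lead in lead_names(x)) {
      x$signal[[lead]] <- denoise_ecg(x$signal[[lead]], x$sampling_rate)
    }
    return(x)
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (length(x) < 4 || all(x == 0)) return(x)
  b <- baseline_wander(x, sampling_rate)
  if (sqrt(mean(b^2)) > 0.05 * sqrt(mean(x^2))) x <- x - b
  dec <- wave_dec(x, 2)
  d1 <- dec$d[[2]]                            # finest details
  sigma <- median(abs(d1)) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  soft <- function(w) sign(w) * pmax(abs(w) - thr, 0)
  dec$d[[2]] <- soft(dec$d[[2]])
  dec$d[[1]] <- soft(dec$d[[1]])
  wave_rec(dec)
}

#' Detect R peaks with a Mexican-hat CWT
#'
#' Computes the continuous wavelet transform at scales matched to the QRS
#' band (default 12–30 Hz equivalent), takes the maximum absolute coefficient
#' across scales as the detection function, thresholds it at `k` times its
#' median absolute value, and keeps local maxima separated by a refractory
#' period. A candidate within 360 ms of a preceding candidate with less than
#' half its detection amplitude is rejected as a T wave (the classic
#' Pan–Tompkins T-rejection rule). Each survivor is then refined to the
#' local extremum of the signal itself within a 50 ms neighborhood. Ties
#' among candidates closer than the refractory period are broken toward the
#' larger detection amplitude, then the earlier index.
#'
#' @param x Numeric signal (ideally denoised), or an `ecg_record` (lead A,
#'   i.e. the first lead, is used).
#' @param sampling_rate Sampling rate in Hz (ignored for records).
#' @param freq_range QRS band in Hz targeted by the CWT scales.
#' @param k Threshold multiplier on the median absolute detection value.
#' @param refractory Minimum R-to-R spacing in seconds (default 0.2).
#' @return Sorted integer vector of 0-based R sample indices (empty for a
#'   flat signal).
#' @export
detect_r_peaks <- function(x, sampling_rate = 360,
                           freq_range = c(12, 30), k = 4,
                           refractory = 0.2) {
  if (inherits(x, "ecg_record")) {
    sampling_rate <- x$sampling_rate
    x <- x$signal[[lead_names(x)[1]]]
  }
  n <- length(x)
  if (n < 8 || all(x == x[1])) return(integer(0))
  # Mexican-hat center frequency ~ 0.25 cycles/sample at scale 1
  scales <- 0.25 * sampling_rate / seq(freq_range[2], freq_range[1], length.out = 4)
  cw <- ecg_cwt(x, scales)
  det <- apply(abs(cw), 2, max)
  thr <- k * median(abs(det))
  if (thr <= 0) return(integer(0))
  above <- det > thr
  is_peak <- above &
    det >= c(-Inf, det[-n]) & det > c(det[-1], -Inf)
  cand <- which(is_peak)
  if (length(cand) == 0) return(integer(0))
  # greedy refractory suppression, strongest first, earlier index on ties
  ord <- order(-det[cand], cand)
  min_gap <- round(refractory * sampling_rate)
  kept <- integer(0)
  for (i in cand[ord]) {
    if (all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  # T-wave rejection: a peak shortly after a much stronger one is a T wave
  t_window <- round(0.36 * sampling_rate)
  if (length(kept) > 1) {
    reject <- logical(length(kept))
    for (j in 2:length(kept)) {
      prev <- kept[seq_len(j - 1)]
      near <- prev[kept[j] - prev < t_window & !reject[seq_len(j - 1)]]
      if (length(near) > 0 && det[kept[j]] < 0.5 * max(det[near])) {
        reject[j] <- TRUE
      }
    }
    kept <- kept[!reject]
  }
  # refine to the signal's own extremum nearby
  half <- as.integer(round(0.05 * sampling_rate))
  refined <- vapply(kept, function(i) {
    lo <- max(1L, as.integer(i) - half)
    hi <- min(n, as.integer(i) + half)
    win <- abs(x[lo:hi])
    lo + which.max(win) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # refinement can pull neighbors together; re-apply the refractory rule,
  # strongest signal amplitude first, earlier index on ties
  if (length(refined) > 1) {
    ord2 <- order(-abs(x[refined]), refined)
    kept2 <- integer(0)
    for (i in refined[ord2]) {
      if (all(abs(kept2 - i) >= min_gap)) kept2 <- c(kept2, i)
    }
    refined <- sort(kept2)
  }
  as.integer(refined - 1L)   # 0-based
}

# locate onset/offset of a Gaussian-like wave: walk away from the peak until
# |signal - baseline| falls below frac of the peak excursion
wave_bounds <- function(x, peak, lo, hi, baseline, frac = 0.015) {
  amp <- abs(x[peak] - baseline)
  if (amp == 0) return(c(NA_integer_, NA_integer_))
  thr <- frac * amp
  on <- peak
  while (on > lo && abs(x[on - 1] - baseline) >= thr) on <- on - 1
  off <- peak
  while (off < hi && abs(x[off + 1] - baseline) >= thr) off <- off + 1
  c(on, off)
}

#' Delineate one beat: P/QRS/T boundaries around an R peak
#'
#' Finds QRS onset/offset by walking from the R peak to where the excursion
#' from the local baseline decays, then searches physiologic windows for the
#' P wave (200 to 40 ms before QRS onset) and T wave (80 to 400 ms after QRS
#' offset). A wave whose peak excursion is below `min_wave_amp` is flagged
#' undetected (NA bounds) rather than fabricated. When the neighboring beats
#' are known, `prev_bound`/`next_bound` confine the search windows so the
#' previous beat's T wave is not mistaken for a P wave (and vice versa) at
#' short coupling intervals.
#'
#' @param x Numeric denoised signal, or an `ecg_record` (first lead used).
#' @param r_index 0-based R-peak sample index.
#' @param sampling_rate Sampling rate in Hz (ignored for records).
#' @param min_wave_amp Minimum P/T peak excursion in mV (default 0.04).
#' @param prev_bound 0-based sample before which the P search may not start
#'   (e.g. the previous beat's T offset); `NA` for no constraint.
#' @param next_bound 0-based sample beyond which the T search may not extend
#'   (e.g. 80 ms before the next R peak); `NA` for no constraint.
#' @return One-row tibble: `r_peak`, `p_on`, `p_off`, `qrs_on`, `qrs_off`,
#'   `t_on`, `t_off` (0-based, NA for undetected waves) and `p_detected`,
#'   `t_detected` flags.
#' @export
delineate <- function(x, r_index, sampling_rate = 360, min_wave_amp = 0.04,
                      prev_bound = NA, next_bound = NA) {
  if (inherits(x, "ecg_record")) {
    sampling_rate <- x$sampling_rate
    x <- x$signal[[lead_names(x)[1]]]
  }
  n <- length(x)
  r1 <- as.integer(r_index) + 1L           # 1-based
  if (r1 < 1 || r1 > n) stop("r_index out of bounds")
  fs <- sampling_rate
  ms <- function(t) as.integer(round(t * fs))

  qrs_half <- ms(0.12)
  baseline_qrs <- 0
  qb <- wave_bounds(x, r1, max(1L, r1 - qrs_half), min(n, r1 + qrs_half),
                    baseline_qrs)
  qrs_on <- qb[1]; qrs_off <- qb[2]

  # the signal is denoised with the sub-0.7 Hz bands removed, so the
  # isoelectric level is 0; wave search measures excursions from it
  find_wave <- function(lo, hi) {
    lo <- max(1L, lo); hi <- min(n, hi)
    if (hi - lo < 3) return(c(NA_integer_, NA_integer_, NA_integer_))
    seg <- x[lo:hi]
    peak <- lo + which.max(abs(seg)) - 1L
    if (abs(x[peak]) < min_wave_amp) {
      return(c(NA_integer_, NA_integer_, NA_integer_))
    }
    b <- wave_bounds(x, peak, lo, hi, 0)
    c(peak, b)
  }

  p_lo <- qrs_on - ms(0.200)
  if (!is.na(prev_bound)) p_lo <- max(p_lo, as.integer(prev_bound) + 2L)
  t_hi <- qrs_off + ms(0.400)
  if (!is.na(next_bound)) t_hi <- min(t_hi, as.integer(next_bound))
  p <- find_wave(p_lo, qrs_on - ms(0.040))
  t <- find_wave(qrs_off + ms(0.080), t_hi)

  to0 <- function(i) if (is.na(i)) NA_integer_ else as.integer(i - 1L)
  tibble::tibble(
    r_peak = as.integer(r_index),
    p_on = to0(p[2]), p_off = to0(p[3]),
    qrs_on = to0(qrs_on), qrs_off = to0(qrs_off),
    t_on = to0(t[2]), t_off = to0(t[3]),
    p_detected = !is.na(p[1]), t_detected = !is.na(t[1])
  )
}

#' Delineate every beat of a record
#'
#' Applies [delineate()] to each detected R peak, confining each beat's
#' P search to start after the previous beat's T offset and its T search to
#' end 80 ms before the next R peak, and enforces the fiducial ordering
#' invariant `p_on < p_off <= qrs_on < qrs_off <= t_on < t_off` by clipping
#' P offsets / T onsets that spill into the QRS complex.
#'
#' @param x Numeric denoised signal or `ecg_record`.
#' @param r_indices 0-based R sample indices (e.g. from [detect_r_peaks()]).
#' @param sampling_rate Sampling rate in Hz (ignored for records).
#' @param ... Passed to [delineate()].
#' @return Tibble with one row per beat (columns as in [delineate()]).
#' @export
delineate_beats <- function(x, r_indices, sampling_rate = 360, ...) {
  if (inherits(x, "ecg_record")) {
    sampling_rate <- x$sampling_rate
    x <- x$signal[[lead_names(x)[1]]]
  }
  n_beat <- length(r_indices)
  rows <- vector("list", n_beat)
  prev_bound <- NA
  for (i in seq_len(n_beat)) {
    next_bound <- if (i < n_beat) {
      r_indices[i + 1] - round(0.08 * sampling_rate)
    } else {
      NA
    }
    row <- delineate(x, r_indices[i], sampling_rate, ...,
                     prev_bound = prev_bound, next_bound = next_bound)
    prev_bound <- if (isTRUE(row$t_detected)) row$t_off else row$qrs_off
    rows[[i]] <- row
  }
  fid <- dplyr::bind_rows(rows)
  # ordering invariant: clip boundary spill-over into the QRS
  fid <- dplyr::mutate(
    fid,
    p_off = dplyr::if_else(!is.na(.data$p_off) & .data$p_off > .data$qrs_on,
                           .data$qrs_on, .data$p_off),
    t_on = dplyr::if_else(!is.na(.data$t_on) & .data$t_on < .data$qrs_off,
                          .data$qrs_off, .data$t_on),
    p_detected = .data$p_detected & !is.na(.data$p_on) & !is.na(.data$p_off) &
      .data$p_on < .data$p_off,
    t_detected = .data$t_detected & !is.na(.data$t_on) & !is.na(.data$t_off) &
      .data$t_on < .data$t_off
  )
  fid$p_on[!fid$p_detected] <- NA_integer_
  fid$p_off[!fid$p_detected] <- NA_integer_
  fid$t_on[!fid$t_detected] <- NA_integer_
  fid$t_off[!fid$t_detected] <- NA_integer_
  fid
}
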