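# Attributable feature sets:
#   A — 235 single-lead morphology samples (90 before R, 144 after, the R
#       sample itself included)
#   B — 470 dual-lead morphology samples (lead A window then lead B window)
#   C — 7 interval features in seconds
#   D — QRS area in mV*s
#   E — db6 wavelet coefficients of the lead-A window

#' Morphology features of one beat
#'
#' Set A is the lead-A window verbatim (235 samples with the defaults);
#' set B appends the lead-B window (470 values).
#'
#' @param lead_a_window Numeric window around the R peak.
#' @param lead_b_window Lead-B window (required when `dual_lead = TRUE`).
#' @param dual_lead Return the dual-lead vector (set B) instead of set A.
#' @return Numeric vector of length 235 (single) or 470 (dual).
#' @export
morphology_features <- function(lead_a_window, lead_b_window = NULL,
                                dual_lead = FALSE) {
  if (!dual_lead) return(as.numeric(lead_a_window))
  if (is.null(lead_b_window)) stop("dual_lead = TRUE requires lead_b_window")
  c(as.numeric(lead_a_window), as.numeric(lead_b_window))
}

#' Interval features of one beat
#'
#' The seven standard interval features, each a sample-index difference
#' divided by the sampling rate: P wave interval `(p_off - p_on)/SR`,
#' QRS interval `(qrs_off - qrs_on)/SR`, T wave interval `(t_off - t_on)/SR`,
#' PR segment `(qrs_on - p_off)/SR`, ST-T interval `(t_off - qrs_off)/SR`,
#' QT interval `(t_off - qrs_on)/SR`, and RR interval
#' `(next_r - r_peak)/SR`. Intervals whose fiducials are undetected come
#' back `NA`; [extract_features()] imputes them with the per-record median.
#'
#' @param fid One-row fiducial tibble (as from [delineate()]) or a list with
#'   the fiducial fields.
#' @param next_r 0-based R index of the following beat (`NA` for the last
#'   beat; the caller supplies the sentinel).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @return Named numeric vector of the 7 intervals in seconds.
#' @export
#' @examples
#' interval_features(
#'   list(r_peak = 180, p_on = 100, p_off = 136, qrs_on = 166,
#'        qrs_off = 194, t_on = 230, t_off = 310),
#'   next_r = 468, sampling_rate = 360
#' )
interval_features <- function(fid, next_r, sampling_rate) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  g <- function(f) {
    v <- fid[[f]]
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  }
  r <- g("r_peak")
  if (!is.na(next_r) && !is.na(r) && next_r <= r) {
    stop("next_r must exceed the current r_peak")
  }
  c(p_wave = (g("p_off") - g("p_on")) / sampling_rate,
    qrs_wave = (g("qrs_off") - g("qrs_on")) / sampling_rate,
    t_wave = (g("t_off") - g("t_on")) / sampling_rate,
    pr_segment = (g("qrs_on") - g("p_off")) / sampling_rate,
    stt_interval = (g("t_off") - g("qrs_off")) / sampling_rate,
    qt_interval = (g("t_off") - g("qrs_on")) / sampling_rate,
    rr_interval = (as.numeric(next_r) - r) / sampling_rate)
}

#' QRS area of one beat
#'
#' Trapezoidal integral of `|signal - baseline|` over the closed interval
#' `[qrs_on, qrs_off]`, in mV*s. The baseline is the mean of the PR segment
#' (`[p_off, qrs_on)`) when a P wave is present, otherwise the mean of the
#' 20 samples preceding QRS onset; subtracting it makes the area invariant
#' to constant offsets.
#'
#' @param x Numeric signal in mV.
#' @param fid Fiducials (list or one-row tibble) with `qrs_on`, `qrs_off`
#'   and optionally `p_off`, all 0-based.
#' @param sampling_rate Sampling rate in Hz.
#' @return Non-negative area in mV*s.
#' @export
qrs_area <- function(x, fid, sampling_rate) {
  on <- fid[["qrs_on"]]
  off <- fid[["qrs_off"]]
  if (is.na(on) || is.na(off) || off - on < 2) {
    stop("degenerate QRS window: need qrs_off - qrs_on >= 2 samples")
  }
  if (on < 0 || off > length(x) - 1) stop("QRS window outside the signal")
  p_off <- fid[["p_off"]]
  base_lo <- if (!is.null(p_off) && length(p_off) == 1 && !is.na(p_off)) {
    p_off
  } else {
    max(0, on - 20)
  }
  baseline <- if (base_lo < on) mean(x[(base_lo:(on - 1)) + 1]) else 0
  seg <- abs(x[(on:off) + 1] - baseline)
  h <- 1 / sampling_rate
  sum((seg[-1] + seg[-length(seg)]) / 2) * h
}

#' Wavelet-coefficient features of one beat window
#'
#' Multilevel db6 decomposition of the (zero-padded) beat window; the
#' concatenated approximation and detail blocks form set E. With the default
#' 235-sample window and level 4 the vector has 240 entries (the window is
#' padded to 240, the next multiple of 2^4). The transform is orthogonal, so
#' coefficient energy equals window energy.
#'
#' @param window Numeric beat window.
#' @param level Decomposition depth (default 4; 235 samples cannot support
#'   very deep decompositions).
#' @return Numeric coefficient vector of fixed length for fixed
#'   `(level, window length)`.
#' @export
wavelet_features <- function(window, level = 4) {
  if (2^level > length(window)) stop("level too deep for this window length")
  wave_coefs(wave_dec(as.numeric(window), level))
}

feature_set_columns <- function(sets, n_a = 235, n_e = 240,
                                interval_names = c("p_wave", "qrs_wave",
                                                   "t_wave", "pr_segment",
                                                   "stt_interval",
                                                   "qt_interval",
                                                   "rr_interval")) {
  cols <- character(0)
  if ("A" %in% sets) cols <- c(cols, sprintf("A_%03d", seq_len(n_a)))
  if ("B" %in% sets) cols <- c(cols, sprintf("B_%03d", seq_len(2 * n_a)))
  if ("C" %in% sets) cols <- c(cols, paste0("C_", interval_names))
  if ("D" %in% sets) cols <- c(cols, "D_qrs_area")
  if ("E" %in% sets) cols <- c(cols, sprintf("E_%03d", seq_len(n_e)))
  cols
}

parse_sets <- function(sets) {
  if (length(sets) == 1 && nchar(sets) > 1) {
    sets <- strsplit(sets, "")[[1]]
  }
  sets <- toupper(sets)
  bad <- setdiff(sets, c("A", "B", "C", "D", "E"))
  if (length(bad) > 0 || length(sets) == 0) {
    stop("active sets must be a nonempty subset of A, B, C, D, E")
  }
  intersect(c("A", "B", "C", "D", "E"), unique(sets))  # canonical order
}

#' Assemble a feature matrix from segmented beats and fiducials
#'
#' Computes the requested feature sets per beat and binds them, columns in
#' canonical A, B, C, D, E order. Interval features use the detected
#' fiducials plus the next detected R peak; the RR interval of the last beat
#' repeats the previous one, and intervals of undetected waves are imputed
#' with the per-call column median (beats and columns recorded in the
#' `imputed` attribute).
#'
#' @param beats Tibble from [segment_beats()] (needs `lead_a`, and `lead_b`
#'   for set B).
#' @param fiducials Tibble from [delineate_beats()], one row per beat in
#'   `beats` (same order). Only needed for sets C and D.
#' @param sets Active sets as a character vector or compact string, e.g.
#'   `"BCDE"`.
#' @param sampling_rate Sampling rate in Hz.
#' @param signal Full lead-A signal (needed for set D, the QRS area).
#' @param wavelet_level Decomposition depth for set E.
#' @return Tibble with a `label` column and one column per feature; active
#'   sets stored in the `active_sets` attribute.
#' @export
extract_features <- function(beats, fiducials = NULL, sets = "BCDE",
                             sampling_rate = 360, signal = NULL,
                             wavelet_level = 4) {
  sets <- parse_sets(sets)
  n <- nrow(beats)
  if (n == 0) stop("no beats to extract features from")
  needs_fid <- any(c("C", "D") %in% sets)
  if (needs_fid && (is.null(fiducials) || nrow(fiducials) != n)) {
    stop("sets C/D require one fiducial row per beat")
  }
  if ("B" %in% sets && !"lead_b" %in% names(beats)) {
    stop("set B requires a lead_b window column")
  }
  blocks <- list()

  if ("A" %in% sets) {
    m <- do.call(rbind, beats$lead_a)
    colnames(m) <- sprintf("A_%03d", seq_len(ncol(m)))
    blocks$A <- m
  }
  if ("B" %in% sets) {
    m <- cbind(do.call(rbind, beats$lead_a), do.call(rbind, beats$lead_b))
    colnames(m) <- sprintf("B_%03d", seq_len(ncol(m)))
    blocks$B <- m
  }
  if ("C" %in% sets) {
    next_r <- c(beats$r_sample[-1], NA_real_)
    m <- t(vapply(seq_len(n), function(i) {
      interval_features(fiducials[i, ], next_r[i], sampling_rate)
    }, numeric(7)))
    # last beat: repeat the previous RR
    if (n > 1 && is.na(m[n, "rr_interval"])) {
      m[n, "rr_interval"] <- m[n - 1, "rr_interval"]
    }
    colnames(m) <- paste0("C_", colnames(m))
    blocks$C <- m
  }
  if ("D" %in% sets) {
    if (is.null(signal)) stop("set D requires the full lead-A signal")
    area <- vapply(seq_len(n), function(i) {
      qrs_area(signal, fiducials[i, ], sampling_rate)
    }, numeric(1))
    blocks$D <- matrix(area, ncol = 1, dimnames = list(NULL, "D_qrs_area"))
  }
  if ("E" %in% sets) {
    m <- t(vapply(beats$lead_a, wavelet_features,
                  numeric(length(wavelet_features(beats$lead_a[[1]],
                                                  wavelet_level))),
                  level = wavelet_level))
    colnames(m) <- sprintf("E_%03d", seq_len(ncol(m)))
    blocks$E <- m
  }

  out <- tibble::as_tibble(as.data.frame(do.call(cbind, blocks[sets])))
  out <- impute_intervals(dplyr::mutate(out, beat = beats$beat,
                                        label = beats$label))
  out <- dplyr::relocate(out, "beat", "label")
  attr(out, "active_sets") <- sets
  out
}
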