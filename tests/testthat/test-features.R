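test_that("morphology feature lengths and construction identities hold", {
  a <- rnorm(235)
  b <- rnorm(235)
  expect_length(morphology_features(a), 235)
  expect_length(morphology_features(a, b, dual_lead = TRUE), 470)
  expect_equal(morphology_features(numeric(235)), numeric(235))
  expect_equal(morphology_features(a, b, dual_lead = TRUE)[1:235],
               morphology_features(a))
  expect_error(morphology_features(a, dual_lead = TRUE), "lead_b")
})

test_that("interval features compute each defining ratio exactly", {
  fid <- list(r_peak = 180, p_on = 100, p_off = 136, qrs_on = 200,
              qrs_off = 236, t_on = 300, t_off = 344)
  v <- interval_features(fid, next_r = 468, sampling_rate = 360)
  expect_equal(unname(v["p_wave"]), 0.1)                 # 36 samples
  expect_equal(unname(v["qrs_wave"]), 0.1)
  expect_equal(unname(v["qt_interval"]), (344 - 200) / 360)  # 0.4 s
  expect_equal(unname(v["stt_interval"]), (344 - 236) / 360) # 0.3 s
  expect_equal(unname(v["pr_segment"]), (200 - 136) / 360)
  expect_equal(unname(v["t_wave"]), (344 - 300) / 360)
  expect_equal(unname(v["rr_interval"]), (468 - 180) / 360)
  expect_error(interval_features(fid, next_r = 100, sampling_rate = 360),
               "exceed")
  expect_error(interval_features(fid, 468, sampling_rate = 0), "positive")
  # undetected waves give NA, not fabricated numbers
  fid$p_on <- NA_integer_
  v2 <- interval_features(fid, 468, 360)
  expect_true(is.na(v2["p_wave"]))
  expect_false(is.na(v2["qrs_wave"]))
})

test_that("detected-fiducial intervals match the generator oracle exactly", {
  gen <- synth_ecg(quiet_config(n_beats = 30, seed = 7))
  tr <- gen$truth
  n_samp <- nrow(gen$record$signal)
  oracle <- ground_truth_features(tr, 360, n_samples = n_samp)
  # feed the true fiducials through the feature path: equality must be exact
  beats <- segment_beats(gen$record, tr$r_sample, tr$label)
  fid <- tr[tr$beat %in% beats$beat, ]
  names(fid)[names(fid) == "r_sample"] <- "r_peak"
  feats <- extract_features(beats, fid, sets = "C", sampling_rate = 360)
  expect_equal(feats$C_p_wave, oracle$p_wave)
  expect_equal(feats$C_qrs_wave, oracle$qrs_wave)
  expect_equal(feats$C_t_wave, oracle$t_wave)
  expect_equal(feats$C_pr_segment, oracle$pr_segment)
  expect_equal(feats$C_stt_interval, oracle$stt_interval)
  expect_equal(feats$C_qt_interval, oracle$qt_interval)
  expect_equal(feats$C_rr_interval, oracle$rr_interval)
})

test_that("QRS area integrates a rectangular pulse and is offset-invariant", {
  fs <- 360
  x <- numeric(500)
  x[101:137] <- 1                      # 1 mV across samples 100..136 (0-based)
  fid <- list(qrs_on = 100L, qrs_off = 136L, p_off = 60L)
  a <- qrs_area(x, fid, fs)
  expect_equal(a, 0.1, tolerance = 0.1 / 36)   # 36/360 s, end-correction slack
  expect_equal(qrs_area(2 * x, fid, fs), 2 * a)          # linearity
  expect_equal(qrs_area(x + 0.5, fid, fs), a)            # offset invariance
  expect_equal(qrs_area(numeric(500), fid, fs), 0)
  expect_error(qrs_area(x, list(qrs_on = 10L, qrs_off = 11L), fs),
               "degenerate")
})

test_that("wavelet features are orthogonal, deterministic, and sparse on DC", {
  w <- rnorm(235)
  v1 <- wavelet_features(w)
  v2 <- wavelet_features(w)
  expect_identical(v1, v2)
  expect_length(v1, 240)               # zero-padded to the next dyadic grid
  expect_equal(sum(v1^2), sum(w^2), tolerance = 1e-6)    # Parseval
  const <- rep(1.5, 256)               # dyadic length: no padding edge
  dec <- wave_dec(const, 4)
  expect_lt(max(abs(unlist(dec$d))), 1e-8)   # details vanish on constants
  expect_gt(sum(dec$a^2), 0.99 * sum(const^2))
  expect_error(wavelet_features(rnorm(8), level = 4), "too deep")
})

test_that("assembled matrices have the right columns for all 16 combinations", {
  gen <- synth_ecg(quiet_config(n_beats = 25, seed = 13))
  beats <- segment_beats(gen$record, gen$truth$r_sample, gen$truth$label)
  x <- gen$record$signal$lead_a
  fid <- delineate_beats(x, beats$r_sample, 360)
  lens <- c(A = 235, B = 470, C = 7, D = 1, E = 240)
  combos <- c("A", "B", "C", "D", "E", "BC", "BD", "BE", "CD", "CE", "DE",
              "BCD", "BCE", "BDE", "CDE", "BCDE")
  for (combo in combos) {
    ft <- extract_features(beats, fid, sets = combo, sampling_rate = 360,
                           signal = x)
    sets <- strsplit(combo, "")[[1]]
    expect_equal(ncol(ft) - 2, sum(lens[sets]), info = combo)
    expect_equal(nrow(ft), nrow(beats), info = combo)
  }
  # sets A and B agree on their shared lead-A block
  fa <- extract_features(beats, fid, sets = "A", sampling_rate = 360)
  fb <- extract_features(beats, fid, sets = "B", sampling_rate = 360)
  expect_equal(unname(as.matrix(fa[, sprintf("A_%03d", 1:235)])),
               unname(as.matrix(fb[, sprintf("B_%03d", 1:235)])))
  expect_error(extract_features(beats, fid, sets = ""), "nonempty")
  expect_error(extract_features(beats, fid, sets = "XY"), "subset")
})

test_that("undetected-wave intervals are imputed with the record median", {
  gen <- synth_ecg(quiet_config(n_beats = 40, seed = 15))
  beats <- segment_beats(gen$record, gen$truth$r_sample, gen$truth$label)
  x <- gen$record$signal$lead_a
  fid <- delineate_beats(x, beats$r_sample, 360)
  ft <- extract_features(beats, fid, sets = "C", sampling_rate = 360)
  expect_false(anyNA(ft))
  imputed <- attr(ft, "imputed")
  expect_true(length(imputed$C_p_wave) > 0)   # S/V/Q beats lack P waves
  med <- median(ft$C_p_wave[-imputed$C_p_wave])
  expect_true(all(ft$C_p_wave[imputed$C_p_wave] == med))
})
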