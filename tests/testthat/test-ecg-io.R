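test_that("WFDB triplet round-trips samples and annotations", {
  gen <- synth_ecg(synth_config(n_beats = 25, seed = 9))
  rec <- gen$record
  dir <- withr::local_tempdir()
  write_wfdb(rec, dir, gain = 200)
  back <- read_wfdb(file.path(dir, rec$record_id))
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(nrow(back$signal), nrow(rec$signal))
  # format 212 quantizes at 1/(2*gain) mV
  expect_lt(max(abs(back$signal$lead_a - rec$signal$lead_a)), 1 / 400 + 1e-12)
  expect_lt(max(abs(back$signal$lead_b - rec$signal$lead_b)), 1 / 400 + 1e-12)
  ord <- order(rec$annotations$sample)
  expect_identical(back$annotations$sample,
                   as.integer(rec$annotations$sample[ord]))
  expect_identical(back$annotations$symbol, rec$annotations$symbol[ord])
})

test_that("annotation codec handles long gaps and clipping extremes", {
  sig <- tibble::tibble(sample = 0:99999, time = (0:99999) / 360,
                        lead_a = numeric(100000))
  sig$lead_a[c(1, 2)] <- c(50, -50)  # far outside the 12-bit range
  rec <- ecg_record("gap01", 360, sig,
                    tibble::tibble(sample = c(10L, 90000L),  # gap > 1023
                                   symbol = c("N", "V")))
  dir <- withr::local_tempdir()
  write_wfdb(rec, dir)
  back <- read_wfdb(file.path(dir, "gap01"))
  expect_identical(back$annotations$sample, c(10L, 90000L))
  expect_identical(back$annotations$symbol, c("N", "V"))
  expect_equal(back$signal$lead_a[1], 2047 / 200)   # clipped, not wrapped
  expect_equal(back$signal$lead_a[2], -2048 / 200)
})

test_that("reader reports malformed or missing files", {
  dir <- withr::local_tempdir()
  expect_error(read_wfdb(file.path(dir, "absent")), "header not found")
  writeLines("rec01 1 360 100", file.path(dir, "rec01.hea"))
  expect_error(read_wfdb(file.path(dir, "rec01")), "malformed|not found")
  writeLines(c("rec02 1 360 100", "rec02.dat 16 200 12 0 0 0 0 lead_a"),
             file.path(dir, "rec02.hea"))
  writeBin(raw(300), file.path(dir, "rec02.dat"))
  expect_error(read_wfdb(file.path(dir, "rec02")), "format")
})

test_that("AAMI mapping follows EC57 and excludes non-beat symbols", {
  expect_equal(map_to_aami(c("N", "L", "R", "e", "j")), rep("N", 5))
  expect_equal(map_to_aami(c("A", "a", "J", "S")), rep("S", 4))
  expect_equal(map_to_aami(c("V", "E")), rep("V", 2))
  expect_equal(map_to_aami("F"), "F")
  expect_equal(map_to_aami(c("/", "f", "Q")), rep("Q", 3))
  expect_true(all(is.na(map_to_aami(c("+", "~", "|", "?", "x")))))
})

test_that("beat windows are closed intervals with the boundary drop rule", {
  sig <- tibble::tibble(sample = 0:234, time = (0:234) / 360,
                        lead_a = as.numeric(0:234))
  rec <- ecg_record("seg01", 360, sig)
  b <- segment_beats(rec, r_indices = 90L, labels = "N")
  expect_equal(nrow(b), 1)
  expect_length(b$lead_a[[1]], 235)
  expect_equal(b$lead_a[[1]], as.numeric(0:234))  # verbatim samples
  expect_equal(nrow(segment_beats(rec, 50L, "N")), 0)      # window underflow
  # r at end - 144 kept; end - 143 dropped
  expect_equal(nrow(segment_beats(rec, 234L - 144L, "N")), 1)
  expect_equal(nrow(segment_beats(rec, 234L - 143L, "N")), 0)
  expect_error(segment_beats(rec, c(100L, 90L), c("N", "N")), "sorted")
})

test_that("dual-lead windows concatenate to the 470-sample morphology vector", {
  gen <- synth_ecg(synth_config(n_beats = 10, seed = 21))
  beats <- segment_beats(gen$record, gen$truth$r_sample, gen$truth$label)
  expect_true(all(lengths(beats$lead_a) == 235))
  expect_true(all(lengths(beats$lead_b) == 235))
  v <- morphology_features(beats$lead_a[[1]], beats$lead_b[[1]],
                           dual_lead = TRUE)
  expect_length(v, 470)
  expect_equal(v[1:235], beats$lead_a[[1]])
})

test_that("train/test split is a disjoint exhaustive stratified partition", {
  gen <- synth_ecg(synth_config(n_beats = 400, seed = 23, noise = no_noise))
  spl <- suppressWarnings(split_train_test(gen$truth, train_frac = 0.9,
                                           seed = 2))
  expect_equal(nrow(spl$train) + nrow(spl$test), 400)
  expect_length(intersect(spl$train$beat, spl$test$beat), 0)
  # classes with at least 2 beats: test counts within 1 of 10% of class size
  for (cl in unique(gen$truth$label)) {
    n_cl <- sum(gen$truth$label == cl)
    if (n_cl < 2) next
    n_te <- sum(spl$test$label == cl)
    expect_lte(abs(n_te - round(0.1 * n_cl)), 1)
    expect_gte(n_te, 1)
  }
  spl2 <- suppressWarnings(split_train_test(gen$truth, train_frac = 0.9,
                                            seed = 2))
  expect_identical(spl$test_idx, spl2$test_idx)
  expect_error(split_train_test(gen$truth, train_frac = 1.2), "in \\(0, 1\\)")
  # singleton class stays in training, with a warning
  df <- tibble::tibble(beat = 1:11, label = c(rep("N", 10), "F"))
  expect_warning(s3 <- split_train_test(df, 0.9, seed = 1), "fewer than 2")
  expect_false("F" %in% s3$test$label)
})
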