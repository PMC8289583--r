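# ECG record container, WFDB (format 212) reading/writing, AAMI symbol
# mapping, beat segmentation and train/test splitting.

#' Construct an ECG record
#'
#' Lightweight container for a sampled multi-lead ECG plus beat annotations.
#'
#' @param record_id Record identifier string.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param signal Tibble with columns `sample` (0-based), `time` (s) and one
#'   column per lead (mV); leads must have equal length by construction.
#' @param annotations Tibble with columns `sample` (0-based index into the
#'   signal) and `symbol` (annotation character).
#' @return Object of class `"ecg_record"`.
#' @export
ecg_record <- function(record_id, sampling_rate, signal,
                       annotations = tibble::tibble(sample = integer(),
                                                    symbol = character())) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (nrow(annotations) > 0 &&
      (min(annotations$sample) < 0 ||
       max(annotations$sample) >= nrow(signal))) {
    stop("annotation sample indices out of record bounds")
  }
  structure(list(record_id = record_id, sampling_rate = sampling_rate,
                 signal = signal, annotations = annotations),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  leads <- setdiff(names(x$signal), c("sample", "time"))
  cat(sprintf("<ecg_record %s: %d samples @ %g Hz, leads: %s, %d annotations>\n",
              x$record_id, nrow(x$signal), x$sampling_rate,
              paste(leads, collapse = ", "), nrow(x$annotations)))
  invisible(x)
}

lead_names <- function(record) setdiff(names(record$signal), c("sample", "time"))

# ---- AAMI mapping ---------------------------------------------------------

# MIT annotation code <-> symbol table (beat and common non-beat codes)
MIT_ANN_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L, "~" = 14L,
  "|" = 16L, "x" = 19L, "[" = 24L, "]" = 25L, "!" = 26L, "+" = 28L,
  "\"" = 30L, "e" = 34L, "n" = 35L, "f" = 38L
)

#' Map MIT-BIH annotation symbols to AAMI classes
#'
#' Deterministic mapping per the ANSI/AAMI EC57 convention:
#' `N,L,R,e,j -> N`; `A,a,J,S -> S`; `V,E -> V`; `F -> F`; `/,f,Q -> Q`.
#' Non-beat symbols (rhythm changes, noise markers, unknown symbols) map to
#' `NA` and should be excluded from beat-level processing.
#'
#' @param symbol Character vector of annotation symbols.
#' @return Character vector of AAMI classes, `NA` where excluded.
#' @export
#' @examples
#' map_to_aami(c("V", "L", "+", "A"))
map_to_aami <- function(symbol) {
  lut <- c(N = "N", L = "N", R = "N", e = "N", j = "N",
           A = "S", a = "S", J = "S", S = "S",
           V = "V", E = "V",
           F = "F",
           "/" = "Q", f = "Q", Q = "Q")
  unname(lut[symbol])
}

# symbols the generator writes into .atr files, one representative per class
aami_to_symbol <- function(class) {
  lut <- c(N = "N", S = "A", V = "V", F = "F", Q = "Q")
  unname(lut[class])
}

# ---- WFDB writer ----------------------------------------------------------

# pack a 2 x n matrix of 12-bit two's-complement integers into format 212
pack_212 <- function(dig) {
  flat <- as.integer(dig)              # s(1,1), s(2,1), s(1,2), ...
  if (length(flat) %% 2 == 1) flat <- c(flat, 0L)
  u <- flat %% 4096L                   # two's complement in 12 bits
  s1 <- u[seq(1, length(u), by = 2)]
  s2 <- u[seq(2, length(u), by = 2)]
  b1 <- s1 %% 256L
  b2 <- (s2 %/% 256L) * 16L + s1 %/% 256L
  b3 <- s2 %% 256L
  as.raw(as.vector(rbind(b1, b2, b3)))
}

unpack_212 <- function(bytes, n_values) {
  b <- as.integer(bytes)
  n_tri <- length(b) %/% 3
  b1 <- b[seq(1, 3 * n_tri, by = 3)]
  b2 <- b[seq(2, 3 * n_tri, by = 3)]
  b3 <- b[seq(3, 3 * n_tri, by = 3)]
  s1 <- (b2 %% 16L) * 256L + b1
  s2 <- (b2 %/% 16L) * 256L + b3
  u <- as.vector(rbind(s1, s2))[seq_len(n_values)]
  ifelse(u >= 2048L, u - 4096L, u)
}

# encode annotation stream as MIT .atr words (code<<10 | interval), with
# SKIP(59) + 4-byte extension for intervals that overflow 10 bits
encode_atr <- function(samples, symbols) {
  codes <- MIT_ANN_CODES[symbols]
  if (any(is.na(codes))) {
    stop("cannot encode annotation symbol(s): ",
         paste(unique(symbols[is.na(codes)]), collapse = ", "))
  }
  out <- integer(0)
  prev <- 0L
  for (i in seq_along(samples)) {
    dt <- samples[i] - prev
    prev <- samples[i]
    if (dt > 1023L) {
      # SKIP word (code 59, interval 0) followed by the 32-bit interval,
      # high 16-bit word first, each word little-endian
      out <- c(out, 59L * 1024L, dt %/% 65536L, dt %% 65536L)
      dt <- 0L
    }
    out <- c(out, codes[i] * 1024L + dt)
  }
  out <- c(out, 0L)                         # EOF word
  lo <- out %% 256L
  hi <- out %/% 256L
  as.raw(as.vector(rbind(lo, hi)))
}

decode_atr <- function(bytes) {
  b <- as.integer(bytes)
  n_words <- length(b) %/% 2
  samples <- integer(0)
  symbols <- character(0)
  sym_by_code <- setNames(names(MIT_ANN_CODES), MIT_ANN_CODES)
  t_cur <- 0L
  pending_skip <- 0L
  i <- 1L
  while (i <= n_words) {
    word <- b[2 * i - 1] + 256L * b[2 * i]
    code <- word %/% 1024L
    interval <- word %% 1024L
    if (word == 0L) break
    if (code == 59L && interval == 0L) {
      # next two words carry a 32-bit interval (high word first)
      w1 <- b[2 * i + 1] + 256L * b[2 * i + 2]
      w2 <- b[2 * i + 3] + 256L * b[2 * i + 4]
      pending_skip <- w1 * 65536L + w2
      i <- i + 3L
      next
    }
    if (code %in% c(60L, 61L, 62L, 63L)) {          # NUM/SUB/CHN/AUX
      if (code == 63L) i <- i + as.integer(ceiling(interval / 2))
      i <- i + 1L
      next
    }
    t_cur <- t_cur + pending_skip + interval
    pending_skip <- 0L
    samples <- c(samples, t_cur)
    symbols <- c(symbols, sym_by_code[[as.character(code)]])
    i <- i + 1L
  }
  tibble::tibble(sample = samples, symbol = symbols)
}

#' Write an ECG record as a WFDB triplet
#'
#' Emits `<record_id>.hea`, `<record_id>.dat` (format 212, 12-bit samples at
#' the configured gain) and, when annotations are present, `<record_id>.atr`
#' (MIT annotation format). A sidecar ground-truth CSV can be written with
#' [readr::write_csv()] by the caller.
#'
#' @param record An `ecg_record` with one or two leads.
#' @param dir Output directory (created if missing).
#' @param gain ADC gain in adu/mV (default 200, the MIT-BIH convention).
#' @return Invisibly, the path to the header file.
#' @export
write_wfdb <- function(record, dir, gain = 200) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  leads <- lead_names(record)
  if (!length(leads) %in% c(1, 2)) stop("write_wfdb supports 1 or 2 leads")
  n <- nrow(record$signal)
  phys <- as.matrix(record$signal[, leads, drop = FALSE])
  dig <- round(phys * gain)
  dig[dig > 2047] <- 2047
  dig[dig < -2048] <- -2048
  dat_name <- paste0(record$record_id, ".dat")
  hea <- c(
    sprintf("%s %d %g %d", record$record_id, length(leads),
            record$sampling_rate, n),
    vapply(seq_along(leads), function(j) {
      sprintf("%s 212 %g 12 0 %d 0 0 %s", dat_name, gain,
              as.integer(dig[1, j]), leads[j])
    }, character(1))
  )
  writeLines(hea, file.path(dir, paste0(record$record_id, ".hea")))
  dig_pairs <- if (length(leads) == 2) t(dig) else rbind(as.integer(dig[, 1]), rep(0L, n))
  writeBin(pack_212(dig_pairs), file.path(dir, dat_name))
  if (nrow(record$annotations) > 0) {
    ann <- dplyr::arrange(record$annotations, .data$sample)
    writeBin(encode_atr(as.integer(ann$sample), ann$symbol),
             file.path(dir, paste0(record$record_id, ".atr")))
  }
  invisible(file.path(dir, paste0(record$record_id, ".hea")))
}

#' Read a WFDB record
#'
#' Parses a `.hea` header, decodes the format-212 `.dat` signal into physical
#' units (mV), and reads the `.atr` beat annotations when present.
#'
#' @param record_path Path to the record without extension (or to the `.hea`
#'   file).
#' @return An [ecg_record()].
#' @export
read_wfdb <- function(record_path) {
  record_path <- sub("\\.hea$", "", record_path)
  hea_path <- paste0(record_path, ".hea")
  if (!file.exists(hea_path)) stop("header not found: ", hea_path)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4) stop("malformed header line in ", hea_path)
  record_id <- top[1]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  sig_lines <- lines[1 + seq_len(n_sig)]
  parse_sig <- function(ln, idx) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 3) stop("malformed signal line ", idx, " in ", hea_path)
    fmt <- as.integer(sub("[^0-9].*$", "", f[2]))
    if (is.na(fmt) || fmt != 212) {
      stop("unsupported signal format '", f[2], "' in ", hea_path,
           " (signal line ", idx, "): only format 212 is supported")
    }
    gain <- suppressWarnings(as.numeric(sub("[(/].*$", "", f[3])))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", f[3])) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", f[3]))
    } else if (length(f) >= 5) as.numeric(f[5]) else 0
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = "_") else paste0("lead_", idx)
    list(file = f[1], gain = gain, baseline = baseline, desc = desc)
  }
  sigs <- lapply(seq_len(n_sig), function(i) parse_sig(sig_lines[i], i))
  dat_path <- file.path(dirname(hea_path), sigs[[1]]$file)
  if (!file.exists(dat_path)) stop("signal file not found: ", dat_path)
  n_values <- n * 2L  # format 212 always stores sample pairs
  bytes <- readBin(dat_path, what = "raw", n = ceiling(n_values / 2) * 3)
  u <- unpack_212(bytes, n_values)
  dig <- matrix(u, nrow = 2)
  sig_tbl <- tibble::tibble(sample = seq_len(n) - 1L, time = (seq_len(n) - 1L) / fs)
  for (j in seq_len(n_sig)) {
    sig_tbl[[make.names(tolower(sigs[[j]]$desc))]] <-
      (dig[j, ] - sigs[[j]]$baseline) / sigs[[j]]$gain
  }
  atr_path <- paste0(record_path, ".atr")
  ann <- if (file.exists(atr_path)) {
    decode_atr(readBin(atr_path, "raw", file.size(atr_path)))
  } else {
    tibble::tibble(sample = integer(), symbol = character())
  }
  ecg_record(record_id, fs, sig_tbl, ann)
}

# ---- segmentation and splitting -------------------------------------------

#' Segment a record into fixed-length labeled beats
#'
#' Extracts, for every R index, the closed window `[r - pre, r + post]`
#' (default 90 samples before and 144 after the R peak, 235 samples in all)
#' from each lead. Beats whose window crosses the record bounds are dropped.
#'
#' @param record An `ecg_record`.
#' @param r_indices Sorted 0-based R-peak sample indices.
#' @param labels AAMI class label per R index.
#' @param pre,post Samples before/after the R peak.
#' @return Tibble with `beat`, `r_sample`, `label` and one list-column of
#'   window samples per lead (`lead_a`, `lead_b`, ...).
#' @export
segment_beats <- function(record, r_indices, labels, pre = 90, post = 144) {
  stopifnot(length(r_indices) == length(labels))
  if (is.unsorted(r_indices)) stop("r_indices must be sorted ascending")
  n <- nrow(record$signal)
  keep <- r_indices - pre >= 0 & r_indices + post <= n - 1
  r_keep <- r_indices[keep]
  out <- tibble::tibble(
    beat = which(keep), r_sample = r_keep, label = labels[keep]
  )
  for (lead in lead_names(record)) {
    x <- record$signal[[lead]]
    out[[lead]] <- purrr::map(r_keep, function(r) x[(r - pre):(r + post) + 1L])
  }
  out
}

#' Stratified train/test split of beats
#'
#' Randomly partitions rows into disjoint, exhaustive train and test sets.
#' By default the split is stratified by class so every class is represented
#' in the test set at close to `1 - train_frac` of its size; classes with a
#' single beat go wholly to training (with a warning).
#'
#' @param beats Tibble with a class column.
#' @param train_frac Fraction assigned to training, in (0, 1); default 0.9.
#' @param seed Integer seed; identical seeds give identical partitions.
#' @param stratify Stratify by class (default TRUE).
#' @param class_col Name of the class column (default `"label"`).
#' @return List with tibbles `train` and `test` and the integer `test_idx`.
#' @export
split_train_test <- function(beats, train_frac = 0.9, seed = 1L,
                             stratify = TRUE, class_col = "label") {
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  n <- nrow(beats)
  set.seed(as.integer(seed))
  if (stratify) {
    test_idx <- integer(0)
    for (cl in unique(beats[[class_col]])) {
      idx <- which(beats[[class_col]] == cl)
      n_test <- round(length(idx) * (1 - train_frac))
      if (length(idx) < 2) {
        warning("class ", cl, " has fewer than 2 beats; kept in training")
        next
      }
      n_test <- max(1L, min(n_test, length(idx) - 1L))
      test_idx <- c(test_idx, sample(idx, n_test))
    }
    test_idx <- sort(test_idx)
  } else {
    test_idx <- sort(sample.int(n, round(n * (1 - train_frac))))
  }
  list(train = beats[setdiff(seq_len(n), test_idx), ],
       test = beats[test_idx, ],
       test_idx = test_idx)
}
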