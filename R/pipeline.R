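# End-to-end orchestration: generate or read a record, preprocess, extract
# the chosen feature sets, split, train, predict, and report — plus the
# feature-set-combination and tree-count sweeps.

#' Run the full heartbeat-classification pipeline
#'
#' Executes preprocess (denoise, R detection, delineation) -> feature
#' extraction -> stratified split -> AdaBoost + Random Forest training ->
#' prediction -> per-class metrics, on either a synthetic record or a WFDB
#' record on disk. A single seed drives the generator, the split, and the
#' forests, so a run is reproducible from its configuration alone. When an
#' output directory is given, the feature table (CSV), the JSON and text
#' reports, the confusion matrix (CSV) and a manifest (JSON) are written.
#'
#' For synthetic sources the class labels of detected beats are assigned by
#' matching each detected R peak to the nearest ground-truth beat within 50
#' ms (unmatched detections are dropped); for WFDB sources the annotated
#' beat positions and symbols are used directly.
#'
#' @param source A [synth_config()], an `ecg_record`, or a path to a WFDB
#'   record (without extension).
#' @param sets Active feature sets, e.g. `"BCDE"`.
#' @param train_frac Training fraction for the stratified split.
#' @param rounds,num_trees AdaBoost rounds and trees per forest.
#' @param seed Integer seed for split and training (and the generator, when
#'   `source` is a config whose seed is `NULL`).
#' @param use_annotations For WFDB/record sources with annotations: use the
#'   annotated R positions instead of running detection (default TRUE).
#' @param outdir Optional artifact directory.
#' @return List of class `"heartbeat_run"`: `metrics` (a `beat_metrics`),
#'   `model`, `features`, `split`, `r_detection` (detected/matched counts)
#'   and `manifest`.
#' @export
run_heartbeat_pipeline <- function(source = synth_config(), sets = "BCDE",
                                   train_frac = 0.9, rounds = 10,
                                   num_trees = 70, seed = 1L,
                                   use_annotations = TRUE, outdir = NULL) {
  sets <- parse_sets(sets)
  truth <- NULL
  if (inherits(source, "synth_config")) {
    gen <- synth_ecg(source)
    record <- gen$record
    truth <- gen$truth
  } else if (inherits(source, "ecg_record")) {
    record <- source
  } else if (is.character(source)) {
    record <- read_wfdb(source)
  } else {
    stop("source must be a synth_config, an ecg_record, or a WFDB path")
  }
  fs <- record$sampling_rate

  den <- denoise_ecg(record)
  lead_a <- den$signal[[lead_names(den)[1]]]

  if (!is.null(truth)) {
    r_det <- detect_r_peaks(lead_a, fs)
    matched <- match_r_peaks(r_det, truth$r_sample, tol = round(0.05 * fs))
    keep <- !is.na(matched)
    r_idx <- r_det[keep]
    labels <- truth$label[matched[keep]]
    r_detection <- list(n_detected = length(r_det),
                        n_matched = sum(keep),
                        n_true = nrow(truth))
  } else if (use_annotations && nrow(record$annotations) > 0) {
    aami <- map_to_aami(record$annotations$symbol)
    keep <- !is.na(aami)
    r_idx <- as.integer(record$annotations$sample[keep])
    labels <- aami[keep]
    ord <- order(r_idx)
    r_idx <- r_idx[ord]
    labels <- labels[ord]
    r_detection <- list(n_detected = length(r_idx),
                        n_matched = length(r_idx),
                        n_true = length(r_idx))
  } else {
    stop("unlabeled source: cannot train without annotations or ground truth")
  }

  beats <- segment_beats(den, r_idx, labels)
  fid <- delineate_beats(lead_a, beats$r_sample, fs)
  features <- extract_features(beats, fid, sets = sets, sampling_rate = fs,
                               signal = lead_a)

  spl <- split_train_test(features, train_frac = train_frac, seed = seed)
  feat_cols <- setdiff(names(features), c("beat", "label"))
  model <- fit_adaboost(spl$train[, feat_cols], spl$train$label,
                        rounds = rounds, num_trees = num_trees, seed = seed)
  pred <- predict(model, spl$test[, feat_cols])
  metrics <- beat_metrics(beat_confusion(spl$test$label, pred))

  manifest <- list(
    record_id = record$record_id, sampling_rate = fs,
    sets = paste(sets, collapse = ""), train_frac = train_frac,
    rounds = rounds, num_trees = num_trees, seed = as.integer(seed),
    n_beats = nrow(features), n_train = nrow(spl$train),
    n_test = nrow(spl$test),
    package_version = as.character(utils::packageVersion("adabeat"))
  )
  out <- structure(
    list(metrics = metrics, model = model, features = features, split = spl,
         r_detection = r_detection, manifest = manifest),
    class = "heartbeat_run"
  )
  if (!is.null(outdir)) write_run_artifacts(out, outdir)
  out
}

#' @export
print.heartbeat_run <- function(x, ...) {
  cat(sprintf("<heartbeat_run: sets %s, %d beats (%d train / %d test)>\n",
              x$manifest$sets, x$manifest$n_beats, x$manifest$n_train,
              x$manifest$n_test))
  print(x$metrics)
  invisible(x)
}

# nearest-true-beat matching with a one-to-one constraint
match_r_peaks <- function(detected, true_r, tol) {
  out <- rep(NA_integer_, length(detected))
  used <- logical(length(true_r))
  for (i in seq_along(detected)) {
    d <- abs(true_r - detected[i])
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= tol && !used[j]) {
      out[i] <- j
      used[j] <- TRUE
    }
  }
  out
}

write_run_artifacts <- function(run, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  readr::write_csv(run$features, file.path(outdir, "features.csv"))
  write_metrics_report(run$metrics, file.path(outdir, "report.json"))
  write_metrics_report(run$metrics, file.path(outdir, "report.txt"))
  utils::write.csv(unclass(run$metrics$confusion),
                   file.path(outdir, "confusion.csv"))
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

all_set_combinations <- function() {
  sets <- c("A", "B", "C", "D", "E")
  combos <- unlist(lapply(seq_along(sets), function(k) {
    utils::combn(sets, k, paste, collapse = "", simplify = FALSE)
  }))
  # the canonical 16-test grid: the five singletons plus every combination
  # of {B, C, D, E} of size >= 2
  keep <- vapply(combos, function(s) {
    nchar(s) == 1 || !grepl("A", s)
  }, logical(1))
  combos[keep]
}

#' Sweep feature-set combinations
#'
#' Trains and evaluates the ensemble once per feature-set combination on the
#' same record, split and seed. The default grid is the canonical 16-test
#' design: each single set A–E, then every pairwise, three-way and four-way
#' combination of B, C, D, E.
#'
#' @param source,train_frac,rounds,num_trees,seed As in
#'   [run_heartbeat_pipeline()].
#' @param combos Character vector of set combinations (e.g. `c("B","BCDE")`).
#' @return Tibble with `combination`, `n_features`, `accuracy` (percent).
#' @export
sweep_feature_sets <- function(source = synth_config(),
                               combos = all_set_combinations(),
                               train_frac = 0.9, rounds = 10,
                               num_trees = 70, seed = 1L) {
  prep <- prepare_features_once(source, sets = "ABCDE", seed = seed)
  purrr::map_dfr(combos, function(combo) {
    sets <- parse_sets(combo)
    cols <- unlist(lapply(sets, function(s) {
      grep(paste0("^", s, "_"), names(prep$features), value = TRUE)
    }))
    spl <- split_train_test(prep$features, train_frac = train_frac,
                            seed = seed)
    model <- fit_adaboost(spl$train[, cols], spl$train$label,
                          rounds = rounds, num_trees = num_trees,
                          seed = seed)
    pred <- predict(model, spl$test[, cols])
    acc <- beat_metrics(beat_confusion(spl$test$label, pred))$overall_accuracy
    tibble::tibble(combination = paste(sets, collapse = ""),
                   n_features = length(cols), accuracy = acc)
  })
}

#' Sweep the number of trees per forest
#'
#' Trains and evaluates once per `num_trees` value with a fixed split and
#' seed. The default grid (20–90 by 10) mirrors the published tuning sweep
#' whose optimum is 70.
#'
#' @param source,sets,train_frac,rounds,seed As in
#'   [run_heartbeat_pipeline()].
#' @param tree_counts Positive integer vector of forest sizes.
#' @return Tibble with `num_trees`, `accuracy` (percent).
#' @export
sweep_n_trees <- function(source = synth_config(), sets = "BCDE",
                          tree_counts = seq(20, 90, by = 10),
                          train_frac = 0.9, rounds = 10, seed = 1L) {
  if (any(tree_counts < 1)) stop("tree_counts must be positive")
  prep <- prepare_features_once(source, sets = sets, seed = seed)
  cols <- setdiff(names(prep$features), c("beat", "label"))
  spl <- split_train_test(prep$features, train_frac = train_frac, seed = seed)
  purrr::map_dfr(tree_counts, function(nt) {
    model <- fit_adaboost(spl$train[, cols], spl$train$label,
                          rounds = rounds, num_trees = nt, seed = seed)
    pred <- predict(model, spl$test[, cols])
    acc <- beat_metrics(beat_confusion(spl$test$label, pred))$overall_accuracy
    tibble::tibble(num_trees = nt, accuracy = acc)
  })
}

# shared front half of the pipeline (record -> labeled feature table)
prepare_features_once <- function(source, sets, seed) {
  truth <- NULL
  if (inherits(source, "synth_config")) {
    gen <- synth_ecg(source)
    record <- gen$record
    truth <- gen$truth
  } else if (inherits(source, "ecg_record")) {
    record <- source
  } else {
    record <- read_wfdb(source)
  }
  fs <- record$sampling_rate
  den <- denoise_ecg(record)
  lead_a <- den$signal[[lead_names(den)[1]]]
  if (!is.null(truth)) {
    r_det <- detect_r_peaks(lead_a, fs)
    matched <- match_r_peaks(r_det, truth$r_sample, tol = round(0.05 * fs))
    keep <- !is.na(matched)
    r_idx <- r_det[keep]
    labels <- truth$label[matched[keep]]
  } else {
    aami <- map_to_aami(record$annotations$symbol)
    keep <- !is.na(aami)
    r_idx <- as.integer(record$annotations$sample[keep])
    labels <- aami[keep]
  }
  beats <- segment_beats(den, r_idx, labels)
  fid <- delineate_beats(lead_a, beats$r_sample, fs)
  features <- extract_features(beats, fid, sets = sets, sampling_rate = fs,
                               signal = lead_a)
  list(record = record, features = features)
}
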