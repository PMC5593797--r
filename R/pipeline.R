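#' Assemble per-class training features from a corpus
#'
#' Reads each WAV + label pair, computes the 39-dimensional feature stack
#' and groups frames by their (collapsed) reference class: pooled frame
#' matrices for a GMM bank, per-utterance frame sequences for an HMM bank.
#'
#' @param corpus tibble with columns `wav` and `labels` (paths), e.g. from
#'   [make_training_corpus()].
#' @param kind `"gmm"` or `"hmm"`.
#' @param recipe `"fft-mfcc"` or `"emd-mfcc"`.
#' @param min_run minimum frames per utterance kept for HMM training
#'   (default 5).
#' @param ... passed to [cry_features()].
#' @return Named list over [CLASS_LABELS], ready for
#'   [train_classifier_bank()].
#' @export
collect_training_features <- function(corpus, kind = c("gmm", "hmm"),
                                      recipe = c("fft-mfcc", "emd-mfcc"),
                                      min_run = 5, ...) {
  kind <- match.arg(kind)
  recipe <- match.arg(recipe)
  dots <- list(...)
  frame_len_s <- dots$frame_len_s %||% 0.030
  overlap_s <- dots$overlap_s %||% 0.021
  acc <- stats::setNames(vector("list", length(CLASS_LABELS)), CLASS_LABELS)
  for (i in seq_len(nrow(corpus))) {
    rec <- to_mono(read_wav(corpus$wav[i]))
    X <- cry_features(rec, recipe = recipe, ...)
    track <- read_labels(corpus$labels[i])
    ref <- collapse_to_classes(track_to_frame_labels(
      track, nrow(X), frame_len_s,
      frame_len_s - overlap_s
    ))
    if (kind == "gmm") {
      for (cls in CLASS_LABELS) {
        acc[[cls]] <- rbind(acc[[cls]], X[ref == cls, , drop = FALSE])
      }
    } else {
      r <- rle(ref)
      ends <- cumsum(r$lengths)
      starts <- c(1L, head(ends, -1) + 1L)
      for (j in seq_along(starts)) {
        if (r$lengths[j] < min_run) next
        cls <- r$values[j]
        acc[[cls]] <- c(acc[[cls]],
                        list(X[starts[j]:ends[j], , drop = FALSE]))
      }
    }
  }
  empty <- names(acc)[vapply(acc, is.null, TRUE)]
  if (length(empty)) {
    abort(paste0("collect_training_features: no training data for: ",
                 paste(empty, collapse = ", ")))
  }
  acc
}

#' Initial classification of one recording
#'
#' Computes the bank's feature recipe on the recording and produces the
#' initial per-frame class labels and their segment track.
#'
#' @param rec an [audio_recording()] or path to a WAV file.
#' @param bank a trained `classifier_bank`.
#' @param frame_len_s,overlap_s analysis grid.
#' @param smooth_window,switch_penalty see [classify_frames()].
#' @param out optional path; when given the segment track is written there.
#' @param ... passed to [cry_features()].
#' @return List with `frame_labels`, `track` (a [label_track()]) and
#'   `n_frames`.
#' @export
run_segment <- function(rec, bank, frame_len_s = 0.030, overlap_s = 0.021,
                        smooth_window = 1, switch_penalty = 0,
                        out = NULL, ...) {
  if (is.character(rec)) rec <- read_wav(rec)
  rec <- to_mono(rec)
  X <- cry_features(rec, recipe = bank$recipe, frame_len_s = frame_len_s,
                    overlap_s = overlap_s, ...)
  frame_labels <- classify_frames(bank, X, smooth_window = smooth_window,
                                  switch_penalty = switch_penalty)
  track <- frame_labels_to_track(frame_labels, frame_len_s,
                                 frame_len_s - overlap_s,
                                 total_s = duration_s(rec))
  if (!is.null(out)) write_labels(track, out)
  list(frame_labels = frame_labels, track = track,
       n_frames = length(frame_labels))
}

#' Full segmentation: initial classification plus post-processing
#'
#' Runs [run_segment()] and then [refine()]s the labels and boundaries
#' with the dynamic-threshold stage. The thresholds used are reported via
#' `message()` for reproducibility.
#'
#' @inheritParams run_segment
#' @param verbose log the dynamic thresholds (default `FALSE`).
#' @param ... passed to [refine()].
#' @return List with `initial` (the [run_segment()] result), `track`
#'   (the refined [label_track()]), `frame_labels` (refined per-frame
#'   labels) and `thresholds`.
#' @export
run_full <- function(rec, bank, frame_len_s = 0.030, overlap_s = 0.021,
                     smooth_window = 1, switch_penalty = 0, out = NULL,
                     verbose = FALSE, ...) {
  if (is.character(rec)) rec <- read_wav(rec)
  rec <- to_mono(rec)
  initial <- run_segment(rec, bank, frame_len_s, overlap_s,
                         smooth_window, switch_penalty)
  refined <- refine(initial$frame_labels, rec, frame_len_s = frame_len_s,
                    overlap_s = overlap_s, tables = TRUE, ...)
  thr <- attr(refined, "thresholds")
  if (verbose) {
    message(sprintf("thresholds: ZC_BKG=%.3f INT_BKG=%.3f (source: %s)",
                    thr$ZC_BKG, thr$INT_BKG, thr$source))
  }
  frame_labels <- track_to_frame_labels(refined, initial$n_frames,
                                        frame_len_s,
                                        frame_len_s - overlap_s)
  if (!is.null(out)) write_labels(refined, out)
  list(initial = initial, track = refined, frame_labels = frame_labels,
       thresholds = thr)
}

#' Cross-validated evaluation over a corpus
#'
#' Splits the corpus by recording into `k` folds, trains a bank on each
#' training side and scores frame labels on the held-out recordings,
#' with and without post-processing.
#'
#' @param corpus tibble with `id`, `wav`, `labels` columns.
#' @param k number of folds.
#' @param seed fold-shuffle and training seed.
#' @param kind,recipe model configuration, see [train_classifier_bank()].
#' @param J,n_states model sizes.
#' @param postprocess also evaluate refined labels (default `TRUE`).
#' @param frame_len_s,overlap_s analysis grid.
#' @return Tibble: one row per fold x class x stage with confusion counts,
#'   rates and fold accuracy.
#' @export
crossval <- function(corpus, k = 10, seed = 1L, kind = "gmm",
                     recipe = "fft-mfcc", J = 8, n_states = 4,
                     postprocess = TRUE, frame_len_s = 0.030,
                     overlap_s = 0.021) {
  folds <- kfold_split(corpus$id, k = k, seed = seed)
  hop_s <- frame_len_s - overlap_s
  purrr::imap_dfr(folds, function(fold, fi) {
    train_set <- corpus[corpus$id %in% fold$train, ]
    test_set <- corpus[corpus$id %in% fold$test, ]
    feats <- collect_training_features(train_set, kind = kind,
                                       recipe = recipe,
                                       frame_len_s = frame_len_s,
                                       overlap_s = overlap_s)
    bank <- train_classifier_bank(feats, kind = kind, recipe = recipe,
                                  J = J, n_states = n_states, seed = seed)
    ref_all <- character(); hyp_init <- character(); hyp_post <- character()
    for (i in seq_len(nrow(test_set))) {
      rec <- to_mono(read_wav(test_set$wav[i]))
      res <- if (postprocess) run_full(rec, bank, frame_len_s, overlap_s)
             else NULL
      init <- if (postprocess) res$initial else
        run_segment(rec, bank, frame_len_s, overlap_s)
      track <- read_labels(test_set$labels[i])
      ref <- collapse_to_classes(track_to_frame_labels(
        track, init$n_frames, frame_len_s, hop_s
      ))
      ref_all <- c(ref_all, ref)
      hyp_init <- c(hyp_init, init$frame_labels)
      if (postprocess) hyp_post <- c(hyp_post, res$frame_labels)
    }
    out <- dplyr::mutate(rates(frame_confusion(ref_all, hyp_init)),
                         stage = "initial",
                         accuracy = 100 * mean(ref_all == hyp_init),
                         fold = fi)
    if (postprocess) {
      out <- dplyr::bind_rows(out, dplyr::mutate(
        rates(frame_confusion(ref_all, hyp_post)),
        stage = "refined",
        accuracy = 100 * mean(ref_all == hyp_post),
        fold = fi
      ))
    }
    out
  })
}
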