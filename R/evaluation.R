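#' One-vs-rest frame confusion counts
#'
#' Compares hypothesized frame labels against the reference for a single
#' class: TP = frames of the class detected as the class, FP = other
#' frames detected as the class, TN = other frames correctly rejected,
#' FN = missed class frames.
#'
#' @param reference,hypothesis equal-length character vectors of
#'   per-frame labels.
#' @param class the class scored one-vs-rest; when `NULL` (default) all
#'   of [CLASS_LABELS] present in either vector are scored.
#' @return Tibble with columns `class`, `TP`, `FP`, `TN`, `FN`.
#' @export
frame_confusion <- function(reference, hypothesis, class = NULL) {
  if (length(reference) != length(hypothesis)) {
    abort("frame_confusion: length mismatch")
  }
  classes <- if (is.null(class)) {
    intersect(CLASS_LABELS, unique(c(reference, hypothesis)))
  } else {
    class
  }
  purrr::map_dfr(classes, function(cls) {
    ref <- reference == cls
    hyp <- hypothesis == cls
    tibble::tibble(
      class = cls,
      TP = sum(ref & hyp), FP = sum(!ref & hyp),
      TN = sum(!ref & !hyp), FN = sum(ref & !hyp)
    )
  })
}

#' Detection rates from confusion counts
#'
#' `TPR = 100 TP / (TP + FN)`, `FPR = 100 FP / (FP + TN)`,
#' `FNR = 100 FN / (TP + FN)`, in percent. Rates with a zero denominator
#' are reported as `NA` rather than 0.
#'
#' @param counts tibble from [frame_confusion()].
#' @return The input with `TPR`, `FPR`, `FNR` columns added.
#' @export
rates <- function(counts) {
  dplyr::mutate(
    counts,
    TPR = ifelse(.data$TP + .data$FN > 0,
                 100 * .data$TP / (.data$TP + .data$FN), NA_real_),
    FPR = ifelse(.data$FP + .data$TN > 0,
                 100 * .data$FP / (.data$FP + .data$TN), NA_real_),
    FNR = ifelse(.data$TP + .data$FN > 0,
                 100 * .data$FN / (.data$TP + .data$FN), NA_real_)
  )
}

#' Frame-level evaluation report
#'
#' Per-class confusion counts and rates plus the overall accuracy
#' (correct frames / total frames, in percent).
#'
#' @param reference,hypothesis per-frame label vectors.
#' @return List with `per_class` (tibble) and `accuracy` (percent).
#' @export
evaluate_frames <- function(reference, hypothesis) {
  per_class <- rates(frame_confusion(reference, hypothesis))
  list(
    per_class = per_class,
    accuracy = 100 * mean(reference == hypothesis)
  )
}

#' Seeded k-fold split by recording
#'
#' Partitions recording identifiers into `k` folds of near-equal size
#' (difference at most one). The split is by recording, never by frame,
#' so no recording contributes to both the training and validation side
#' of a fold.
#'
#' @param recording_ids vector of unique recording identifiers.
#' @param k number of folds (default 10).
#' @param seed shuffle seed.
#' @return List of `k` elements, each `list(train = ..., test = ...)`.
#' @export
kfold_split <- function(recording_ids, k = 10, seed = 1L) {
  n <- length(recording_ids)
  if (k > n) abort("kfold_split: more folds than recordings")
  perm <- with_local_seed(seed, sample(recording_ids))
  # round-robin fold assignment over the shuffled order
  fold_of <- integer(n)
  fold_of[match(perm, recording_ids)] <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    list(train = recording_ids[fold_of != f],
         test = recording_ids[fold_of == f])
  })
}
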