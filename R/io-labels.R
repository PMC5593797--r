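#' Annotation label vocabulary
#'
#' The segment labels used to annotate cry recordings: `EXP` (audible
#' expiratory cry), `INSV` (inspiration with vocalization, "hiccup"),
#' `INS` (silent inspiratory pause), `EXPN` (faint cry), `EXP2`/`INS2`
#' (babbling phases), `SP` (adult speech), `BIP` (machine beep), `NOR`
#' (other noise) and `BKG` (background silence).
#'
#' @format Character vector of the ten permitted labels.
#' @export
LABEL_VOCABULARY <- c("EXP", "INSV", "INS", "EXPN", "EXP2", "INS2",
                      "SP", "BIP", "NOR", "BKG")

#' The four classes modelled by the classifiers
#'
#' `EXP`, `INS` (vocalized inspiration), `BKG` and `NOR` (everything else).
#' The fixed order also defines the tie-break in classification.
#' @format Character vector of four class names.
#' @export
CLASS_LABELS <- c("EXP", "INS", "BKG", "NOR")

#' Construct a label track
#'
#' A label track is a tibble of timed, labelled segments with columns
#' `start_s`, `end_s` and `label`. Segments are half-open `[start, end)`
#' intervals so that abutting segments do not overlap. Construction
#' validates ordering, positivity and overlap-freedom and sorts by start
#' time.
#'
#' @param start_s,end_s segment boundaries in seconds.
#' @param label segment labels, drawn from [LABEL_VOCABULARY].
#' @param validate_vocabulary if `TRUE` (default) reject labels outside the
#'   annotation vocabulary.
#' @return A tibble of class `label_track`.
#' @examples
#' label_track(c(0, 1.2), c(1.2, 1.45), c("EXP", "INSV"))
#' @export
label_track <- function(start_s = numeric(), end_s = numeric(),
                        label = character(), validate_vocabulary = TRUE) {
  tr <- tibble::tibble(
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    label = as.character(label)
  )
  tr <- dplyr::arrange(tr, .data$start_s)
  validate_label_track(tr, validate_vocabulary = validate_vocabulary)
  class(tr) <- c("label_track", class(tr))
  tr
}

validate_label_track <- function(tr, validate_vocabulary = TRUE) {
  if (nrow(tr) == 0) return(invisible(tr))
  bad <- which(tr$start_s >= tr$end_s)
  if (length(bad)) {
    abort(sprintf("label_track: segment %d has start_s >= end_s", bad[1]))
  }
  if (validate_vocabulary) {
    unk <- setdiff(unique(tr$label), LABEL_VOCABULARY)
    if (length(unk)) {
      abort(paste0("label_track: unknown label(s): ",
                   paste(unk, collapse = ", ")))
    }
  }
  if (nrow(tr) > 1) {
    # half-open intervals: overlap iff next start < current end
    ov <- which(head(tr$end_s, -1) > tail(tr$start_s, -1) + 1e-9)
    if (length(ov)) {
      abort(sprintf("label_track: segments %d and %d overlap", ov[1], ov[1] + 1))
    }
  }
  invisible(tr)
}

#' Read a segment label file
#'
#' Parses tab-separated annotation files with one segment per line,
#' `start_s<TAB>end_s<TAB>label` (the WaveSurfer transcription
#' convention). Lines may appear out of order; segments are sorted and
#' checked for overlap.
#'
#' @param path path to a label file.
#' @param validate_vocabulary reject labels outside [LABEL_VOCABULARY].
#' @return A [label_track()].
#' @export
read_labels <- function(path, validate_vocabulary = TRUE) {
  if (!file.exists(path)) abort(paste0("read_labels: no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(label_track())
  parts <- strsplit(lines, "[\t ]+")
  nf <- vapply(parts, length, integer(1))
  if (any(nf != 3L)) {
    abort(sprintf("read_labels: line %d does not have 3 fields",
                  which(nf != 3L)[1]))
  }
  start_s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  end_s <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(start_s) || anyNA(end_s)) {
    abort(sprintf("read_labels: non-numeric time on line %d",
                  which(is.na(start_s) | is.na(end_s))[1]))
  }
  label_track(start_s, end_s, vapply(parts, `[[`, "", 3L),
              validate_vocabulary = validate_vocabulary)
}

#' Write a segment label file
#'
#' @param track a [label_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(track, path) {
  validate_label_track(track, validate_vocabulary = FALSE)
  lines <- sprintf("%.6f\t%.6f\t%s", track$start_s, track$end_s, track$label)
  writeLines(lines, path)
  invisible(path)
}

#' Convert a frame index to its time span
#'
#' Frames are numbered from 1; frame `i` spans
#' `[(i - 1) * hop_s, (i - 1) * hop_s + frame_len_s)`.
#'
#' @param frame_index 1-based frame number(s).
#' @param frame_len_s frame length in seconds.
#' @param hop_s hop (frame advance) in seconds; `0 < hop_s <= frame_len_s`.
#' @return A tibble with columns `frame`, `start_s`, `end_s`.
#' @export
frames_to_time <- function(frame_index, frame_len_s, hop_s) {
  if (frame_len_s <= 0) abort("frames_to_time: frame_len_s must be positive")
  if (hop_s <= 0 || hop_s > frame_len_s) {
    abort("frames_to_time: need 0 < hop_s <= frame_len_s")
  }
  if (any(frame_index < 1)) abort("frames_to_time: frame_index must be >= 1")
  start_s <- (frame_index - 1) * hop_s
  tibble::tibble(frame = frame_index, start_s = start_s,
                 end_s = start_s + frame_len_s)
}

#' Per-frame labels from a label track
#'
#' Assigns each analysis frame the label of the segment containing the
#' midpoint of the frame's hop cell `[(i-1) hop, i hop)`; frames outside
#' any segment get `fill`. This is the exact inverse of
#' [frame_labels_to_track()], whose segment boundaries fall on hop
#' boundaries.
#'
#' @param track a [label_track()].
#' @param n_frames number of analysis frames.
#' @param frame_len_s,hop_s framing parameters in seconds.
#' @param fill label for uncovered frames (default `"BKG"`).
#' @return Character vector of length `n_frames`.
#' @export
track_to_frame_labels <- function(track, n_frames, frame_len_s, hop_s,
                                  fill = "BKG") {
  centre <- (seq_len(n_frames) - 1) * hop_s + hop_s / 2
  out <- rep(fill, n_frames)
  for (i in seq_len(nrow(track))) {
    inside <- centre >= track$start_s[i] & centre < track$end_s[i]
    out[inside] <- track$label[i]
  }
  out
}

#' Segments from per-frame labels
#'
#' Collapses maximal runs of identical frame labels into segments. Segment
#' boundaries fall on hop boundaries (frame `i` contributes
#' `[(i-1) * hop, i * hop)`); the final segment is extended to
#' `total_s` when given, so the segments partition the recording.
#'
#' @param labels character vector of per-frame labels.
#' @param frame_len_s,hop_s framing parameters in seconds.
#' @param total_s optional total recording duration in seconds.
#' @return A [label_track()].
#' @export
frame_labels_to_track <- function(labels, frame_len_s, hop_s, total_s = NULL) {
  n <- length(labels)
  if (n == 0) return(label_track())
  r <- rle(labels)
  ends_frame <- cumsum(r$lengths)
  starts_frame <- c(1L, head(ends_frame, -1) + 1L)
  start_s <- (starts_frame - 1) * hop_s
  end_s <- ends_frame * hop_s
  # the last frame extends to the end of its analysis window / recording
  end_s[length(end_s)] <- max(
    (ends_frame[length(ends_frame)] - 1) * hop_s + frame_len_s,
    if (is.null(total_s)) 0 else total_s
  )
  label_track(start_s, end_s, r$values, validate_vocabulary = FALSE)
}

#' Collapse annotation labels onto the four modelled classes
#'
#' `EXP` stays `EXP`; `INSV` (vocalized inspiration) becomes the `INS`
#' class; `BKG` stays `BKG`; every other annotation (silent `INS`, `EXPN`,
#' `EXP2`, `INS2`, `SP`, `BIP`, `NOR`) collapses to `NOR`.
#'
#' @param labels character vector of annotation labels.
#' @return Character vector over [CLASS_LABELS].
#' @export
collapse_to_classes <- function(labels) {
  out <- rep("NOR", length(labels))
  out[labels == "EXP"] <- "EXP"
  out[labels == "INSV"] <- "INS"
  out[labels == "BKG"] <- "BKG"
  out
}

#' @export
autoplot.label_track <- function(object, ...) {
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start_s, xmax = .data$end_s,
      ymin = 0, ymax = 1, fill = .data$label
    )) +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "label") +
    ggplot2::theme_minimal()
}
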