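#' Pre-emphasis filter
#'
#' Applies the first-order high-pass emphasis filter
#' `y[n] = x[n] - alpha * x[n - 1]` (transfer function `1 - alpha z^-1`),
#' boosting the high-frequency content before cepstral analysis.
#'
#' @param rec a mono [audio_recording()].
#' @param alpha emphasis coefficient in `[0, 1)`; default 0.97.
#' @return An [audio_recording()] of the same length.
#' @export
preemphasize <- function(rec, alpha = 0.97) {
  stopifnot(inherits(rec, "audio_recording"))
  if (rec$n_channels != 1L) abort("preemphasize: mono input required")
  if (alpha < 0 || alpha >= 1) abort("preemphasize: alpha must be in [0, 1)")
  x <- rec$samples[, 1]
  y <- x - alpha * c(0, head(x, -1))
  y[1] <- x[1]
  audio_recording(y, rec$sample_rate_hz)
}

#' Split a signal into overlapping frames
#'
#' Cuts the mono waveform into frames of `frame_len_s` seconds advancing by
#' `frame_len_s - overlap_s` (the hop). Defaults follow the 30 ms window /
#' 21 ms overlap analysis grid, i.e. a 9 ms hop. Trailing samples shorter
#' than one frame are dropped, so
#' `n_frames = floor((N - frame_len) / hop) + 1`.
#'
#' @param rec a mono [audio_recording()].
#' @param frame_len_s frame length in seconds (default 0.030).
#' @param overlap_s overlap between consecutive frames in seconds
#'   (default 0.021); must be smaller than `frame_len_s`.
#' @return A `frame_matrix`: list with `frames` (n_frames x frame_len
#'   matrix), `frame_len_samples`, `hop_samples`, `sample_rate_hz`,
#'   `windowed`.
#' @export
frame_signal <- function(rec, frame_len_s = 0.030, overlap_s = 0.021) {
  stopifnot(inherits(rec, "audio_recording"))
  if (rec$n_channels != 1L) abort("frame_signal: mono input required")
  if (overlap_s >= frame_len_s) {
    abort("frame_signal: overlap_s must be smaller than frame_len_s")
  }
  rate <- rec$sample_rate_hz
  flen <- round(frame_len_s * rate)
  hop <- round((frame_len_s - overlap_s) * rate)
  if (hop < 1) abort("frame_signal: hop shorter than one sample")
  x <- rec$samples[, 1]
  n <- length(x)
  if (n < flen) abort("frame_signal: signal shorter than one frame")
  n_frames <- (n - flen) %/% hop + 1L
  idx <- outer(seq_len(flen) - 1L, (seq_len(n_frames) - 1L) * hop, `+`) + 1L
  frames <- t(matrix(x[idx], nrow = flen))
  structure(
    list(
      frames = frames,
      frame_len_samples = flen,
      hop_samples = hop,
      sample_rate_hz = rate,
      windowed = FALSE
    ),
    class = "frame_matrix"
  )
}

#' @export
print.frame_matrix <- function(x, ...) {
  cat(sprintf(
    "<frame_matrix> %d frames of %d samples (hop %d) at %d Hz%s\n",
    nrow(x$frames), x$frame_len_samples, x$hop_samples, x$sample_rate_hz,
    if (x$windowed) ", windowed" else ""
  ))
  invisible(x)
}

#' Hamming window
#'
#' `w(n) = 0.54 - 0.46 cos(2 pi n / (N - 1))`, `0 <= n <= N - 1`.
#'
#' @param n window length in samples.
#' @return Numeric vector of length `n`.
#' @export
hamming_window <- function(n) {
  if (n == 1) return(1)
  k <- seq_len(n) - 1
  0.54 - 0.46 * cos(2 * pi * k / (n - 1))
}

#' Apply a Hamming window to every frame
#'
#' @param fm a `frame_matrix` from [frame_signal()], not yet windowed.
#' @return The windowed `frame_matrix`.
#' @export
apply_hamming <- function(fm) {
  stopifnot(inherits(fm, "frame_matrix"))
  if (fm$windowed) abort("apply_hamming: frames already windowed")
  w <- hamming_window(fm$frame_len_samples)
  fm$frames <- sweep(fm$frames, 2, w, `*`)
  fm$windowed <- TRUE
  fm
}

n_frames <- function(fm) nrow(fm$frames)

frame_hop_s <- function(fm) fm$hop_samples / fm$sample_rate_hz

frame_len_s <- function(fm) fm$frame_len_samples / fm$sample_rate_hz
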