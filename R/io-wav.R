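#' Audio recordings
#'
#' An `audio_recording` holds a sampled waveform together with its sample
#' rate. Samples are stored as a numeric matrix with one column per channel
#' and amplitudes in the nominal range \[-1, 1\].
#'
#' @param samples numeric vector (mono) or matrix with one column per channel.
#' @param sample_rate_hz positive sampling rate in Hz.
#' @return An object of class `audio_recording` with elements `samples`
#'   (matrix, one column per channel), `sample_rate_hz` and `n_channels`.
#' @examples
#' rec <- audio_recording(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), 8000)
#' rec$n_channels
#' @export
audio_recording <- function(samples, sample_rate_hz) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (nrow(samples) == 0) abort("audio_recording: empty sample array")
  if (!ncol(samples) %in% c(1L, 2L)) {
    abort("audio_recording: n_channels must be 1 or 2")
  }
  sample_rate_hz <- as.integer(sample_rate_hz)
  if (is.na(sample_rate_hz) || sample_rate_hz <= 0) {
    abort("audio_recording: sample_rate_hz must be a positive integer")
  }
  structure(
    list(
      samples = samples,
      sample_rate_hz = sample_rate_hz,
      n_channels = ncol(samples)
    ),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf(
    "<audio_recording> %d samples, %d channel(s), %d Hz (%.3f s)\n",
    nrow(x$samples), x$n_channels, x$sample_rate_hz,
    nrow(x$samples) / x$sample_rate_hz
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an [audio_recording()].
#' @return length in seconds.
#' @export
duration_s <- function(rec) nrow(rec$samples) / rec$sample_rate_hz

#' Read a PCM WAV file
#'
#' Reads an uncompressed PCM RIFF/WAVE file (8-, 16- or 24-bit integer
#' samples, any rate, 1 or 2 channels) and rescales amplitudes to
#' \[-1, 1\] (full-scale negative integer maps to -1).
#'
#' @param path path to a `.wav` file.
#' @return An [audio_recording()].
#' @seealso [write_wav()], [to_mono()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort(paste0("read_wav: no such file: ", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) abort("read_wav: not a RIFF file")
  readBin(con, "integer", 1, size = 4, endian = "little") # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) abort("read_wav: not a WAVE file")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2,
                               endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, size = 2,
                               endian = "little", signed = FALSE)
      )
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      break
    } else {
      readBin(con, "raw", sz + (sz %% 2))
    }
  }
  if (is.null(fmt)) abort("read_wav: missing fmt chunk")
  if (is.null(data_raw)) abort("read_wav: missing data chunk")
  if (fmt$audio_format != 1L) {
    abort(sprintf("read_wav: unsupported (non-PCM) format code %d",
                  fmt$audio_format))
  }
  x <- switch(as.character(fmt$bits),
    "8" = {
      # 8-bit WAV is unsigned, midpoint 128
      v <- as.integer(data_raw)
      (v - 128) / 128
    },
    "16" = {
      v <- readBin(data_raw, "integer", n = length(data_raw) / 2,
                   size = 2, endian = "little", signed = TRUE)
      v / 32768
    },
    "24" = {
      n <- length(data_raw) / 3
      b <- matrix(as.integer(data_raw), nrow = 3)
      v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    },
    abort(sprintf("read_wav: unsupported bit depth %d", fmt$bits))
  )
  nch <- fmt$n_channels
  if (!nch %in% c(1L, 2L)) {
    abort(sprintf("read_wav: unsupported channel count %d", nch))
  }
  samples <- matrix(x, ncol = nch, byrow = TRUE)
  audio_recording(samples, fmt$sample_rate)
}

#' Write a PCM WAV file
#'
#' @param rec an [audio_recording()].
#' @param path output path.
#' @param bits sample resolution: 8, 16 (default) or 24.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16L) {
  stopifnot(inherits(rec, "audio_recording"))
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L, 24L)) abort("write_wav: bits must be 8, 16 or 24")
  x <- t(rec$samples) # interleave channels
  x <- as.vector(x)
  x <- pmax(pmin(x, 1), -1)
  nch <- rec$n_channels
  rate <- rec$sample_rate_hz
  block_align <- nch * bits / 8L
  data_len <- length(x) * bits / 8L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * block_align), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  if (bits == 8L) {
    v <- as.integer(round(x * 128) + 128)
    v <- pmax(pmin(v, 255L), 0L)
    writeBin(as.raw(v), con)
  } else if (bits == 16L) {
    v <- as.integer(round(x * 32768))
    v <- pmax(pmin(v, 32767L), -32768L)
    writeBin(v, con, size = 2, endian = "little")
  } else {
    v <- round(x * 8388608)
    v <- pmax(pmin(v, 8388607), -8388608)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(as.vector(b)), con)
  }
  invisible(path)
}

#' Average a stereo recording down to mono
#'
#' Two-channel recordings are converted by taking the per-sample mean of
#' both channels; mono input is returned unchanged.
#'
#' @param rec an [audio_recording()].
#' @return A single-channel [audio_recording()].
#' @export
to_mono <- function(rec) {
  stopifnot(inherits(rec, "audio_recording"))
  if (rec$n_channels == 1L) return(rec)
  audio_recording(rowMeans(rec$samples), rec$sample_rate_hz)
}
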