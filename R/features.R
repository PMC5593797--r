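#' Per-frame sound intensity level
#'
#' Logarithmic intensity of each frame in decibels,
#' `I = 10 log10( sum_n s^2(n) w(n) + eps )`, where `w` is the Hamming
#' analysis window and `eps` a small floor guarding all-zero frames.
#' Computed on the raw (un-emphasized) frames so the dynamic endpoint
#' thresholds of the post-processing stage see the true energy profile.
#'
#' @param fm an unwindowed `frame_matrix`.
#' @param eps silence floor added inside the logarithm (default 1e-10).
#' @return Numeric vector, one dB value per frame.
#' @export
frame_intensity <- function(fm, eps = 1e-10) {
  stopifnot(inherits(fm, "frame_matrix"))
  w <- hamming_window(fm$frame_len_samples)
  10 * log10(drop(fm$frames^2 %*% w) + eps)
}

#' Per-frame zero-crossing count
#'
#' Number of sign changes between consecutive samples within each frame;
#' exact zeros are treated as positive. Frames must be unwindowed so the
#' sign pattern is the signal's own.
#'
#' @param fm an unwindowed `frame_matrix`.
#' @return Integer vector, one count per frame.
#' @export
frame_zcr <- function(fm) {
  stopifnot(inherits(fm, "frame_matrix"))
  if (fm$windowed) abort("frame_zcr: expected unwindowed frames")
  s <- fm$frames >= 0
  rowSums(s[, -1, drop = FALSE] != s[, -ncol(s), drop = FALSE])
}

#' Fundamental frequency by the autocorrelation method
#'
#' For each frame the normalized autocorrelation `r(tau) / r(0)` is
#' maximized over candidate lags `rate/fmax_hz .. rate/fmin_hz`; the frame
#' is voiced when the peak exceeds `voicing_threshold`, and then
#' `f0 = rate / tau*`.
#'
#' @param fm an unwindowed `frame_matrix` of the raw signal.
#' @param fmin_hz,fmax_hz search band in Hz (defaults 75 and 1000).
#' @param voicing_threshold minimum normalized peak for a voiced decision
#'   (default 0.45).
#' @return An `f0_track` tibble with columns `frame`, `f0_hz` (`NA` on
#'   unvoiced frames), `voiced`, `peak` (the normalized peak height).
#' @export
f0_autocorr <- function(fm, fmin_hz = 75, fmax_hz = 1000,
                        voicing_threshold = 0.45) {
  stopifnot(inherits(fm, "frame_matrix"))
  rate <- fm$sample_rate_hz
  if (!(fmin_hz < fmax_hz && fmax_hz < rate / 2)) {
    abort("f0_autocorr: need fmin < fmax < sample_rate / 2")
  }
  flen <- fm$frame_len_samples
  lag_min <- max(2L, floor(rate / fmax_hz))
  lag_max <- min(flen - 1L, ceiling(rate / fmin_hz))
  if (lag_min > lag_max) {
    abort("f0_autocorr: frame too short for the requested band")
  }
  nfft <- 2^ceiling(log2(2 * flen))
  X <- rbind(t(fm$frames), matrix(0, nfft - flen, nrow(fm$frames)))
  # autocorrelation of each frame via the Wiener-Khinchin identity
  R <- Re(stats::mvfft(Mod(stats::mvfft(X))^2, inverse = TRUE)) / nfft
  r0 <- R[1, ]
  band <- R[(lag_min:lag_max) + 1L, , drop = FALSE]
  peak_idx <- apply(band, 2, which.max)
  peak <- band[cbind(peak_idx, seq_along(peak_idx))] /
    pmax(r0, .Machine$double.eps)
  voiced <- r0 > 0 & peak >= voicing_threshold
  f0 <- ifelse(voiced, rate / (lag_min + peak_idx - 1L), NA_real_)
  out <- tibble::tibble(
    frame = seq_along(f0), f0_hz = f0, voiced = voiced, peak = peak
  )
  class(out) <- c("f0_track", class(out))
  out
}

#' Utterance-level fundamental-frequency statistics
#'
#' Minimum, maximum and mean F0 over the voiced frames of a (subset of a)
#' track; `NA` when no frame is voiced.
#'
#' @param track an `f0_track` from [f0_autocorr()].
#' @param frames optional frame indices delimiting the utterance.
#' @return A one-row tibble `f0_min`, `f0_max`, `f0_mean`, `n_voiced`.
#' @export
f0_stats <- function(track, frames = NULL) {
  if (!is.null(frames)) track <- track[track$frame %in% frames, ]
  v <- track$f0_hz[track$voiced]
  if (length(v) == 0) {
    return(tibble::tibble(f0_min = NA_real_, f0_max = NA_real_,
                          f0_mean = NA_real_, n_voiced = 0L))
  }
  tibble::tibble(f0_min = min(v), f0_max = max(v), f0_mean = mean(v),
                 n_voiced = length(v))
}

#' @export
autoplot.f0_track <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frame, .data$f0_hz)) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.8) +
    ggplot2::labs(x = "frame", y = "F0 (Hz)") +
    ggplot2::theme_minimal()
}

#' Hertz to mel conversion
#'
#' `Mel(f) = 2595 log10(1 + f / 700)`.
#'
#' @param f_hz frequency in Hz, non-negative.
#' @return Mel value(s).
#' @export
mel_scale <- function(f_hz) {
  if (any(f_hz < 0)) abort("mel_scale: negative frequency")
  2595 * log10(1 + f_hz / 700)
}

#' Mel to hertz conversion
#' @param mel mel value(s).
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(mel) 700 * (10^(mel / 2595) - 1)

# triangular mel filterbank: n_filters x n_bins weight matrix
mel_filterbank <- function(n_filters, nfft, rate, fmin_hz = 0,
                           fmax_hz = rate / 2) {
  mels <- seq(mel_scale(fmin_hz), mel_scale(fmax_hz), length.out = n_filters + 2)
  hz <- mel_to_hz(mels)
  bins <- hz / rate * nfft # fractional bin centres
  n_bins <- nfft %/% 2 + 1
  fb <- matrix(0, n_filters, n_bins)
  k <- 0:(n_bins - 1)
  for (m in seq_len(n_filters)) {
    left <- bins[m]; centre <- bins[m + 1]; right <- bins[m + 2]
    up <- (k - left) / (centre - left)
    down <- (right - k) / (right - centre)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Mel-frequency cepstral coefficients from the FFT power spectrum
#'
#' Per frame: FFT power spectrum, triangular mel filterbank energies
#' `S_k`, natural log, then the cosine transform
#' `c_n = sum_k log(S_k) cos(n (k - 1/2) pi / M)` for `n = 1..K`
#' over the `M` filters. A log-energy term is appended as the 13th static
#' coefficient so that with delta and acceleration coefficients the frame
#' vector reaches the standard 39 dimensions.
#'
#' @param fm a windowed `frame_matrix` (typically of the pre-emphasized
#'   signal).
#' @param n_filters number of mel filters (default 26).
#' @param n_cepstra number of cepstra `K` (default 12).
#' @param include_energy append the log-energy term (default `TRUE`).
#' @param floor filterbank energy floor before the log (default 1e-12).
#' @return Numeric matrix, `n_frames` x `(n_cepstra + include_energy)`,
#'   columns `c1..cK` and `logE`.
#' @export
mfcc_fft <- function(fm, n_filters = 26, n_cepstra = 12,
                     include_energy = TRUE, floor = 1e-12) {
  stopifnot(inherits(fm, "frame_matrix"))
  if (!fm$windowed) abort("mfcc_fft: frames must be windowed first")
  if (n_cepstra > n_filters) abort("mfcc_fft: n_cepstra > n_filters")
  flen <- fm$frame_len_samples
  nfft <- 2^ceiling(log2(flen))
  rate <- fm$sample_rate_hz
  X <- rbind(t(fm$frames), matrix(0, nfft - flen, nrow(fm$frames)))
  P <- Mod(stats::mvfft(X))^2
  P <- P[seq_len(nfft %/% 2 + 1), , drop = FALSE]
  fb <- mel_filterbank(n_filters, nfft, rate)
  S <- pmax(fb %*% P, floor) # n_filters x n_frames
  logS <- log(S)
  k <- seq_len(n_filters)
  dct <- outer(seq_len(n_cepstra), k,
               function(n, k) cos(n * (k - 0.5) * pi / n_filters))
  C <- t(dct %*% logS)
  colnames(C) <- paste0("c", seq_len(n_cepstra))
  if (include_energy) {
    logE <- log(rowSums(fm$frames^2) + floor)
    C <- cbind(C, logE = logE)
  }
  C
}

#' Append delta and acceleration coefficients
#'
#' Dynamic coefficients by the standard regression formula
#' `d_t = sum_{theta=1..W} theta (c_{t+theta} - c_{t-theta}) / (2 sum theta^2)`
#' with edge frames replicated; acceleration coefficients are deltas of
#' deltas. Triples the feature dimensionality (13 static -> 39).
#'
#' @param X feature matrix, frames in rows.
#' @param window regression half-width `W` (default 2).
#' @return Matrix with `3 * ncol(X)` columns: static, `d_*`, `dd_*`.
#' @export
add_deltas <- function(X, window = 2) {
  X <- as.matrix(X)
  if (nrow(X) < 2 * window + 1) {
    abort("add_deltas: need at least 2 * window + 1 frames")
  }
  d <- delta_regression(X, window)
  dd <- delta_regression(d, window)
  nm <- colnames(X)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(X)))
  colnames(d) <- paste0("d_", nm)
  colnames(dd) <- paste0("dd_", nm)
  cbind(X, d, dd)
}

delta_regression <- function(X, window) {
  n <- nrow(X)
  denom <- 2 * sum((1:window)^2)
  num <- matrix(0, n, ncol(X))
  for (theta in seq_len(window)) {
    fwd <- pmin(seq_len(n) + theta, n) # edge replication
    bwd <- pmax(seq_len(n) - theta, 1L)
    num <- num + theta * (X[fwd, , drop = FALSE] - X[bwd, , drop = FALSE])
  }
  num / denom
}

#' Full 39-dimensional classifier feature stack
#'
#' Convenience wrapper producing the frame features used by the initial
#' classifiers: pre-emphasis, framing, Hamming window, mel cepstra
#' (`c1..c12` + log-energy) and delta/acceleration stacking. With
#' `recipe = "emd-mfcc"` the cepstra are computed on the recombination of
#' intrinsic mode functions 3-5 from [emd_decompose()] instead of the raw
#' signal.
#'
#' @param rec a mono [audio_recording()].
#' @param recipe `"fft-mfcc"` (default) or `"emd-mfcc"`.
#' @param frame_len_s,overlap_s analysis grid (defaults 0.030 / 0.021).
#' @param preemphasis_alpha emphasis coefficient (default 0.97).
#' @param n_filters,n_cepstra,delta_window cepstral parameters.
#' @param imf_indices IMFs summed for the `"emd-mfcc"` recipe
#'   (default `c(3, 4, 5)`).
#' @return Numeric matrix, frames in rows, 39 columns at the defaults.
#' @export
cry_features <- function(rec, recipe = c("fft-mfcc", "emd-mfcc"),
                         frame_len_s = 0.030, overlap_s = 0.021,
                         preemphasis_alpha = 0.97, n_filters = 26,
                         n_cepstra = 12, delta_window = 2,
                         imf_indices = c(3, 4, 5)) {
  recipe <- match.arg(recipe)
  rec <- to_mono(rec)
  if (recipe == "emd-mfcc") {
    dec <- emd_decompose(rec$samples[, 1], n_imfs_min = max(imf_indices))
    rec <- audio_recording(combine_imfs(dec, imf_indices), rec$sample_rate_hz)
  }
  emph <- preemphasize(rec, preemphasis_alpha)
  fm <- apply_hamming(frame_signal(emph, frame_len_s, overlap_s))
  static <- mfcc_fft(fm, n_filters = n_filters, n_cepstra = n_cepstra)
  add_deltas(static, window = delta_window)
}
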