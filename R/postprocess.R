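#' Dynamic background thresholds
#'
#' Estimates the zero-crossing and intensity thresholds that separate
#' background silence from acoustic activity, in the style of
#' Rabiner-Sambur endpoint detection but recomputed per recording from
#' the frames the initial classifier called background. With `ZCR_sil`
#' and `INT_sil` the zero-crossing and intensity vectors of the silence
#' span and `INT_sig` the intensity vector of the whole signal:
#'
#' \preformatted{
#' ZC_BKG  = mean(ZCR_sil) + 2 sd(ZCR_sil)
#' Imean   = mean(INT_sil);  Imax = max(INT_sig)
#' I1      = 0.03 (Imax - Imean) + Imean
#' I2      = 4 Imean
#' ITL     = min(I1, I2)
#' INT_BKG = 5 ITL
#' }
#'
#' The silence span is the earliest `silence_span_ms` worth of frames
#' initially labelled `BKG`; when no frame is labelled `BKG`, the
#' minimum-mean-intensity window of that length is used instead. By
#' default (`linear_energy = TRUE`) the multiplicative algebra operates on
#' linear frame energy `10^(I/10)` — the domain of the original endpoint
#' rules — and `INT_BKG` is converted back to dB, which places the
#' threshold roughly 13 dB above the silence floor. With
#' `linear_energy = FALSE` the same algebra is applied to the dB values
#' themselves; note that this degenerates whenever the silence intensity
#' is negative in dB (amplitudes below 1), since `4 Imean` then falls
#' below every frame intensity and no interval can be classified
#' inactive.
#'
#' @param intensity per-frame intensity in dB.
#' @param zcr per-frame zero-crossing counts.
#' @param initial_labels per-frame class labels from the initial
#'   classification (may be `NULL`: fallback window is used).
#' @param silence_span_ms length of the silence span (default 250).
#' @param hop_s frame hop in seconds (default 0.009).
#' @param linear_energy apply the threshold algebra on linear energy
#'   (default `TRUE`); `FALSE` applies it to the dB values directly.
#' @return A one-row `threshold_set` tibble: `ZC_BKG`, `INT_BKG`,
#'   `Imean`, `Imax`, `I1`, `I2`, `ITL`, `source`.
#' @export
compute_thresholds <- function(intensity, zcr, initial_labels = NULL,
                               silence_span_ms = 250, hop_s = 0.009,
                               linear_energy = TRUE) {
  n <- length(intensity)
  if (n == 0) abort("compute_thresholds: no frames")
  if (length(zcr) != n) abort("compute_thresholds: length mismatch")
  n_sil <- max(1L, round(silence_span_ms / 1000 / hop_s))
  if (n < n_sil) {
    warn("compute_thresholds: signal shorter than the silence span; using all frames")
    n_sil <- n
  }
  bkg <- if (is.null(initial_labels)) integer() else which(initial_labels == "BKG")
  if (length(bkg) >= 1) {
    sil_idx <- head(bkg, n_sil)
    source <- "initial-BKG"
  } else {
    # minimum-mean-intensity sliding window fallback
    cs <- cumsum(c(0, intensity))
    win_mean <- (cs[(n_sil + 1):(n + 1)] - cs[1:(n - n_sil + 1)]) / n_sil
    s0 <- which.min(win_mean)
    sil_idx <- s0:(s0 + n_sil - 1)
    source <- "min-intensity-window"
  }
  zcr_sil <- zcr[sil_idx]
  if (linear_energy) {
    e_sil <- 10^(intensity[sil_idx] / 10)
    e_sig <- 10^(intensity / 10)
    Imean <- mean(e_sil); Imax <- max(e_sig)
    I1 <- 0.03 * (Imax - Imean) + Imean
    I2 <- 4 * Imean
    ITL <- min(I1, I2)
    INT_BKG <- 10 * log10(5 * ITL)
    Imean <- 10 * log10(Imean); Imax <- 10 * log10(Imax)
    I1 <- 10 * log10(I1); I2 <- 10 * log10(I2); ITL <- 10 * log10(ITL)
  } else {
    Imean <- mean(intensity[sil_idx])
    Imax <- max(intensity)
    I1 <- 0.03 * (Imax - Imean) + Imean
    I2 <- 4 * Imean
    ITL <- min(I1, I2)
    INT_BKG <- 5 * ITL
  }
  zc_sd <- if (length(zcr_sil) > 1) sd(zcr_sil) else 0
  out <- tibble::tibble(
    ZC_BKG = mean(zcr_sil) + 2 * zc_sd,
    INT_BKG = INT_BKG,
    Imean = Imean, Imax = Imax, I1 = I1, I2 = I2, ITL = ITL,
    source = source
  )
  class(out) <- c("threshold_set", class(out))
  out
}

#' Per-frame voicing index
#'
#' 1 where a fundamental-frequency estimate exists, 0 elsewhere.
#'
#' @param f0 an `f0_track` from [f0_autocorr()] (or a numeric vector with
#'   `NA` on unvoiced frames).
#' @return Integer vector of 0/1.
#' @export
voicing_index <- function(f0) {
  v <- if (inherits(f0, "f0_track") || is.data.frame(f0)) f0$f0_hz else f0
  if (length(v) == 0) abort("voicing_index: empty track")
  as.integer(!is.na(v))
}

#' Mark voicing transitions
#'
#' A frame is marked (index 2) when its voicing differs from the next
#' frame's, i.e. the mark sits on the last frame of each voicing run.
#'
#' @param voicing per-frame 0/1 voicing index.
#' @return Integer vector: 2 at transition frames, `NA` elsewhere.
#' @export
mark_transitions <- function(voicing) {
  n <- length(voicing)
  if (n == 0) abort("mark_transitions: empty input")
  marks <- rep(NA_integer_, n)
  if (n > 1) {
    marks[which(voicing[-n] != voicing[-1])] <- 2L
  }
  marks
}

#' Mark local minima of the intensity contour
#'
#' Interior frame `t` is marked (index 2) when
#' `intensity[t] < intensity[t - 1]` and `intensity[t] <= intensity[t + 1]`;
#' the first frame is marked when the contour rises away from it.
#' Optionally the contour is median-smoothed over 3 frames first.
#'
#' @param intensity per-frame intensity in dB.
#' @param smooth apply 3-frame median smoothing before detection
#'   (default `FALSE`).
#' @return Integer vector: 2 at minima, `NA` elsewhere.
#' @export
mark_intensity_minima <- function(intensity, smooth = FALSE) {
  n <- length(intensity)
  if (n < 3) abort("mark_intensity_minima: need at least 3 frames")
  x <- intensity
  if (smooth) {
    x <- vapply(seq_len(n), function(t) {
      median(intensity[max(1, t - 1):min(n, t + 1)])
    }, 0)
  }
  marks <- rep(NA_integer_, n)
  if (x[1] < x[2]) marks[1] <- 2L
  interior <- 2:(n - 1)
  hit <- x[interior] < x[interior - 1] & x[interior] <= x[interior + 1]
  marks[interior][hit] <- 2L
  marks
}

#' Combine voicing, transition and minima indexes
#'
#' The combined per-frame index is 2 wherever a transition or minima mark
#' sits (and always on the final frame, which closes the last interval);
#' elsewhere it is the voicing index.
#'
#' @param voicing per-frame 0/1.
#' @param transitions,minima mark vectors from [mark_transitions()] /
#'   [mark_intensity_minima()].
#' @return Integer vector over \{0, 1, 2\}.
#' @export
combine_indices <- function(voicing, transitions, minima) {
  n <- length(voicing)
  if (length(transitions) != n || length(minima) != n) {
    abort("combine_indices: length mismatch")
  }
  out <- as.integer(voicing)
  out[!is.na(transitions) | !is.na(minima)] <- 2L
  out[n] <- 2L
  out
}

#' Cut the frame range into intervals at the combined boundaries
#'
#' Every frame with combined index 2 closes an interval; the next interval
#' starts at the following frame. A boundary on frame 1 opens (rather
#' than closes) the first interval.
#'
#' @param combined per-frame combined index from [combine_indices()].
#' @return Tibble with columns `start_frame`, `end_frame`.
#' @export
build_intervals <- function(combined) {
  n <- length(combined)
  if (combined[n] != 2L) abort("build_intervals: final frame must be a boundary")
  ends <- which(combined == 2L)
  if (length(ends) > 0 && ends[1] == 1L && n > 1) ends <- ends[-1]
  starts <- c(1L, head(ends, -1) + 1L)
  tibble::tibble(start_frame = starts, end_frame = ends)
}

#' Activity index per interval
#'
#' Computes the mean intensity and mean zero-crossing count over each
#' interval and compares them with the dynamic thresholds: an interval is
#' active (`new_index = 1`) when its mean intensity reaches `INT_BKG` or
#' its mean ZCR reaches `ZC_BKG`; otherwise inactive (0).
#'
#' @param intervals tibble from [build_intervals()].
#' @param intensity,zcr per-frame vectors.
#' @param thresholds a `threshold_set` from [compute_thresholds()].
#' @return The interval tibble with `mean_intensity`, `mean_zcr`,
#'   `new_index` columns added.
#' @export
classify_intervals <- function(intervals, intensity, zcr, thresholds) {
  if (nrow(intervals) == 0) abort("classify_intervals: no intervals")
  dplyr::mutate(
    intervals,
    mean_intensity = purrr::map2_dbl(
      .data$start_frame, .data$end_frame,
      ~ mean(intensity[.x:.y])
    ),
    mean_zcr = purrr::map2_dbl(
      .data$start_frame, .data$end_frame,
      ~ mean(zcr[.x:.y])
    ),
    new_index = as.integer(
      .data$mean_intensity >= thresholds$INT_BKG |
        .data$mean_zcr >= thresholds$ZC_BKG
    )
  )
}

#' Merge initial class labels with interval activity indexes
#'
#' Each frame's composite label is its initial class concatenated with
#' the activity index of the interval containing it (e.g. `EXP1`, `NOR0`).
#'
#' @param initial_labels per-frame class labels.
#' @param intervals tibble with `start_frame`, `end_frame`, `new_index`.
#' @return Character vector of composite labels, one per frame.
#' @export
merge_with_initial <- function(initial_labels, intervals) {
  n <- length(initial_labels)
  idx <- rep(NA_integer_, n)
  for (i in seq_len(nrow(intervals))) {
    idx[intervals$start_frame[i]:intervals$end_frame[i]] <-
      intervals$new_index[i]
  }
  if (anyNA(idx)) {
    abort(sprintf("merge_with_initial: frame %d outside all intervals",
                  which(is.na(idx))[1]))
  }
  paste0(initial_labels, idx)
}

#' Default relabeling rule set for the final decision
#'
#' F0 bands (Hz) used to rescue voiced activity that the initial
#' classifier called `NOR` or `BKG`: runs whose mean F0 falls in the
#' expiratory band become `EXP` (precedence), in the inspiratory band
#' `INS`. Two guards temper the rescue. Runs whose F0 spread
#' (`f0_max - f0_min`) stays below `min_f0_range_hz` are never rescued:
#' a flat fundamental is the signature of a machine beep, whereas cry
#' phonation carries a moving contour. Runs whose mean F0 falls in the
#' adult speech pitch band stay `NOR` unless they carry the cry
#' intensity profile, i.e. their mean intensity reaches within
#' `speech_margin_db` of the recording's own confident cry runs
#' (`EXP1`/`INS1`); the crying newborn is the closest, loudest source,
#' so background speech sits well below that reference.
#'
#' @param exp_band,ins_band two-element numeric ranges in Hz.
#' @param min_f0_range_hz minimum F0 spread for a rescue (default 20).
#' @param speech_band adult speech pitch range in Hz (default 100-300).
#' @param speech_margin_db how far below the cry intensity reference a
#'   speech-band run may sit and still be rescued (default 6).
#' @return Named list with the bands and guards.
#' @export
relabel_rules <- function(exp_band = c(250, 1000), ins_band = c(100, 800),
                          min_f0_range_hz = 20, speech_band = c(100, 300),
                          speech_margin_db = 6) {
  list(exp_band = exp_band, ins_band = ins_band,
       min_f0_range_hz = min_f0_range_hz, speech_band = speech_band,
       speech_margin_db = speech_margin_db)
}

#' Final decision on composite runs
#'
#' Maximal runs of equal composite labels become candidate utterances.
#' Mean intensity and F0 statistics (min/max/mean over voiced frames) are
#' attached to each run, then the default rule table is applied: inactive
#' runs (`*0`) become `BKG`; `EXP1` and `INS1` keep their class; `NOR1`
#' and `BKG1` runs are relabeled `EXP` or `INS` when their mean F0 falls
#' in the corresponding band (flat-F0 runs are marked `NOR` as machine
#' beeps, runs without any voiced frame keep the classifier's class),
#' else `NOR`. Adjacent runs with equal final labels are merged and
#' converted to seconds.
#'
#' @param composite per-frame composite labels from [merge_with_initial()].
#' @param intensity per-frame intensity (dB).
#' @param f0 an `f0_track` at the same frame rate.
#' @param thresholds a `threshold_set` (carried for inspection).
#' @param rules a [relabel_rules()] list.
#' @param frame_len_s,hop_s framing parameters for the time conversion.
#' @param total_s optional recording duration in seconds.
#' @return A [label_track()] over `EXP`, `INS`, `BKG`, `NOR`.
#' @export
finalize_labels <- function(composite, intensity, f0, thresholds,
                            rules = relabel_rules(),
                            frame_len_s = 0.030, hop_s = 0.009,
                            total_s = NULL) {
  n <- length(composite)
  r <- rle(composite)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  in_band <- function(x, band) !is.na(x) && x >= band[1] && x <= band[2]
  # intensity reference from the runs the classifier already calls cry
  cry_frames <- which(rep(r$values %in% c("EXP1", "INS1"), r$lengths))
  cry_ref <- if (length(cry_frames)) mean(intensity[cry_frames]) else NA_real_
  final <- character(length(starts))
  for (i in seq_along(starts)) {
    lab <- r$values[i]
    cls <- sub("[01]$", "", lab)
    active <- grepl("1$", lab)
    if (!active) {
      final[i] <- "BKG"
    } else if (cls %in% c("EXP", "INS")) {
      final[i] <- cls
    } else {
      st <- f0_stats(f0, frames = starts[i]:ends[i])
      run_int <- mean(intensity[starts[i]:ends[i]])
      speech_like <- in_band(st$f0_mean, rules$speech_band) &&
        (is.na(cry_ref) || run_int < cry_ref - rules$speech_margin_db)
      if (st$n_voiced == 0) {
        # no F0 evidence to overturn the classifier: keep its class
        final[i] <- cls
      } else if ((st$f0_max - st$f0_min) < rules$min_f0_range_hz) {
        final[i] <- "NOR" # beep-like constant fundamental
      } else if (in_band(st$f0_mean, rules$exp_band)) {
        final[i] <- "EXP"
      } else if (speech_like) {
        final[i] <- "NOR" # speech pitch without the cry intensity profile
      } else if (in_band(st$f0_mean, rules$ins_band)) {
        final[i] <- "INS"
      } else {
        final[i] <- "NOR"
      }
    }
  }
  per_frame <- rep(final, r$lengths)
  frame_labels_to_track(per_frame, frame_len_s, hop_s, total_s)
}

#' Refine an initial labelling against the audio
#'
#' Orchestrates the full post-processing stage: side features (intensity,
#' ZCR, F0) on the raw signal, dynamic thresholds from the
#' initially-labelled background, voicing/transition/minima marking,
#' interval construction and activity indexing, composite merging and the
#' final relabeling decision.
#'
#' @param initial_labels per-frame class labels over [CLASS_LABELS].
#' @param rec a mono [audio_recording()].
#' @param frame_len_s,overlap_s analysis grid (defaults 0.030 / 0.021).
#' @param fmin_hz,fmax_hz,voicing_threshold F0 parameters, see
#'   [f0_autocorr()].
#' @param silence_span_ms,linear_energy see [compute_thresholds()].
#' @param rules see [relabel_rules()].
#' @param smooth_minima median-smooth intensity before minima detection.
#' @param tables if `TRUE`, attach the intermediate frame/interval tables
#'   (attributes `frame_table`, `interval_table`, `thresholds`).
#' @return A [label_track()] over the four classes.
#' @export
refine <- function(initial_labels, rec, frame_len_s = 0.030,
                   overlap_s = 0.021, fmin_hz = 75, fmax_hz = 1000,
                   voicing_threshold = 0.45, silence_span_ms = 250,
                   linear_energy = TRUE, rules = relabel_rules(),
                   smooth_minima = FALSE, tables = FALSE) {
  rec <- to_mono(rec)
  fm <- frame_signal(rec, frame_len_s, overlap_s)
  if (length(initial_labels) != n_frames(fm)) {
    abort(sprintf("refine: %d labels for %d frames",
                  length(initial_labels), n_frames(fm)))
  }
  intensity <- frame_intensity(fm)
  zcr <- frame_zcr(fm)
  f0 <- f0_autocorr(fm, fmin_hz, fmax_hz, voicing_threshold)
  hop_s <- frame_hop_s(fm)
  thr <- compute_thresholds(intensity, zcr, initial_labels,
                            silence_span_ms = silence_span_ms,
                            hop_s = hop_s, linear_energy = linear_energy)
  voicing <- voicing_index(f0)
  transitions <- mark_transitions(voicing)
  minima <- mark_intensity_minima(intensity, smooth = smooth_minima)
  combined <- combine_indices(voicing, transitions, minima)
  intervals <- classify_intervals(build_intervals(combined),
                                  intensity, zcr, thr)
  composite <- merge_with_initial(initial_labels, intervals)
  out <- finalize_labels(composite, intensity, f0, thr, rules = rules,
                         frame_len_s = frame_len_s, hop_s = hop_s,
                         total_s = duration_s(rec))
  if (tables) {
    attr(out, "frame_table") <- tibble::tibble(
      frame = seq_along(voicing),
      initial_label = initial_labels,
      voicing = voicing,
      transition_mark = transitions,
      minima_mark = minima,
      combined = combined,
      composite = composite,
      intensity = intensity,
      zcr = zcr
    )
    attr(out, "interval_table") <- intervals
    attr(out, "thresholds") <- thr
  }
  out
}
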