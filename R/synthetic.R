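#' Synthetic cry scenes
#'
#' Seeded source-filter style generator emulating the acoustic classes of
#' a clinical cry corpus: harmonic expiratory cries with a falling F0
#' contour, short vocalized inspirations in a lower F0 band, adult speech
#' with syllabic amplitude modulation in the 100-300 Hz pitch range,
#' constant-frequency machine beeps, low-level white background noise and
#' broadband noise bursts. Every generated scene carries an exact ground
#' truth label track, so all pipeline stages are testable without a
#' clinical corpus.
#'
#' @name synthetic
NULL

# additive harmonic source with 1/h spectral rolloff, pitch jitter and
# amplitude shimmer; returns samples in [-1, 1] * amplitude
harmonic_source <- function(n, rate, f0_start, f0_end, amplitude = 0.5,
                            jitter = 0.01, shimmer = 0.05, n_harmonics = 12) {
  f0 <- seq(f0_start, f0_end, length.out = n)
  if (jitter > 0) {
    wob <- stats::filter(rnorm(n, 0, jitter), rep(1 / 50, 50), sides = 2)
    wob[is.na(wob)] <- 0
    f0 <- f0 * (1 + as.numeric(wob) * sqrt(50))
  }
  phase <- 2 * pi * cumsum(f0) / rate
  n_h <- max(1, min(n_harmonics, floor(rate / 2 / max(f0)) - 1))
  x <- numeric(n)
  for (h in seq_len(n_h)) x <- x + sin(h * phase) / h
  if (shimmer > 0) {
    am <- stats::filter(rnorm(n, 0, shimmer), rep(1 / 200, 200), sides = 2)
    am[is.na(am)] <- 0
    x <- x * (1 + as.numeric(am) * sqrt(200))
  }
  amplitude * x / max(abs(x))
}

# raised-cosine attack/decay envelope
ad_envelope <- function(n, attack = 0.1, decay = 0.15) {
  na <- max(1, round(attack * n)); nd <- max(1, round(decay * n))
  env <- rep(1, n)
  env[seq_len(na)] <- (1 - cos(pi * seq_len(na) / na)) / 2
  env[(n - nd + 1):n] <- (1 + cos(pi * seq_len(nd) / nd)) / 2
  env
}

#' Synthesize one acoustic event
#'
#' @param class one of `EXP`, `INSV`, `SP`, `BIP`, `BKG`, `NOR`.
#' @param duration_s event duration in seconds.
#' @param sample_rate_hz sampling rate (default 16000).
#' @param f0_start,f0_end fundamental-frequency contour endpoints in Hz;
#'   class-specific defaults are used when `NULL` (`EXP` 500 -> 380,
#'   `INSV` 200 -> 170, `SP` 180 -> 140, `BIP` constant 1000).
#' @param amplitude peak amplitude (class defaults when `NULL`).
#' @param jitter,shimmer fractional pitch / amplitude perturbations.
#' @param noise_snr_db SNR of additive white noise over the event
#'   (default 30; ignored for the noise classes).
#' @param seed optional integer seed.
#' @return Numeric sample vector.
#' @export
synth_event <- function(class, duration_s, sample_rate_hz = 16000,
                        f0_start = NULL, f0_end = NULL, amplitude = NULL,
                        jitter = 0.01, shimmer = 0.05, noise_snr_db = 30,
                        seed = NULL) {
  n <- max(2L, round(duration_s * sample_rate_hz))
  with_local_seed(seed, {
    x <- switch(class,
      EXP = {
        f0a <- f0_start %||% 500; f0b <- f0_end %||% 380
        a <- amplitude %||% 0.6
        harmonic_source(n, sample_rate_hz, f0a, f0b, a, jitter, shimmer) *
          ad_envelope(n)
      },
      INSV = {
        f0a <- f0_start %||% 200; f0b <- f0_end %||% 170
        a <- amplitude %||% 0.35
        harmonic_source(n, sample_rate_hz, f0a, f0b, a, jitter, shimmer,
                        n_harmonics = 8) * ad_envelope(n, 0.2, 0.2)
      },
      SP = {
        f0a <- f0_start %||% 180; f0b <- f0_end %||% 140
        a <- amplitude %||% 0.3
        syllabic <- 0.55 + 0.45 *
          sin(2 * pi * 4 * seq_len(n) / sample_rate_hz)
        harmonic_source(n, sample_rate_hz, f0a, f0b, a, jitter,
                        shimmer, n_harmonics = 10) * syllabic
      },
      BIP = {
        f <- f0_start %||% 1000
        a <- amplitude %||% 0.25
        a * sin(2 * pi * f * seq_len(n) / sample_rate_hz)
      },
      BKG = {
        a <- amplitude %||% 0.003
        rnorm(n, 0, a)
      },
      NOR = {
        a <- amplitude %||% 0.25
        bursts <- rep(c(1, 0.15), length.out = 8)
        env <- rep(bursts, each = ceiling(n / 8))[seq_len(n)]
        rnorm(n, 0, a / 3) * env
      },
      abort(paste0("synth_event: unknown class ", class))
    )
    if (!class %in% c("BKG", "NOR")) {
      sig_pow <- mean(x^2)
      noise_sd <- sqrt(sig_pow / 10^(noise_snr_db / 10))
      x <- x + rnorm(n, 0, noise_sd)
    }
    x
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a scene specification
#'
#' @param events tibble (or data frame) with columns `class` and
#'   `duration_s`, optionally `f0_start`, `f0_end`, `amplitude`,
#'   `jitter`, `shimmer`, `noise_snr_db`.
#' @param sample_rate_hz sampling rate (default 16000).
#' @param seed scene seed; identical (spec, seed) gives identical audio.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(events, sample_rate_hz = 16000, seed = 1L) {
  events <- tibble::as_tibble(events)
  stopifnot(all(c("class", "duration_s") %in% names(events)))
  if (any(events$duration_s <= 0)) abort("scene_spec: durations must be > 0")
  structure(list(events = events, sample_rate_hz = sample_rate_hz,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render a scene into audio and its ground-truth labels
#'
#' Events are synthesized with per-event sub-seeds derived from the scene
#' seed and concatenated; label boundaries match event boundaries exactly
#' (after snapping durations to whole samples).
#'
#' @param spec a [scene_spec()].
#' @return List with `audio` (an [audio_recording()]) and `labels`
#'   (a [label_track()]).
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  ev <- spec$events
  rate <- spec$sample_rate_hz
  n_ev <- nrow(ev)
  opt <- function(col, i) {
    if (col %in% names(ev) && !is.na(ev[[col]][i])) ev[[col]][i] else NULL
  }
  chunks <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    chunks[[i]] <- synth_event(
      class = ev$class[i],
      duration_s = ev$duration_s[i],
      sample_rate_hz = rate,
      f0_start = opt("f0_start", i), f0_end = opt("f0_end", i),
      amplitude = opt("amplitude", i),
      jitter = opt("jitter", i) %||% 0.01,
      shimmer = opt("shimmer", i) %||% 0.05,
      noise_snr_db = opt("noise_snr_db", i) %||% 30,
      seed = spec$seed * 1000L + i
    )
  }
  ns <- vapply(chunks, length, 0L)
  ends <- cumsum(ns) / rate
  starts <- c(0, head(ends, -1))
  list(
    audio = audio_recording(unlist(chunks), rate),
    labels = label_track(starts, ends, ev$class)
  )
}

#' Compose a random cry scene
#'
#' Draws a plausible clinical recording: background silence interleaved
#' with 2-4 cry cycles (expiration, optional vocalized inspiration) and
#' occasional speech, beep or noise interference. Durations: expirations
#' 0.5-1.2 s, inspirations 0.2-0.5 s, background gaps 0.4-1.0 s.
#'
#' @param seed scene seed.
#' @param sample_rate_hz sampling rate (default 16000).
#' @param p_interference probability of inserting an interference event
#'   after each cycle (default 0.4).
#' @return A `scene_spec`.
#' @export
random_scene_spec <- function(seed, sample_rate_hz = 16000,
                              p_interference = 0.4) {
  with_local_seed(seed, {
    rows <- list(tibble::tibble(class = "BKG",
                                duration_s = runif(1, 0.4, 1.0)))
    n_cycles <- sample(2:4, 1)
    for (i in seq_len(n_cycles)) {
      f0a <- runif(1, 380, 650)
      rows <- c(rows, list(tibble::tibble(
        class = "EXP", duration_s = runif(1, 0.5, 1.2),
        f0_start = f0a, f0_end = f0a - runif(1, 50, 150)
      )))
      if (runif(1) < 0.7) {
        rows <- c(rows, list(tibble::tibble(
          class = "INSV", duration_s = runif(1, 0.2, 0.5),
          f0_start = runif(1, 160, 230), f0_end = runif(1, 140, 200)
        )))
      }
      rows <- c(rows, list(tibble::tibble(
        class = "BKG", duration_s = runif(1, 0.4, 1.0)
      )))
      if (runif(1) < p_interference) {
        cls <- sample(c("SP", "BIP", "NOR"), 1)
        rows <- c(rows, list(tibble::tibble(
          class = cls, duration_s = runif(1, 0.4, 0.9),
          f0_start = if (cls == "BIP") runif(1, 800, 1500) else NA_real_
        )), list(tibble::tibble(class = "BKG",
                                duration_s = runif(1, 0.3, 0.8))))
      }
    }
    scene_spec(dplyr::bind_rows(rows), sample_rate_hz, seed)
  })
}

#' Generate a reproducible training corpus on disk
#'
#' Renders `n_scenes` random scenes and writes each as a WAV plus a
#' tab-separated label file.
#'
#' @param n_scenes number of scenes.
#' @param seed base seed; scene `i` uses `seed * 100 + i`.
#' @param dir output directory (created if needed).
#' @param sample_rate_hz sampling rate (default 16000).
#' @return Tibble with columns `id`, `wav`, `labels`.
#' @export
make_training_corpus <- function(n_scenes, seed = 1L,
                                 dir = tempfile("cry_corpus_"),
                                 sample_rate_hz = 16000) {
  if (n_scenes < 1) abort("make_training_corpus: n_scenes must be >= 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::map_dfr(seq_len(n_scenes), function(i) {
    sc <- render_scene(random_scene_spec(seed * 100L + i, sample_rate_hz))
    wav <- file.path(dir, sprintf("scene_%03d.wav", i))
    lab <- file.path(dir, sprintf("scene_%03d.lab", i))
    write_wav(sc$audio, wav)
    write_labels(sc$labels, lab)
    tibble::tibble(id = sprintf("scene_%03d", i), wav = wav, labels = lab)
  })
}
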