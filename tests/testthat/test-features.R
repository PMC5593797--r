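test_that("frame intensity matches the literal windowed-energy formula", {
  set.seed(31)
  rec <- audio_recording(rnorm(400, sd = 0.3), 1000)
  fm <- frame_signal(rec, 0.030, 0.021)
  got <- frame_intensity(fm)
  w <- hamming_window(30)
  oracle <- apply(fm$frames, 1, function(s) 10 * log10(sum(s^2 * w) + 1e-10))
  expect_equal(got, oracle)
  # scaling law: doubling amplitudes raises intensity by 10 log10(4)
  fm2 <- fm; fm2$frames <- 2 * fm$frames
  expect_equal(frame_intensity(fm2, eps = 0) - frame_intensity(fm, eps = 0),
               rep(10 * log10(4), nrow(fm$frames)))
  # an all-zero frame sits at the floor
  fm0 <- frame_signal(audio_recording(rep(0, 100), 1000), 0.030, 0.021)
  expect_equal(frame_intensity(fm0), rep(10 * log10(1e-10), nrow(fm0$frames)))
})

test_that("zero-crossing counts equal an independent sign-change scan", {
  pos <- frame_signal(audio_recording(rep(0.5, 100), 1000), 0.030, 0.021)
  expect_equal(frame_zcr(pos), rep(0, nrow(pos$frames)))
  alt <- frame_signal(audio_recording(rep(c(1, -1), 50) * 0.5, 1000),
                      0.030, 0.021)
  expect_equal(frame_zcr(alt), rep(29, nrow(alt$frames)))
  # 100 Hz sine framed at 8 kHz / 30 ms: about 2 f T crossings per frame
  t <- seq(0, 0.5, by = 1 / 8000)
  sine <- audio_recording(sin(2 * pi * 100 * t), 8000)
  fm <- frame_signal(sine, 0.030, 0.021)
  got <- frame_zcr(fm)
  oracle <- apply(fm$frames, 1, function(x) {
    s <- x >= 0
    sum(s[-1] != s[-length(s)])
  })
  expect_equal(got, oracle)
  expect_true(all(abs(got - 6) <= 1))
})

test_that("autocorrelation pitch tracking recovers pure tones and rejects noise", {
  rate <- 16000
  t <- seq(0, 0.5, by = 1 / rate)
  sine <- audio_recording(0.8 * sin(2 * pi * 440 * t), rate)
  fm <- frame_signal(sine)
  tr <- f0_autocorr(fm)
  expect_true(all(tr$voiced))
  # within one lag quantum of 440 Hz
  lag_true <- rate / 440
  expect_true(all(abs(rate / tr$f0_hz - lag_true) <= 1))
  st <- f0_stats(tr)
  expect_true(st$f0_mean >= st$f0_min && st$f0_mean <= st$f0_max)

  set.seed(41)
  noise <- audio_recording(rnorm(8000, sd = 0.3), rate)
  trn <- f0_autocorr(frame_signal(noise))
  expect_lt(mean(trn$voiced), 0.05)

  silent <- audio_recording(rep(0, 2000), rate)
  trs <- f0_autocorr(frame_signal(silent))
  expect_false(any(trs$voiced))
})

test_that("pitch tracking follows a programmed harmonic sweep", {
  rate <- 16000
  n <- rate # 1 s
  f0 <- seq(300, 500, length.out = n)
  phase <- 2 * pi * cumsum(f0) / rate
  x <- audio_recording(0.7 * (sin(phase) + 0.5 * sin(2 * phase)), rate)
  fm <- frame_signal(x)
  tr <- f0_autocorr(fm)
  centre <- (tr$frame - 1) * 0.009 + 0.015
  truth <- 300 + 200 * pmin(centre, 1)
  v <- tr$voiced
  expect_gt(mean(v), 0.9)
  # at least 95% of voiced frames within one lag quantum of the contour
  lag_err <- abs(rate / tr$f0_hz[v] - rate / truth[v])
  expect_gt(mean(lag_err <= 1), 0.95)
})

test_that("the mel scale maps the printed anchor points monotonically", {
  expect_equal(mel_scale(0), 0)
  expect_equal(mel_scale(700), 2595 * log10(2))
  expect_equal(round(mel_scale(700), 2), 781.17)
  f <- seq(0, 8000, by = 50)
  expect_true(all(diff(mel_scale(f)) > 0))
  expect_error(mel_scale(-1), "negative")
  expect_equal(mel_to_hz(mel_scale(1234)), 1234)
})

test_that("cepstra equal a brute-force evaluation of the printed steps", {
  set.seed(51)
  rate <- 8000
  rec <- audio_recording(c(rnorm(400, sd = 0.2),
                           sin(2 * pi * 350 * seq_len(400) / rate),
                           c(1, rep(0, 399))), rate)
  fm <- apply_hamming(frame_signal(rec, 0.030, 0.021))
  got <- mfcc_fft(fm, n_filters = 20, n_cepstra = 12)
  # literal per-frame pipeline: FFT -> power -> mel filterbank -> log -> DCT
  flen <- fm$frame_len_samples
  nfft <- 2^ceiling(log2(flen))
  fb <- cryseg:::mel_filterbank(20, nfft, rate)
  for (i in c(1, 7, nrow(fm$frames))) {
    spec <- Mod(fft(c(fm$frames[i, ], rep(0, nfft - flen))))^2
    S <- pmax(as.numeric(fb %*% spec[1:(nfft / 2 + 1)]), 1e-12)
    cn <- vapply(1:12, function(n) {
      sum(log(S) * cos(n * (seq_len(20) - 0.5) * pi / 20))
    }, 0)
    expect_equal(unname(got[i, 1:12]), cn, tolerance = 1e-8)
    expect_equal(unname(got[i, "logE"]), log(sum(fm$frames[i, ]^2) + 1e-12))
  }
  # determinism: identical frames give identical rows
  fm2 <- fm; fm2$frames <- fm$frames[c(1, 1), ]
  rows <- mfcc_fft(fm2, n_filters = 20)
  expect_equal(rows[1, ], rows[2, ])
})

test_that("frame gain moves only the energy term, never c1..cK", {
  set.seed(52)
  rec <- audio_recording(rnorm(600, sd = 0.1), 8000)
  fm <- apply_hamming(frame_signal(rec))
  a <- mfcc_fft(fm)
  fm_g <- fm; fm_g$frames <- 3 * fm$frames
  b <- mfcc_fft(fm_g)
  expect_equal(a[, 1:12], b[, 1:12], tolerance = 1e-9)
  expect_true(all(b[, "logE"] > a[, "logE"]))
})

test_that("delta stacking triples the dimension and matches the regression form", {
  const <- matrix(1, 10, 3)
  out <- add_deltas(const, window = 2)
  expect_equal(ncol(out), 9)
  expect_true(all(out[, 4:9] == 0))
  # 13 static dims in, 39 out
  expect_equal(ncol(add_deltas(matrix(rnorm(130), 10, 13))), 39)
  # linear ramp: interior deltas equal the slope, accelerations vanish
  a <- 0.7
  ramp <- matrix(a * (1:20), ncol = 1)
  d <- add_deltas(ramp, window = 2)
  expect_equal(d[3:18, 2], rep(a, 16))
  expect_equal(d[5:16, 3], rep(0, 12))
  expect_error(add_deltas(matrix(1, 3, 2), window = 2), "frames")
})
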