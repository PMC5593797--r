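test_that("dynamic thresholds follow the printed worked values", {
  # Imean = 10, Imax = 110 -> I1 = 13, I2 = 40, ITL = 13, INT_BKG = 65
  n_sil <- 28 # 250 ms of 9 ms hops
  intensity <- c(rep(10, n_sil), 110, rep(30, 10))
  zcr <- rep(5, length(intensity))
  labels <- c(rep("BKG", n_sil), rep("EXP", 11))
  thr <- compute_thresholds(intensity, zcr, labels, linear_energy = FALSE)
  expect_equal(thr$Imean, 10)
  expect_equal(thr$Imax, 110)
  expect_equal(thr$I1, 13)
  expect_equal(thr$I2, 40)
  expect_equal(thr$ITL, 13)
  expect_equal(thr$INT_BKG, 65)
  # constant silence ZCR: sd = 0, so ZC_BKG = mean
  expect_equal(thr$ZC_BKG, 5)
  expect_equal(thr$source, "initial-BKG")
})

test_that("threshold intermediates satisfy their algebra on random vectors", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(30:120, 1)
    intensity <- rnorm(n, -20, 15)
    zcr <- rpois(n, 40)
    labels <- sample(c("BKG", "EXP", "NOR"), n, replace = TRUE)
    thr <- compute_thresholds(intensity, zcr, labels, linear_energy = FALSE)
    expect_equal(thr$ITL, min(thr$I1, thr$I2))
    expect_equal(thr$INT_BKG, 5 * thr$ITL)
    expect_equal(thr$I2, 4 * thr$Imean)
    expect_equal(thr$Imax, max(intensity))
  }
})

test_that("the silence fallback picks the quietest window when no BKG exists", {
  intensity <- c(rep(20, 10), rep(-40, 30), rep(15, 10))
  zcr <- rep(3, 50)
  thr <- compute_thresholds(intensity, zcr, rep("EXP", 50))
  expect_equal(thr$source, "min-intensity-window")
  expect_equal(thr$Imean, -40, tolerance = 1e-9)
  expect_warning(
    compute_thresholds(rep(0, 5), rep(1, 5), NULL),
    "shorter"
  )
})

test_that("energy-domain thresholds sit usably above the silence floor", {
  # silence at -30 dB, activity up to +15 dB
  intensity <- c(rep(-30, 28), rep(15, 20))
  zcr <- rep(50, 48)
  labels <- c(rep("BKG", 28), rep("EXP", 20))
  thr <- compute_thresholds(intensity, zcr, labels) # linear_energy default
  expect_gt(thr$INT_BKG, -30) # above silence
  expect_lt(thr$INT_BKG, 15)  # below the cry
  expect_equal(thr$INT_BKG, -30 + 10 * log10(20), tolerance = 1e-6)
})

test_that("voicing indexing flags frames with a fundamental", {
  tr <- tibble::tibble(frame = 1:4, f0_hz = c(400, NA, 380, NA),
                       voiced = c(TRUE, FALSE, TRUE, FALSE),
                       peak = c(0.9, 0.1, 0.8, 0.2))
  class(tr) <- c("f0_track", class(tr))
  expect_equal(voicing_index(tr), c(1L, 0L, 1L, 0L))
  expect_equal(voicing_index(rep(1, 5) + 0), rep(1L, 5))
  expect_error(voicing_index(numeric()), "empty")
})

test_that("transition marks sit on the last frame of each voicing run", {
  v <- worked_voicing()
  marks <- mark_transitions(v)
  expect_equal(which(!is.na(marks)), c(5, 9, 13))
  expect_true(all(marks[c(5, 9, 13)] == 2))
  expect_true(all(is.na(mark_transitions(rep(1, 10)))))
  expect_equal(which(!is.na(mark_transitions(c(1, 0, 1, 0)))), 1:3)
})

test_that("intensity minima marking matches the worked contour", {
  marks <- mark_intensity_minima(worked_intensity())
  expect_equal(which(!is.na(marks)), c(1, 7, 11, 13))
  expect_equal(which(!is.na(mark_intensity_minima(1:10))), 1)
  expect_equal(which(!is.na(mark_intensity_minima(c(5, 3, 5)))), 2)
  expect_error(mark_intensity_minima(c(1, 2)), "3 frames")
})

test_that("index combination reproduces the printed 16-frame column", {
  v <- worked_voicing()
  combined <- combine_indices(v, mark_transitions(v),
                              mark_intensity_minima(worked_intensity()))
  expect_equal(combined, worked_combined())
  # no marks anywhere: combined = voicing except the closing frame
  no_marks <- rep(NA_integer_, 6)
  expect_equal(combine_indices(c(1, 1, 0, 0, 1, 1), no_marks, no_marks),
               c(1L, 1L, 0L, 0L, 1L, 2L))
  all_marks <- rep(2L, 6)
  expect_equal(combine_indices(rep(0, 6), all_marks, all_marks), rep(2L, 6))
})

test_that("interval construction reproduces the printed six spans", {
  iv <- build_intervals(worked_combined())
  expect_equal(iv$start_frame, c(1, 6, 8, 10, 12, 14))
  expect_equal(iv$end_frame, c(5, 7, 9, 11, 13, 16))
  # a single trailing boundary spans everything
  expect_equal(build_intervals(c(0, 1, 0, 2)),
               tibble::tibble(start_frame = 1L, end_frame = 4L))
  # all boundaries: a leading 2 opens the first interval, the rest close
  iv2 <- build_intervals(rep(2L, 4))
  expect_equal(iv2$start_frame, c(1, 3, 4))
  expect_equal(iv2$end_frame, c(2, 3, 4))
  expect_error(build_intervals(c(2, 1, 0)), "boundary")
})

test_that("interval activity applies the OR of the two threshold tests", {
  thr <- tibble::tibble(ZC_BKG = 10, INT_BKG = 0)
  iv <- tibble::tibble(start_frame = c(1L, 4L, 7L), end_frame = c(3L, 6L, 9L))
  intensity <- c(5, 5, 5, -20, -20, -20, -20, -20, -20)
  zcr <- c(2, 2, 2, 2, 2, 2, 15, 15, 15)
  out <- classify_intervals(iv, intensity, zcr, thr)
  expect_equal(out$new_index, c(1L, 0L, 1L)) # intensity / neither / zcr
  expect_equal(out$mean_intensity, c(5, -20, -20))
  expect_equal(out$mean_zcr, c(2, 2, 15))
})

test_that("composite merging reproduces the printed combination column", {
  initial <- c(rep("BKG", 5), rep("EXP", 4), rep("INS", 4), rep("NOR", 3))
  iv <- build_intervals(worked_combined())
  iv$new_index <- c(0L, 0L, 1L, 1L, 0L, 1L)
  got <- merge_with_initial(initial, iv)
  expect_equal(got, c(rep("BKG0", 5), "EXP0", "EXP0", "EXP1", "EXP1",
                      "INS1", "INS1", "INS0", "INS0",
                      "NOR1", "NOR1", "NOR1"))
  # uniform label + uniform index
  iv1 <- tibble::tibble(start_frame = 1L, end_frame = 4L, new_index = 1L)
  expect_equal(merge_with_initial(rep("EXP", 4), iv1), rep("EXP1", 4))
  iv_gap <- tibble::tibble(start_frame = 1L, end_frame = 2L, new_index = 0L)
  expect_error(merge_with_initial(rep("EXP", 4), iv_gap), "outside")
})

test_that("the final decision relabels runs by activity and F0 band", {
  f0_of <- function(vals) {
    tr <- tibble::tibble(frame = seq_along(vals), f0_hz = vals,
                         voiced = !is.na(vals),
                         peak = ifelse(is.na(vals), 0.1, 0.9))
    class(tr) <- c("f0_track", class(tr))
    tr
  }
  thr <- tibble::tibble(ZC_BKG = 10, INT_BKG = 0)
  # inactive runs collapse to background
  out <- finalize_labels(rep("EXP0", 20), rep(-30, 20), f0_of(rep(NA, 20)),
                         thr)
  expect_equal(out$label, "BKG")
  expect_equal(nrow(out), 1)
  # voiced NOR1 run inside the expiratory band is rescued
  f0 <- f0_of(c(rep(NA, 5), seq(380, 450, length.out = 10), rep(NA, 5)))
  comp <- c(rep("BKG0", 5), rep("NOR1", 10), rep("BKG0", 5))
  out2 <- finalize_labels(comp, rep(0, 20), f0, thr)
  expect_equal(out2$label, c("BKG", "EXP", "BKG"))
  # a flat fundamental (machine beep) is never rescued
  f0_flat <- f0_of(c(rep(NA, 5), rep(400, 10), rep(NA, 5)))
  out3 <- finalize_labels(comp, rep(0, 20), f0_flat, thr)
  expect_equal(out3$label, c("BKG", "NOR", "BKG"))
  # inspiratory band rescue: loud voiced run next to a confident cry run
  comp2 <- c(rep("EXP1", 5), rep("NOR1", 10), rep("BKG0", 5))
  f0_low <- f0_of(c(seq(400, 450, length.out = 5),
                    seq(150, 220, length.out = 10), rep(NA, 5)))
  out4 <- finalize_labels(comp2, rep(0, 20), f0_low, thr)
  expect_equal(out4$label, c("EXP", "INS", "BKG"))
  # the same run well below the cry intensity is speech, stays NOR
  quiet <- c(rep(0, 5), rep(-12, 10), rep(-30, 5))
  out5 <- finalize_labels(comp2, quiet, f0_low, thr)
  expect_equal(out5$label, c("EXP", "NOR", "BKG"))
})

test_that("refinement tightens expiratory boundaries on a clean scene", {
  spec <- scene_spec(tibble::tibble(
    class = c("BKG", "EXP", "BKG"),
    duration_s = c(0.8, 1.0, 0.8),
    f0_start = c(NA, 500, NA), f0_end = c(NA, 400, NA)
  ), sample_rate_hz = 8000, seed = 17)
  sc <- render_scene(spec)
  fm <- frame_signal(to_mono(sc$audio))
  nf <- nrow(fm$frames)
  ref <- scene_reference(sc, nf)
  # corrupt: pad the EXP run 12 frames into the silence on both sides
  run <- range(which(ref == "EXP"))
  init <- ref
  init[max(1, run[1] - 12):min(nf, run[2] + 12)] <- "EXP"
  out <- refine(init, sc$audio)
  hyp <- track_to_frame_labels(out, nf, 0.030, 0.009)
  got <- range(which(hyp == "EXP"))
  # boundaries pulled back to within a few hops of the truth
  expect_lte(abs(got[1] - run[1]), 4)
  expect_lte(abs(got[2] - run[2]), 4)
})

test_that("refinement is near-idempotent on clean labels and inert on noise", {
  sc <- render_scene(random_scene_spec(123, 8000))
  fm <- frame_signal(to_mono(sc$audio))
  nf <- nrow(fm$frames)
  ref <- scene_reference(sc, nf)
  out <- refine(ref, sc$audio)
  hyp <- track_to_frame_labels(out, nf, 0.030, 0.009)
  expect_gt(mean(hyp == ref), 0.9)
  validate_ok <- tryCatch({
    cryseg:::validate_label_track(out, validate_vocabulary = FALSE)
    TRUE
  }, error = function(e) FALSE)
  expect_true(validate_ok)
  # pure noise: no cry classes emitted
  noise <- audio_recording(rnorm(8000 * 2, sd = 0.002), 8000)
  nf2 <- nrow(frame_signal(noise)$frames)
  out2 <- refine(rep("BKG", nf2), noise)
  expect_false(any(out2$label %in% c("EXP", "INS")))
  # the refined track partitions the recording
  expect_equal(out2$start_s[1], 0)
  expect_gte(max(out2$end_s), 2 - 1e-9)
})
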