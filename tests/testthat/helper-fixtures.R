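# Shared fixtures, built in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

# the worked 16-frame indexing example: voicing runs 1-5, 10-13 voiced,
# and an intensity contour whose local minima sit exactly at 1, 7, 11, 13
worked_voicing <- function() c(1, 1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0)

worked_intensity <- function() {
  c(1, 3, 4, 5, 6, 4, 2, 5, 6, 4, 1, 3, 0, 2, 4, 6)
}

worked_combined <- function() {
  c(2, 1, 1, 1, 2, 0, 2, 0, 2, 1, 2, 1, 2, 0, 0, 2)
}

fixture_corpus <- function() {
  if (is.null(.fixtures$corpus)) {
    dir <- file.path(tempdir(), "cryseg_fixture_corpus")
    .fixtures$corpus <- make_training_corpus(6, seed = 7, dir = dir,
                                             sample_rate_hz = 8000)
  }
  .fixtures$corpus
}

fixture_bank <- function() {
  if (is.null(.fixtures$bank)) {
    feats <- collect_training_features(fixture_corpus(), kind = "gmm")
    .fixtures$bank <- train_classifier_bank(feats, kind = "gmm",
                                            J = 4, seed = 1)
  }
  .fixtures$bank
}

# reference frame labels for a rendered scene at the default grid
scene_reference <- function(scene, n_frames) {
  collapse_to_classes(
    track_to_frame_labels(scene$labels, n_frames, 0.030, 0.009)
  )
}

exp_fpr <- function(reference, hypothesis) {
  cc <- frame_confusion(reference, hypothesis, "EXP")
  100 * cc$FP / (cc$FP + cc$TN)
}
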