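#' Train a bank of per-class models
#'
#' Fits one model per class over `EXP`, `INS`, `BKG`, `NOR`. With
#' `kind = "gmm"` each class gets a Gaussian mixture over its pooled
#' frames (the 40-mixture FFT-MFCC configuration at corpus scale); with
#' `kind = "hmm"` each class gets a left-to-right HMM with
#' Gaussian-mixture emissions (the 4-state configuration, fed EMD-based
#' cepstra).
#'
#' @param training named list: for `"gmm"` a feature matrix per class; for
#'   `"hmm"` a list of per-utterance feature matrices per class. Names
#'   must cover all of [CLASS_LABELS].
#' @param kind `"gmm"` or `"hmm"`.
#' @param recipe feature recipe identifier stored with the bank
#'   (`"fft-mfcc"` or `"emd-mfcc"`).
#' @param J mixture components (per class for `"gmm"`, per state for
#'   `"hmm"`).
#' @param n_states HMM states per class (default 4).
#' @param seed initialization seed.
#' @param ... passed to [gmm_fit_em()] / [hmm_fit_baumwelch()].
#' @return A `classifier_bank`: list with `models` (named), `kind`,
#'   `recipe`, `D`.
#' @export
train_classifier_bank <- function(training, kind = c("gmm", "hmm"),
                                  recipe = c("fft-mfcc", "emd-mfcc"),
                                  J = 8, n_states = 4, seed = 1L, ...) {
  kind <- match.arg(kind)
  recipe <- match.arg(recipe)
  missing_cls <- setdiff(CLASS_LABELS, names(training))
  if (length(missing_cls)) {
    abort(paste0("train_classifier_bank: missing class(es): ",
                 paste(missing_cls, collapse = ", ")))
  }
  models <- lapply(seq_along(CLASS_LABELS), function(i) {
    cls <- CLASS_LABELS[i]
    if (kind == "gmm") {
      X <- as.matrix(training[[cls]])
      gmm_fit_em(X, J = min(J, nrow(X)), seed = seed + i, ...)
    } else {
      hmm_fit_baumwelch(training[[cls]], n_states = n_states, J = J,
                        topology = "left-right", seed = seed + 10 * i, ...)
    }
  })
  names(models) <- CLASS_LABELS
  D <- if (kind == "gmm") models[[1]]$D else models[[1]]$D
  structure(list(models = models, kind = kind, recipe = recipe, D = D),
            class = "classifier_bank")
}

#' @export
print.classifier_bank <- function(x, ...) {
  cat(sprintf("<classifier_bank> kind=%s recipe=%s D=%d classes=%s\n",
              x$kind, x$recipe, x$D, paste(names(x$models), collapse = ",")))
  invisible(x)
}

#' Composite decoding network over the class models
#'
#' Connects the per-class HMMs (a GMM acts as a single-state HMM)
#' ergodically: within-class transitions follow each model's own `A`;
#' from any state the decoder may switch to another class's entry states
#' with uniform inter-class probability, discounted by `exp(-switch_penalty)`
#' in the log domain. Rows are renormalized, so a larger penalty makes
#' class switching rarer and smooths the decoded label sequence.
#'
#' @param bank a `classifier_bank`.
#' @param switch_penalty non-negative log-domain switching penalty
#'   (default 0).
#' @return List with `log_pi`, `log_A`, `state_class` (class label per
#'   composite state), `emissions` (list of `cry_gmm`, one per state).
#' @export
composite_network <- function(bank, switch_penalty = 0) {
  stopifnot(inherits(bank, "classifier_bank"))
  classes <- names(bank$models)
  pieces <- lapply(classes, function(cls) {
    m <- bank$models[[cls]]
    if (bank$kind == "gmm") {
      list(pi = 1, A = matrix(1, 1, 1), emissions = list(m))
    } else {
      list(pi = m$pi, A = m$A, emissions = m$emissions)
    }
  })
  sizes <- vapply(pieces, function(p) length(p$pi), 0L)
  total <- sum(sizes)
  offset <- cumsum(c(0, head(sizes, -1)))
  A <- matrix(0, total, total)
  pi0 <- numeric(total)
  state_class <- character(total)
  emissions <- vector("list", total)
  n_cls <- length(classes)
  for (c in seq_len(n_cls)) {
    rows <- offset[c] + seq_len(sizes[c])
    A[rows, rows] <- pieces[[c]]$A
    pi0[rows] <- pieces[[c]]$pi / n_cls
    state_class[rows] <- classes[c]
    emissions[rows] <- pieces[[c]]$emissions
    for (c2 in seq_len(n_cls)) {
      if (c2 == c) next
      cols <- offset[c2] + seq_len(sizes[c2])
      # uniform class switch into the target class's entry distribution
      A[rows, cols] <- A[rows, cols] +
        matrix(pieces[[c2]]$pi, length(rows), sizes[c2], byrow = TRUE) *
          exp(-switch_penalty) / (n_cls - 1)
    }
  }
  A <- A / rowSums(A)
  list(log_pi = log(pi0), log_A = log(A), state_class = state_class,
       emissions = emissions)
}

#' Decode frame labels through the composite network
#'
#' Scores every composite state's emission mixture on each frame and runs
#' the Viterbi algorithm; states are mapped back to their owning class.
#'
#' @param network a [composite_network()].
#' @param X feature matrix, frames in rows.
#' @return Character vector of class labels, one per frame.
#' @export
viterbi_decode <- function(network, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) abort("viterbi_decode: empty feature matrix")
  log_B <- vapply(network$emissions, function(g) gmm_score(g, X),
                  numeric(nrow(X)))
  if (nrow(X) == 1) log_B <- matrix(log_B, nrow = 1)
  res <- viterbi_path(network$log_pi, network$log_A, log_B)
  network$state_class[res$path]
}

#' Initial per-frame classification
#'
#' With a GMM bank, each frame is assigned the class of highest
#' log-likelihood (ties go to the earliest class in the fixed order
#' `EXP < INS < BKG < NOR`), optionally smoothed by a sliding majority
#' vote. With an HMM bank, the frame sequence is decoded through the
#' composite Viterbi network.
#'
#' @param bank a `classifier_bank`.
#' @param X feature matrix matching the bank's recipe dimensionality.
#' @param smooth_window odd majority-vote window for the GMM path
#'   (default 1 = plain argmax).
#' @param switch_penalty passed to [composite_network()] for HMM banks.
#' @return Character vector of class labels, one per frame.
#' @export
classify_frames <- function(bank, X, smooth_window = 1, switch_penalty = 0) {
  stopifnot(inherits(bank, "classifier_bank"))
  X <- as.matrix(X)
  if (ncol(X) != bank$D) {
    abort(sprintf("classify_frames: features have %d dims, bank expects %d",
                  ncol(X), bank$D))
  }
  if (bank$kind == "hmm") {
    return(viterbi_decode(composite_network(bank, switch_penalty), X))
  }
  ll <- vapply(bank$models, function(m) gmm_score(m, X), numeric(nrow(X)))
  if (nrow(X) == 1) ll <- matrix(ll, nrow = 1, dimnames = list(NULL, names(bank$models)))
  labels <- CLASS_LABELS[max.col(ll, ties.method = "first")]
  if (smooth_window > 1) labels <- majority_smooth(labels, smooth_window)
  labels
}

# sliding majority vote; ties resolved by the fixed class order
majority_smooth <- function(labels, w) {
  if (w %% 2 == 0) abort("majority_smooth: window must be odd")
  half <- (w - 1) / 2
  n <- length(labels)
  out <- labels
  for (t in seq_len(n)) {
    win <- labels[max(1, t - half):min(n, t + half)]
    counts <- table(factor(win, levels = CLASS_LABELS))
    out[t] <- CLASS_LABELS[which.max(counts)]
  }
  out
}

#' Serialize / restore a classifier bank
#'
#' The bank is written as a JSON container mapping each class to its model
#' parameters (weights, means, variances, and for HMMs `pi` and `A`).
#'
#' @param bank a `classifier_bank`.
#' @param path output / input path.
#' @return `path` invisibly; `read_bank()` returns the `classifier_bank`.
#' @export
write_bank <- function(bank, path) {
  ser_gmm <- function(g) {
    list(weights = g$weights, means = g$means, variances = g$variances)
  }
  obj <- list(
    kind = bank$kind, recipe = bank$recipe, D = bank$D,
    models = lapply(bank$models, function(m) {
      if (bank$kind == "gmm") {
        ser_gmm(m)
      } else {
        list(pi = m$pi, A = m$A, emissions = lapply(m$emissions, ser_gmm))
      }
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_bank
#' @export
read_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_gmm <- function(g, D) {
    m <- matrix(unlist(g$means), ncol = D)
    v <- matrix(unlist(g$variances), ncol = D)
    out <- new_cry_gmm(unlist(g$weights), m, v, D)
    out
  }
  D <- obj$D
  models <- lapply(obj$models, function(m) {
    if (obj$kind == "gmm") {
      de_gmm(m, D)
    } else {
      A <- matrix(unlist(m$A), nrow = length(m$pi))
      ems <- lapply(m$emissions, de_gmm, D = D)
      new_cry_hmm(unlist(m$pi), A, ems)
    }
  })
  names(models) <- names(obj$models)
  structure(list(models = models, kind = obj$kind, recipe = obj$recipe, D = D),
            class = "classifier_bank")
}
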