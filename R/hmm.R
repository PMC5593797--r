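#' Hidden Markov model with Gaussian-mixture emissions
#'
#' An HMM `lambda = {A, B, pi}`: initial distribution `pi`, row-stochastic
#' transition matrix `A`, and one diagonal-covariance Gaussian mixture per
#' state as the emission density `B`. Parameters are estimated with the
#' Baum-Welch algorithm; decoding uses the Viterbi algorithm.
#'
#' @name hmm
NULL

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

new_cry_hmm <- function(pi0, A, emissions) {
  structure(
    list(n_states = length(pi0), pi = pi0, A = A, emissions = emissions,
         D = emissions[[1]]$D, loglik = numeric()),
    class = "cry_hmm"
  )
}

#' @export
print.cry_hmm <- function(x, ...) {
  cat(sprintf("<cry_hmm> %d states, %d-dim mixture emissions\n",
              x$n_states, x$D))
  invisible(x)
}

# T x N matrix of per-state emission log-densities
hmm_log_emissions <- function(model, X) {
  vapply(model$emissions, function(g) gmm_score(g, X),
         numeric(nrow(as.matrix(X))))
}

transition_mask <- function(n_states, topology) {
  if (topology == "ergodic") return(matrix(TRUE, n_states, n_states))
  # left-to-right with self-loops; last state self-loops
  m <- matrix(FALSE, n_states, n_states)
  for (i in seq_len(n_states)) {
    m[i, i] <- TRUE
    if (i < n_states) m[i, i + 1] <- TRUE
  }
  m
}

#' Fit an HMM by the Baum-Welch algorithm
#'
#' Expectation-maximization over one or more observation sequences. The
#' total log-likelihood is non-decreasing across iterations and all
#' stochasticity constraints (rows of `A`, `pi`, mixture weights) hold
#' after every update. Deterministic given `seed`.
#'
#' @param sequences a feature matrix or list of feature matrices (frames
#'   in rows).
#' @param n_states number of hidden states.
#' @param J mixture components per state (default 1).
#' @param topology `"ergodic"` (default) or `"left-right"` (self-loops +
#'   forward transitions only).
#' @param seed seed for the emission initialization.
#' @param tol relative log-likelihood stopping tolerance (default 1e-6).
#' @param max_iter iteration cap (default 50).
#' @param var_floor variance floor for the emissions (default 1e-6).
#' @return A `cry_hmm` with a per-iteration `loglik` trace.
#' @export
hmm_fit_baumwelch <- function(sequences, n_states, J = 1,
                              topology = c("ergodic", "left-right"),
                              seed = 1L, tol = 1e-6, max_iter = 50,
                              var_floor = 1e-6) {
  topology <- match.arg(topology)
  if (is.matrix(sequences) || is.data.frame(sequences)) {
    sequences <- list(as.matrix(sequences))
  }
  sequences <- lapply(sequences, as.matrix)
  if (length(sequences) == 0) abort("hmm_fit_baumwelch: empty training set")
  if (any(vapply(sequences, nrow, 0L) < n_states)) {
    abort("hmm_fit_baumwelch: every sequence must have length >= n_states")
  }
  mask <- transition_mask(n_states, topology)

  # init: uniform time-segmentation of each sequence over the states
  pooled <- vector("list", n_states)
  for (X in sequences) {
    cut_idx <- ceiling(seq_len(nrow(X)) / nrow(X) * n_states)
    for (i in seq_len(n_states)) {
      pooled[[i]] <- rbind(pooled[[i]], X[cut_idx == i, , drop = FALSE])
    }
  }
  emissions <- lapply(seq_len(n_states), function(i) {
    gmm_fit_em(pooled[[i]], J = min(J, nrow(pooled[[i]])), seed = seed + i,
               var_floor = var_floor)
  })
  A <- matrix(0, n_states, n_states)
  A[mask] <- 1
  diag(A) <- diag(A) + 4 # favour self-loops initially
  A <- A / rowSums(A)
  pi0 <- rep(1 / n_states, n_states)
  if (topology == "left-right") pi0 <- c(1, rep(0, n_states - 1))

  loglik <- numeric()
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    total_ll <- 0
    gamma_all <- list(); xi_sum <- matrix(0, n_states, n_states)
    pi_acc <- rep(0, n_states)
    for (s in seq_along(sequences)) {
      X <- sequences[[s]]
      Tt <- nrow(X)
      logB <- hmm_log_emissions(new_cry_hmm(pi0, A, emissions), X)
      logA <- log(A)
      # forward / backward in the log domain
      la <- matrix(-Inf, Tt, n_states)
      la[1, ] <- log(pi0) + logB[1, ]
      if (Tt > 1) {
        for (t in 2:Tt) {
          for (j in seq_len(n_states)) {
            la[t, j] <- logsumexp(la[t - 1, ] + logA[, j]) + logB[t, j]
          }
        }
      }
      lb <- matrix(0, Tt, n_states)
      if (Tt > 1) {
        for (t in (Tt - 1):1) {
          for (i in seq_len(n_states)) {
            lb[t, i] <- logsumexp(logA[i, ] + logB[t + 1, ] + lb[t + 1, ])
          }
        }
      }
      ll <- logsumexp(la[Tt, ])
      total_ll <- total_ll + ll
      lg <- la + lb - ll
      gamma <- exp(lg)
      gamma_all[[s]] <- gamma
      if (Tt > 1) {
        for (i in seq_len(n_states)) {
          for (j in seq_len(n_states)) {
            if (!mask[i, j]) next
            xi_sum[i, j] <- xi_sum[i, j] + sum(exp(
              la[1:(Tt - 1), i] + logA[i, j] + logB[2:Tt, j] +
                lb[2:Tt, j] - ll
            ))
          }
        }
      }
      pi_acc <- pi_acc + gamma[1, ]
    }
    loglik <- c(loglik, total_ll)

    # M-step
    pi0 <- pi_acc / sum(pi_acc)
    if (topology == "left-right") {
      pi0 <- c(1, rep(0, n_states - 1)) # entry fixed at state 1
    }
    A_new <- xi_sum
    A_new[!mask] <- 0
    rs <- rowSums(A_new)
    rs[rs == 0] <- 1
    A <- A_new / rs
    # keep strictly positive where allowed (numerical guard)
    A[mask & A < 1e-12] <- 1e-12
    A <- A / rowSums(A)

    for (i in seq_len(n_states)) {
      emissions[[i]] <- gmm_weighted_refit(
        emissions[[i]], sequences,
        lapply(gamma_all, function(g) g[, i]), var_floor
      )
    }
    if (is.finite(prev) && (total_ll - prev) < tol * abs(prev)) break
    prev <- total_ll
  }
  model <- new_cry_hmm(pi0, A, emissions)
  model$loglik <- loglik
  model
}

# one M-step update of a state's mixture given per-frame state weights
gmm_weighted_refit <- function(g, sequences, state_w, var_floor) {
  X <- do.call(rbind, sequences)
  wts <- unlist(state_w)
  lp <- component_logdens(X, g$means, g$variances) +
    matrix(log(g$weights), nrow(X), g$J, byrow = TRUE)
  mx <- apply(lp, 1, max)
  post <- exp(lp - (mx + log(rowSums(exp(lp - mx))))) # within-state comp. resp.
  r <- post * wts
  nk <- pmax(colSums(r), 1e-10)
  g$weights <- nk / sum(nk)
  g$means <- sweep(t(r) %*% X, 1, nk, `/`)
  Ex2 <- sweep(t(r) %*% X^2, 1, nk, `/`)
  g$variances <- pmax(Ex2 - g$means^2, var_floor)
  g
}

#' Total log-likelihood of sequences under an HMM
#' @param model a `cry_hmm`.
#' @param sequences feature matrix or list of matrices.
#' @return Scalar log-likelihood.
#' @export
hmm_loglik <- function(model, sequences) {
  if (is.matrix(sequences) || is.data.frame(sequences)) {
    sequences <- list(as.matrix(sequences))
  }
  tot <- 0
  for (X in sequences) {
    logB <- hmm_log_emissions(model, as.matrix(X))
    Tt <- nrow(logB)
    logA <- log(model$A)
    la <- log(model$pi) + logB[1, ]
    if (Tt > 1) {
      for (t in 2:Tt) {
        la <- vapply(seq_len(model$n_states),
                     function(j) logsumexp(la + logA[, j]), 0) + logB[t, ]
      }
    }
    tot <- tot + logsumexp(la)
  }
  tot
}

#' Most probable state path (Viterbi algorithm)
#'
#' Core dynamic-programming recursion over log-domain parameters; used
#' both for single-model decoding and for the composite class network.
#'
#' @param log_pi length-N initial log-probabilities.
#' @param log_A N x N transition log-probability matrix.
#' @param log_B T x N emission log-density matrix.
#' @return List with `path` (length-T state indices) and `logp` (path log
#'   probability).
#' @export
viterbi_path <- function(log_pi, log_A, log_B) {
  Tt <- nrow(log_B); N <- ncol(log_B)
  if (Tt == 0) abort("viterbi_path: empty observation sequence")
  delta <- matrix(-Inf, Tt, N)
  psi <- matrix(0L, Tt, N)
  delta[1, ] <- log_pi + log_B[1, ]
  if (all(!is.finite(delta[1, ]))) {
    abort("viterbi_path: all states impossible at frame 1")
  }
  if (Tt > 1) {
    for (t in 2:Tt) {
      for (j in seq_len(N)) {
        cand <- delta[t - 1, ] + log_A[, j]
        psi[t, j] <- which.max(cand)
        delta[t, j] <- cand[psi[t, j]] + log_B[t, j]
      }
      if (all(!is.finite(delta[t, ]))) {
        abort(sprintf("viterbi_path: all states impossible at frame %d", t))
      }
    }
  }
  path <- integer(Tt)
  path[Tt] <- which.max(delta[Tt, ])
  if (Tt > 1) for (t in (Tt - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  list(path = path, logp = max(delta[Tt, ]))
}

#' @export
tidy.cry_hmm <- function(x, ...) {
  tidyr::expand_grid(from = seq_len(x$n_states), to = seq_len(x$n_states)) |>
    dplyr::mutate(probability = as.vector(t(x$A)))
}

#' @export
glance.cry_hmm <- function(x, ...) {
  tibble::tibble(
    n_states = x$n_states,
    J = x$emissions[[1]]$J,
    D = x$D,
    logLik = if (length(x$loglik)) tail(x$loglik, 1) else NA_real_,
    n_iter = length(x$loglik)
  )
}
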