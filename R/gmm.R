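#' Gaussian mixture model with diagonal covariances
#'
#' The frame likelihood is `p(o | lambda) = sum_j w_j G(o; mu_j, Sigma_j)`
#' with mixture weights summing to one and diagonal covariance matrices
#' floored away from zero. Fitting is by expectation-maximization from a
#' seeded k-means initialization, so the result is deterministic given the
#' seed.
#'
#' @param X numeric feature matrix, frames in rows.
#' @param J number of mixture components.
#' @param seed integer seed for the k-means initialization.
#' @param tol relative log-likelihood improvement at which EM stops
#'   (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @param var_floor lower bound applied to every variance (default 1e-6).
#' @return A `cry_gmm`: list with `weights` (J), `means` (J x D),
#'   `variances` (J x D), `loglik` (per-iteration total log-likelihood),
#'   `J`, `D`.
#' @export
gmm_fit_em <- function(X, J, seed = 1L, tol = 1e-6, max_iter = 200,
                       var_floor = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X); D <- ncol(X)
  if (J > n) abort("gmm_fit_em: more components than frames")
  if (J == 1L) {
    mu <- matrix(colMeans(X), 1, D)
    v <- matrix(pmax(apply(X, 2, function(c) mean((c - mean(c))^2)),
                     var_floor), 1, D)
    model <- new_cry_gmm(1, mu, v, D)
    model$loglik <- sum(gmm_score(model, X))
    return(model)
  }
  km <- with_local_seed(seed, kmeans(X, centers = J, nstart = 5,
                                     iter.max = 50))
  mu <- km$centers
  w <- as.numeric(table(factor(km$cluster, levels = seq_len(J)))) / n
  w <- pmax(w, 1e-8); w <- w / sum(w)
  v <- matrix(0, J, D)
  for (j in seq_len(J)) {
    Xi <- X[km$cluster == j, , drop = FALSE]
    v[j, ] <- if (nrow(Xi) > 1) apply(Xi, 2, var) else apply(X, 2, var)
  }
  v <- pmax(v, var_floor)

  loglik <- numeric()
  prev <- -Inf
  for (iter in seq_len(max_iter)) {
    lp <- component_logdens(X, mu, v) +
      matrix(log(w), n, J, byrow = TRUE) # n x J
    mx <- apply(lp, 1, max)
    ll_frame <- mx + log(rowSums(exp(lp - mx)))
    loglik <- c(loglik, sum(ll_frame))
    resp <- exp(lp - ll_frame) # posterior responsibilities
    nk <- colSums(resp)
    collapsed <- nk < 1e-8
    if (any(collapsed)) {
      warn("gmm_fit_em: collapsed component(s); variance floor applied")
      nk <- pmax(nk, 1e-8)
    }
    w <- nk / n
    mu <- sweep(t(resp) %*% X, 1, nk, `/`)
    Ex2 <- sweep(t(resp) %*% X^2, 1, nk, `/`)
    v <- pmax(Ex2 - mu^2, var_floor)
    if (is.finite(prev) &&
        (tail(loglik, 1) - prev) < tol * abs(prev)) break
    prev <- tail(loglik, 1)
  }
  model <- new_cry_gmm(w, mu, v, D)
  model$loglik <- loglik
  model
}

new_cry_gmm <- function(weights, means, variances, D) {
  structure(
    list(weights = as.numeric(weights), means = means, variances = variances,
         J = nrow(means), D = D, loglik = numeric()),
    class = "cry_gmm"
  )
}

# n x J matrix of per-component diagonal Gaussian log-densities
component_logdens <- function(X, mu, v) {
  n <- nrow(X); J <- nrow(mu)
  out <- matrix(0, n, J)
  for (j in seq_len(J)) {
    z <- sweep(X, 2, mu[j, ], `-`)
    out[, j] <- -0.5 * (ncol(X) * log(2 * pi) + sum(log(v[j, ])) +
                          rowSums(sweep(z^2, 2, v[j, ], `/`)))
  }
  out
}

#' Per-frame log-likelihood under a Gaussian mixture
#'
#' @param model a `cry_gmm`.
#' @param X feature matrix with `model$D` columns.
#' @return Numeric vector `log p(o_t | lambda)`, one value per frame.
#' @export
gmm_score <- function(model, X) {
  stopifnot(inherits(model, "cry_gmm"))
  X <- as.matrix(X)
  if (ncol(X) != model$D) abort("gmm_score: dimension mismatch")
  lp <- component_logdens(X, model$means, model$variances) +
    matrix(log(model$weights), nrow(X), model$J, byrow = TRUE)
  mx <- apply(lp, 1, max)
  mx + log(rowSums(exp(lp - mx)))
}

#' @export
print.cry_gmm <- function(x, ...) {
  cat(sprintf("<cry_gmm> %d components, %d dims\n", x$J, x$D))
  invisible(x)
}

#' @export
tidy.cry_gmm <- function(x, ...) {
  purrr::map_dfr(seq_len(x$J), function(j) {
    tibble::tibble(
      component = j,
      weight = x$weights[j],
      dimension = seq_len(x$D),
      mean = x$means[j, ],
      variance = x$variances[j, ]
    )
  })
}

#' @export
glance.cry_gmm <- function(x, ...) {
  tibble::tibble(
    J = x$J, D = x$D,
    logLik = if (length(x$loglik)) tail(x$loglik, 1) else NA_real_,
    n_iter = length(x$loglik),
    n_par = x$J - 1 + 2 * x$J * x$D
  )
}
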