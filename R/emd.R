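#' Empirical mode decomposition
#'
#' Sifting-based decomposition of a signal into intrinsic mode functions
#' (IMFs) and a residue. An IMF is an oscillatory component whose numbers
#' of extrema and zero crossings are equal or differ by one and whose
#' upper/lower spline-envelope midline is (approximately) zero everywhere.
#'
#' @name emd
NULL

# indices of strict local maxima / minima
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(), min = integer()))
  d <- diff(x)
  # collapse exact plateaus by keeping the first point of each
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(max = integer(), min = integer()))
  s_f <- s
  for (i in seq(2, length(s))) if (s_f[i] == 0) s_f[i] <- s_f[i - 1]
  turn <- which(diff(s_f) != 0) + 1L
  list(
    max = turn[s_f[turn - 1] > 0],
    min = turn[s_f[turn - 1] < 0]
  )
}

count_zero_crossings <- function(x) {
  s <- x >= 0
  sum(s[-1] != s[-length(s)])
}

# cubic-spline envelope through extrema, mirror-extended at both ends to
# curb end swings
envelope <- function(x, idx, n_mirror = 2) {
  n <- length(x)
  t <- idx
  v <- x[idx]
  k <- min(n_mirror, length(idx))
  t_left <- 2 - rev(t[seq_len(k)])       # reflect about sample 1
  v_left <- rev(v[seq_len(k)])
  t_right <- 2 * n - rev(rev(t)[seq_len(k)]) # reflect about sample n
  v_right <- rev(rev(v)[seq_len(k)])
  tt <- c(t_left, t, t_right)
  vv <- c(v_left, v, v_right)
  keep <- !duplicated(tt)
  stats::spline(tt[keep], vv[keep], xout = seq_len(n), method = "fmm")$y
}

#' One sifting step
#'
#' Interpolates the local maxima and minima with cubic splines
#' (mirror-extended at the boundaries) to form the upper and lower
#' envelopes `u(t)` and `l(t)`, computes the midline
#' `m(t) = (u(t) + l(t)) / 2` and returns `h(t) = x(t) - m(t)`.
#'
#' @param x numeric signal with at least 2 maxima and 2 minima.
#' @return List with `h` (sifted signal), `m` (envelope midline), and
#'   `ok = TRUE`; when the signal has too few extrema to sift, returns
#'   `ok = FALSE` with `h = x`, `m = 0`.
#' @export
sift_once <- function(x) {
  ext <- local_extrema(x)
  if (length(ext$max) < 2 || length(ext$min) < 2) {
    return(list(h = x, m = rep(0, length(x)), ok = FALSE))
  }
  u <- envelope(x, ext$max)
  l <- envelope(x, ext$min)
  m <- (u + l) / 2
  list(h = x - m, m = m, ok = TRUE)
}

imf_count_criterion <- function(h) {
  ext <- local_extrema(h)
  n_ext <- length(ext$max) + length(ext$min)
  abs(n_ext - count_zero_crossings(h)) <= 1
}

#' Extract one intrinsic mode function
#'
#' Repeats [sift_once()] until the candidate satisfies the
#' extrema/zero-crossing count criterion and the standard-deviation
#' stopping statistic `SD = sum((h_prev - h)^2) / sum(h_prev^2)` has
#' dropped below `sd_threshold` (the count criterion alone is not a
#' reliable stop on broadband signals, and SD alone can accept a
#' candidate whose counts have not yet aligned), or `max_sifts` is
#' reached.
#'
#' @param x numeric signal.
#' @param sd_threshold Huang stopping threshold (default 0.2).
#' @param max_sifts iteration cap (default 100).
#' @return List with `imf`, `residue` (`x - imf`), `n_sifts`, and
#'   `converged` (`FALSE` when stopped by `max_sifts` only).
#' @export
extract_imf <- function(x, sd_threshold = 0.2, max_sifts = 100) {
  h <- x
  converged <- FALSE
  n_sifts <- 0L
  repeat {
    s <- sift_once(h)
    if (!s$ok) {
      if (n_sifts == 0L) abort("extract_imf: too few extrema to sift")
      converged <- TRUE
      break
    }
    n_sifts <- n_sifts + 1L
    sd_stat <- sum((h - s$h)^2) / max(sum(h^2), .Machine$double.eps)
    done <- sd_stat < sd_threshold && imf_count_criterion(s$h)
    h <- s$h
    if (done) {
      converged <- TRUE
      break
    }
    if (n_sifts >= max_sifts) break
  }
  if (!converged) {
    warn("extract_imf: sifting did not converge within max_sifts")
  }
  list(imf = h, residue = x - h, n_sifts = n_sifts, converged = converged)
}

#' Decompose a signal into IMFs and a residue
#'
#' Repeatedly extracts IMFs from successive residues until the residue has
#' too few extrema to sift (monotone trend) or `max_imfs` is reached. The
#' decomposition reconstructs the input exactly:
#' `sum(imfs) + residue == x`.
#'
#' @param x numeric signal.
#' @param n_imfs_min minimum number of IMFs required downstream (error if
#'   fewer are obtainable; default 0).
#' @param max_imfs cap on extracted IMFs (default 16).
#' @param sd_threshold,max_sifts passed to [extract_imf()].
#' @return An `imf_decomposition`: list with `imfs` (list of signals),
#'   `residue`, `sift_counts`.
#' @export
emd_decompose <- function(x, n_imfs_min = 0, max_imfs = 16,
                          sd_threshold = 0.2, max_sifts = 100) {
  residue <- x
  imfs <- list()
  sift_counts <- integer()
  while (length(imfs) < max_imfs) {
    ext <- local_extrema(residue)
    if (length(ext$max) < 2 || length(ext$min) < 2) break
    r <- extract_imf(residue, sd_threshold, max_sifts)
    imfs[[length(imfs) + 1L]] <- r$imf
    sift_counts <- c(sift_counts, r$n_sifts)
    residue <- r$residue
  }
  if (length(imfs) < n_imfs_min) {
    abort(sprintf("emd_decompose: only %d IMF(s) obtainable, %d required",
                  length(imfs), n_imfs_min))
  }
  structure(
    list(imfs = imfs, residue = residue, sift_counts = sift_counts),
    class = "imf_decomposition"
  )
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("<imf_decomposition> %d IMFs + residue (%d samples)\n",
              length(x$imfs), length(x$residue)))
  invisible(x)
}

#' Recombine selected IMFs
#'
#' Pointwise sum of the chosen intrinsic mode functions. The default
#' `c(3, 4, 5)` is the IMF3+IMF4+IMF5 recombination that carries the
#' cry-relevant mid-band and feeds the EMD-based cepstral features.
#'
#' @param d an `imf_decomposition` from [emd_decompose()].
#' @param indices 1-based IMF indices to sum (default `c(3, 4, 5)`).
#' @return Numeric signal of the input length.
#' @export
combine_imfs <- function(d, indices = c(3, 4, 5)) {
  stopifnot(inherits(d, "imf_decomposition"))
  if (max(indices) > length(d$imfs)) {
    abort(sprintf("combine_imfs: decomposition has %d IMFs, index %d requested",
                  length(d$imfs), max(indices)))
  }
  Reduce(`+`, d$imfs[indices])
}
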