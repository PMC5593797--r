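test_that("single-component fits reduce to sample moments", {
  set.seed(71)
  X <- matrix(rnorm(200, mean = 2, sd = 1.5), ncol = 2)
  g <- gmm_fit_em(X, J = 1)
  expect_equal(g$weights, 1)
  expect_equal(g$means[1, ], colMeans(X))
  expect_equal(g$variances[1, ],
               apply(X, 2, function(c) mean((c - mean(c))^2)))
})

test_that("EM recovers well-separated mixture components deterministically", {
  set.seed(72)
  n <- 300
  X <- rbind(matrix(rnorm(2 * n, 0, 1), ncol = 2),
             matrix(rnorm(2 * n, 6, 1), ncol = 2))
  g <- gmm_fit_em(X, J = 2, seed = 5)
  mu <- g$means[order(g$means[, 1]), ]
  se <- 1 / sqrt(n)
  expect_true(all(abs(mu[1, ] - 0) < 3 * se + 0.05))
  expect_true(all(abs(mu[2, ] - 6) < 3 * se + 0.05))
  expect_true(all(diff(g$loglik) > -1e-8))
  expect_equal(sum(g$weights), 1, tolerance = 1e-9)
  g2 <- gmm_fit_em(X, J = 2, seed = 5)
  expect_identical(g$means, g2$means)
  expect_error(gmm_fit_em(X[1:3, ], J = 5), "components")

  # independent oracle: mclust's diagonal EM lands on the same solution
  skip_if_not_installed("mclust")
  mclustBIC <- mclust::mclustBIC # Mclust resolves this in the caller
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVI", verbose = FALSE)
  expect_equal(sort(g$means[, 1]), sort(mc$parameters$mean[1, ]),
               tolerance = 0.05)
})

test_that("mixture scores equal brute-force density summation", {
  set.seed(73)
  J <- 3; D <- 2
  g <- cryseg:::new_cry_gmm(
    weights = c(0.5, 0.3, 0.2),
    means = matrix(rnorm(J * D), J, D),
    variances = matrix(runif(J * D, 0.5, 2), J, D),
    D = D
  )
  X <- matrix(rnorm(20 * D), ncol = D)
  oracle <- apply(X, 1, function(o) {
    log(sum(vapply(1:J, function(j) {
      g$weights[j] * prod(stats::dnorm(o, g$means[j, ],
                                       sqrt(g$variances[j, ])))
    }, 0)))
  })
  got <- gmm_score(g, X)
  expect_equal(got, oracle, tolerance = 1e-10)
  # closed form for a standard normal at the origin
  g1 <- cryseg:::new_cry_gmm(1, matrix(0, 1, 1), matrix(1, 1, 1), 1)
  expect_equal(gmm_score(g1, matrix(0)), log(1 / sqrt(2 * pi)))
  # mixture bound: score >= max_j log(w_j G_j)
  comp <- cryseg:::component_logdens(X, g$means, g$variances) +
    matrix(log(g$weights), nrow(X), J, byrow = TRUE)
  expect_true(all(got >= apply(comp, 1, max) - 1e-12))
  expect_error(gmm_score(g, matrix(0, 2, 5)), "dimension")
})

test_that("Baum-Welch keeps stochasticity and a monotone likelihood", {
  set.seed(74)
  seqs <- lapply(1:4, function(i) matrix(rnorm(60), ncol = 1))
  h <- hmm_fit_baumwelch(seqs, n_states = 2, J = 1, max_iter = 10)
  expect_equal(rowSums(h$A), c(1, 1), tolerance = 1e-9)
  expect_equal(sum(h$pi), 1, tolerance = 1e-9)
  rel <- diff(h$loglik) / pmax(abs(head(h$loglik, -1)), 1)
  expect_true(all(rel > -1e-8))
  expect_error(hmm_fit_baumwelch(list(), 2), "empty")
})

test_that("a single-state HMM degenerates to the plain mixture fit", {
  set.seed(75)
  X <- matrix(rnorm(400, 1, 2), ncol = 2)
  h <- hmm_fit_baumwelch(X, n_states = 1, J = 1, max_iter = 5)
  g <- gmm_fit_em(X, J = 1)
  expect_equal(h$emissions[[1]]$means, g$means, tolerance = 1e-6)
  expect_equal(h$emissions[[1]]$variances, g$variances, tolerance = 1e-6)
  expect_equal(h$A, matrix(1, 1, 1))
})

test_that("Viterbi finds the generating path under near-deterministic emissions", {
  set.seed(76)
  # 2-state toy: distinct means, tiny variance
  A <- matrix(c(0.9, 0.1, 0.15, 0.85), 2, 2, byrow = TRUE)
  states <- numeric(40); states[1] <- 1
  for (t in 2:40) states[t] <- sample(1:2, 1, prob = A[states[t - 1], ])
  obs <- matrix(rnorm(40, mean = c(0, 5)[states], sd = 0.1), ncol = 1)
  ems <- lapply(c(0, 5), function(m) {
    cryseg:::new_cry_gmm(1, matrix(m, 1, 1), matrix(0.01, 1, 1), 1)
  })
  logB <- vapply(ems, function(g) gmm_score(g, obs), numeric(40))
  res <- viterbi_path(log(c(0.9, 0.1)), log(A), logB)
  expect_equal(res$path, states)
})

test_that("decoded paths beat every enumerated alternative", {
  set.seed(77)
  for (case in 1:25) {
    N <- sample(2:4, 1); Tt <- sample(2:6, 1)
    log_pi <- log(prop.table(runif(N)))
    log_A <- log(t(apply(matrix(runif(N * N), N), 1, prop.table)))
    log_B <- matrix(rnorm(Tt * N), Tt, N)
    res <- viterbi_path(log_pi, log_A, log_B)
    paths <- as.matrix(expand.grid(rep(list(seq_len(N)), Tt)))
    score <- function(p) {
      s <- log_pi[p[1]] + log_B[1, p[1]]
      for (t in 2:Tt) s <- s + log_A[p[t - 1], p[t]] + log_B[t, p[t]]
      s
    }
    all_scores <- apply(paths, 1, score)
    expect_equal(res$logp, max(all_scores), tolerance = 1e-10)
    expect_equal(unname(res$path),
                 unname(paths[which.max(all_scores), ]))
  }
})

test_that("frame classification honours the recipe, tie-break and smoothing", {
  set.seed(78)
  mk <- function(m) cryseg:::new_cry_gmm(1, matrix(m, 1, 2, byrow = TRUE),
                                         matrix(1, 1, 2), 2)
  centres <- list(EXP = c(0, 0), INS = c(6, 0), BKG = c(0, 6), NOR = c(6, 6))
  bank <- structure(
    list(models = lapply(centres, mk), kind = "gmm",
         recipe = "fft-mfcc", D = 2),
    class = "classifier_bank"
  )
  X <- do.call(rbind, lapply(centres, function(m) {
    matrix(rnorm(100, mean = rep(m, each = 50), sd = 0.5), ncol = 2)
  }))
  truth <- rep(CLASS_LABELS, each = 50)
  got <- classify_frames(bank, X)
  expect_gt(mean(got == truth), 0.9)
  # exact tie: identical models for all classes -> first class in order wins
  tie_bank <- bank
  tie_bank$models <- lapply(centres, function(m) mk(c(0, 0)))
  expect_equal(unique(classify_frames(tie_bank, X)), "EXP")
  # smoothing removes an isolated flip
  labs <- c(rep("EXP", 5), "BKG", rep("EXP", 5))
  expect_equal(unique(cryseg:::majority_smooth(labs, 3)), "EXP")
  expect_error(classify_frames(bank, matrix(0, 2, 5)), "dims")
})

test_that("an HMM bank decodes class blocks through the composite network", {
  set.seed(79)
  mk_hmm <- function(m) {
    em <- cryseg:::new_cry_gmm(1, matrix(m, 1, 1), matrix(0.05, 1, 1), 1)
    cryseg:::new_cry_hmm(1, matrix(1, 1, 1), list(em))
  }
  bank <- structure(
    list(models = list(EXP = mk_hmm(0), INS = mk_hmm(3),
                       BKG = mk_hmm(6), NOR = mk_hmm(9)),
         kind = "hmm", recipe = "emd-mfcc", D = 1),
    class = "classifier_bank"
  )
  X <- matrix(c(rnorm(30, 0, 0.2), rnorm(30, 6, 0.2), rnorm(30, 3, 0.2)),
              ncol = 1)
  got <- classify_frames(bank, X)
  expect_equal(got, rep(c("EXP", "BKG", "INS"), each = 30))
  # single-class network: constant labels
  net1 <- composite_network(bank)
  expect_equal(length(net1$state_class), 4)
  expect_error(viterbi_decode(net1, X[0, , drop = FALSE]), "empty")
})

test_that("classifier banks survive JSON serialization", {
  bank <- fixture_bank()
  f <- withr::local_tempfile(fileext = ".json")
  write_bank(bank, f)
  back <- read_bank(f)
  expect_equal(back$kind, bank$kind)
  expect_equal(back$recipe, bank$recipe)
  X <- matrix(rnorm(5 * bank$D), ncol = bank$D)
  for (cls in CLASS_LABELS) {
    expect_equal(gmm_score(back$models[[cls]], X),
                 gmm_score(bank$models[[cls]], X), tolerance = 1e-12)
  }
})

test_that("tidy and glance summarise fitted models", {
  set.seed(80)
  g <- gmm_fit_em(matrix(rnorm(100), ncol = 2), J = 2, seed = 1)
  td <- tidy(g)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 2 * 2)
  expect_equal(glance(g)$J, 2)
  h <- hmm_fit_baumwelch(matrix(rnorm(60), ncol = 1), n_states = 2,
                         max_iter = 3)
  expect_equal(nrow(tidy(h)), 4)
  expect_equal(glance(h)$n_states, 2)
})
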