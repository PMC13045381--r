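test_that("transition counting matches hand enumeration and an O(T) oracle", {
  d <- c(1L, 2L, 1L, 2L, 1L)
  cs <- count_transitions(d, lag = 1, mode = "sliding")
  expect_equal(cs$counts, matrix(c(0, 2, 2, 0), 2, 2, byrow = TRUE))
  # strided counting samples the chain every `lag` frames, so sliding and
  # strided coincide at lag 1
  ct <- count_transitions(d, lag = 1, mode = "strided")
  expect_equal(ct$counts, cs$counts)
  # lag 2 strided on [1,2,1,2,1]: sampled frames 1,3,5 are all state 1
  ct2 <- count_transitions(d, lag = 2, mode = "strided")
  expect_equal(ct2$counts, matrix(c(2, 0, 0, 0), 2, 2, byrow = TRUE))
  set.seed(2)
  d2 <- sample.int(4, 300, TRUE)
  expect_equal(count_transitions(d2, 1, "sliding")$counts,
               count_transitions(d2, 1, "strided")$counts)
  # random trajectory vs a direct loop
  for (lag in c(1L, 3L, 7L)) {
    oracle <- matrix(0, 4, 4)
    for (t in seq_len(length(d2) - lag)) {
      oracle[d2[t], d2[t + lag]] <- oracle[d2[t], d2[t + lag]] + 1
    }
    expect_equal(count_transitions(d2, lag, "sliding")$counts, oracle)
  }
  expect_error(count_transitions(list(), 1), "no trajectory")
  # active set excludes states unreachable in both directions
  d3 <- c(1L, 1L, 2L, 2L, 4L, 4L)   # state 3 never seen; 4 absorbing-ish
  cm <- count_transitions(d3, 1)
  expect_false(3L %in% cm$active_set)
})

test_that("reversible MLE satisfies detailed balance and matches closed forms and an optimiser oracle", {
  m <- mle_reversible(matrix(c(8, 2, 2, 8), 2, 2))
  expect_equal(m$transition_matrix, two_state_T(0.2, 0.2), tolerance = 1e-9)
  expect_equal(m$stationary, c(0.5, 0.5), tolerance = 1e-9)
  # any counts: detailed-balance residual < 1e-8 and rows sum to 1
  set.seed(8)
  for (i in 1:5) {
    C <- matrix(rpois(9, 20), 3, 3)
    m3 <- mle_reversible(C)
    P <- m3$stationary * m3$transition_matrix
    expect_lt(max(abs(P - t(P))), 1e-8)
    expect_equal(rowSums(m3$transition_matrix), rep(1, 3), tolerance = 1e-10)
    # likelihood at the MLE >= naive reversible symmetrisation estimate
    loglik <- function(Tm) sum(C[Tm > 0] * log(Tm[Tm > 0]))
    naive <- (C + t(C)) / rowSums(C + t(C))
    expect_gte(loglik(m3$transition_matrix), loglik(naive) - 1e-9)
    # independent numerical optimisation over symmetric flows
    idx <- which(upper.tri(diag(3), diag = TRUE))
    obj <- function(theta) {
      S <- matrix(0, 3, 3)
      S[idx] <- exp(theta)
      S <- S + t(S) - diag(diag(S))
      Tm <- S / rowSums(S)
      -loglik(Tm)
    }
    opt <- stats::optim(rep(0, 6), obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-15))
    S <- matrix(0, 3, 3); S[idx] <- exp(opt$par)
    S <- S + t(S) - diag(diag(S))
    T_oracle <- S / rowSums(S)
    expect_equal(m3$transition_matrix, T_oracle, tolerance = 1e-5)
  }
})

test_that("MLE error shrinks with sampling depth on data from a known reversible chain", {
  T_true <- block_chain(2, 2, 0.2)
  err <- vapply(c(2000L, 50000L), function(n) {
    d <- simulate_chain(T_true, n, seed = 100 + n)
    m <- mle_reversible(count_transitions(d, 1))
    max(abs(m$transition_matrix - T_true))
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 5 / sqrt(50000 / 4))
})

test_that("implied timescales match the closed form and are flat for Markovian data", {
  Tm <- two_state_T(0.1, 0.1)              # lambda2 = 0.8
  d <- simulate_chain(Tm, 200000, seed = 31)
  its <- implied_timescales(d, lags = c(1, 2, 4, 8), n_timescales = 1,
                            frame_interval = 1)
  t_hat <- its$table$timescale_ns[its$table$lag_frames == 1]
  expect_equal(t_hat, -1 / log(0.8), tolerance = 0.05)
  # Markov data: timescales constant across lags within estimator noise
  ts <- its$table$timescale_ns
  expect_lt(max(abs(ts - mean(ts))) / mean(ts), 0.1)
  expect_false(is.na(its$plateau_lag))
  expect_error(implied_timescales(d[1:10], lags = c(1, 50)), "length")
})

test_that("MFPT linear solves match closed forms and brute-force simulation", {
  Tm <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_equal(mfpt_to_set(Tm, 2)[1], 10)             # 1/(1 - 0.9)
  expect_equal(mfpt_to_set(Tm, 2, lag_time = 3)[1], 30)
  expect_equal(diag(mfpt_matrix(Tm)), c(0, 0))
  # unreachable target reported as Inf
  T_abs <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  expect_equal(mfpt_to_set(T_abs, 2)[1], Inf)
  # brute-force mean first passage on a 3-state chain within 2 SE
  T3 <- matrix(c(0.7, 0.2, 0.1,
                 0.3, 0.5, 0.2,
                 0.1, 0.3, 0.6), 3, 3, byrow = TRUE)
  exact <- mfpt_to_set(T3, 3)[1]
  set.seed(77)
  cumT <- t(apply(T3, 1, cumsum))
  hits <- vapply(1:4000, function(i) {
    s <- 1L; t <- 0L
    while (s != 3L) {
      s <- min(findInterval(runif(1), cumT[s, ]) + 1L, 3L)
      t <- t + 1L
    }
    t
  }, numeric(1))
  se <- stats::sd(hits) / sqrt(length(hits))
  expect_lt(abs(mean(hits) - exact), 2 * se + 1e-9)
})

test_that("the Chapman-Kolmogorov test validates Markovian data and flags lumped non-Markov data", {
  T_true <- block_chain(2, 3, 0.02)
  d <- lapply(1:8, function(i) simulate_chain(T_true, 30000, seed = 200 + i))
  cm <- count_transitions(d, 1)
  model <- mle_reversible(cm)
  sets <- list(which(model$active_set <= 3), which(model$active_set > 3))
  ck <- ck_test(model, d, sets, ks = c(1, 2, 4, 8), n_samples = 20, seed = 5)
  # k = 1: predicted equals estimated (same estimator, same data)
  expect_equal(ck[[1]]$predicted, ck[[1]]$estimated, tolerance = 1e-6)
  # Markovian data: predictions within the 95% band for >= 90% of entries
  entries <- ok <- 0
  for (rec in ck) {
    if (is.null(rec$estimated)) next
    dev <- abs(rec$predicted - rec$estimated)
    band <- 1.96 * rec$est_sd + 1e-4
    entries <- entries + length(dev)
    ok <- ok + sum(dev <= band)
  }
  expect_gte(ok / entries, 0.9)
  # lumping a genuinely 3-timescale chain onto 2 labels breaks Markovianity:
  # the long-horizon prediction must deviate systematically
  T_slowfast <- matrix(c(0.98, 0.02, 0.00,
                         0.02, 0.96, 0.02,
                         0.00, 0.02, 0.98), 3, 3, byrow = TRUE)
  raw <- lapply(1:6, function(i) simulate_chain(T_slowfast, 30000, seed = 300 + i))
  lumped <- lapply(raw, function(s) ifelse(s <= 2L, 1L, 2L))   # hide a slow process
  cml <- count_transitions(lumped, 1)
  ml <- mle_reversible(cml)
  ckl <- ck_test(ml, lumped, list(1L, 2L), ks = c(1, 30), n_samples = 0, seed = 6)
  dev_long <- max(abs(ckl[[2]]$predicted - ckl[[2]]$estimated))
  expect_gt(dev_long, 0.02)
})

test_that("the Bayesian ensemble is seeded, reversible, correctly sized and posterior-consistent", {
  T_true <- block_chain(2, 2, 0.1)
  d <- simulate_chain(T_true, 100000, seed = 41)
  cm <- count_transitions(d, 1)
  ens <- bayesian_ensemble(cm, seed = 17)
  expect_length(ens$samples, 100L)           # default ensemble size
  for (s in ens$samples[seq(1, 100, by = 9)]) {
    P <- s$stationary * s$transition_matrix
    expect_lt(max(abs(P - t(P))), 1e-8)
    expect_equal(rowSums(s$transition_matrix), rep(1, 4), tolerance = 1e-10)
  }
  expect_gt(ens$acceptance_rate, 0.05)
  expect_lt(ens$acceptance_rate, 0.95)
  # determinism under seed
  ens2 <- bayesian_ensemble(cm, seed = 17)
  expect_equal(ens$samples[[100]]$transition_matrix,
               ens2$samples[[100]]$transition_matrix, tolerance = 1e-14)
  expect_error(bayesian_ensemble(cm), "seed")
  # posterior concentration: with ~1e5 transitions the ensemble mean is
  # element-wise within 0.01 of the MLE
  mle <- mle_reversible(cm)
  mean_T <- Reduce(`+`, lapply(ens$samples, `[[`, "transition_matrix")) / 100
  expect_lt(max(abs(mean_T - mle$transition_matrix)), 0.01)
})

test_that("stationary vectors are fixed points of their transition matrices", {
  set.seed(55)
  for (i in 1:4) {
    C <- matrix(rpois(25, 10) + 1, 5, 5)
    m <- mle_reversible(C)
    expect_equal(as.numeric(m$stationary %*% m$transition_matrix),
                 m$stationary, tolerance = 1e-8)
    expect_equal(m$eigenvalues[1], 1, tolerance = 1e-10)
  }
})
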