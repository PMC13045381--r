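# Shared helpers: small constructed fixtures and independent brute-force
# oracles used across the suite.

# A minimal valid kinetic fixture with a caller-supplied transition matrix.
make_test_fixture <- function(Tm, stationary = NULL, frame_interval = 1,
                              ar = 0.0, n_feat = 2) {
  n <- nrow(Tm)
  if (is.null(stationary)) stationary <- stationary_distribution(Tm)
  means <- cbind(seq(10, 10 + 20 * (n - 1), by = 20),
                 matrix(rep(seq(5, 5 + 5 * (n - 1), by = 5), n_feat - 1),
                        n, n_feat - 1))
  kinetic_fixture(
    state_names = paste0("S", seq_len(n)),
    transition_matrix = Tm, stationary = stationary,
    frame_interval = frame_interval,
    emission_means = means,
    emission_sds = matrix(1, n, n_feat),
    ar_coefficient = ar, name = "test")
}

# Reversible 2x2 / block chains used in several places.
two_state_T <- function(a = 0.1, b = 0.5) {
  matrix(c(1 - a, a, b, 1 - b), 2, 2, byrow = TRUE)
}

block_chain <- function(n_blocks, block_size, coupling) {
  n <- n_blocks * block_size
  Tm <- matrix(0, n, n)
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * block_size + 1):(b * block_size)
    Tm[idx, idx] <- 1 / block_size
  }
  if (coupling > 0) {
    Tm <- (1 - coupling) * Tm + coupling / n
  }
  Tm / rowSums(Tm)
}

# O(N^2) brute-force lipid-molecule contact count.
brute_contacts <- function(frame, domain, cutoff = 4.0, species = "any",
                           atom_pairs = FALSE) {
  prot <- which(frame$atoms$molecule_class == domain)
  keep <- if (identical(species, "any")) c("POPC", "POPS") else species
  lip <- which(frame$atoms$molecule_class %in% keep)
  hits <- 0L
  touched <- integer(0)
  for (i in prot) for (j in lip) {
    d <- sqrt(sum((frame$coords[i, ] - frame$coords[j, ])^2))
    if (d <= cutoff) {
      hits <- hits + 1L
      touched <- union(touched, frame$atoms$molecule_id[j])
    }
  }
  if (atom_pairs) hits else length(touched)
}

# Stationary AR(1) series with unit marginal variance scale.
ar1_series <- function(n, phi, seed, sd_innov = 1) {
  set.seed(seed)
  as.numeric(stats::filter(rnorm(n, sd = sd_innov * sqrt(1 - phi^2)),
                           phi, method = "recursive"))
}

# Random proper rotation matrix (deterministic under seed).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Simulate a discrete Markov chain directly from a transition matrix.
simulate_chain <- function(Tm, n, seed, start = NULL) {
  set.seed(seed)
  k <- nrow(Tm)
  cumT <- t(apply(Tm, 1, cumsum))
  s <- integer(n)
  s[1] <- if (is.null(start)) sample.int(k, 1) else start
  u <- runif(n)
  for (t in 2:n) {
    s[t] <- min(findInterval(u[t], cumT[s[t - 1], ]) + 1L, k)
  }
  s
}
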