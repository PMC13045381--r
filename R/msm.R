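#' Count microstate transitions at a lag
#'
#' Tallies observed transitions between discrete states at a fixed lag, either
#' with a sliding window (every pair \code{(t, t + lag)}) or a strided window
#' (non-overlapping pairs). The largest strongly connected subset of the
#' directed count graph is recorded as the active set; downstream estimators
#' operate on that subset.
#'
#' @param dtrajs integer vector or list of integer vectors of state labels
#'   (1-based, or 0-based — labels are used as-is against \code{n_states}).
#' @param lag positive integer lag in frames.
#' @param mode `"sliding"` (default) or `"strided"`.
#' @param n_states number of states; defaults to the largest label observed.
#' @return An object of class `msm_counts`: list with `counts` (n x n matrix),
#'   `lag`, `mode`, `active_set` (increasing state indices), `n_states`.
#' @export
count_transitions <- function(dtrajs, lag, mode = c("sliding", "strided"),
                              n_states = NULL) {
  mode <- match.arg(mode)
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  if (length(dtrajs) == 0L || all(lengths(dtrajs) == 0L)) {
    stop("count_transitions: no trajectory data")
  }
  lag <- as.integer(lag)
  if (is.na(lag) || lag < 1L) stop("count_transitions: lag must be >= 1")
  dtrajs <- lapply(dtrajs, function(d) as.integer(d))
  if (is.null(n_states)) n_states <- max(unlist(dtrajs, use.names = FALSE))
  n <- as.integer(n_states)
  counts <- matrix(0, n, n)
  for (d in dtrajs) {
    if (length(d) <= lag) next
    from_idx <- seq_len(length(d) - lag)
    if (mode == "strided") from_idx <- from_idx[seq(1L, length(from_idx), by = lag)]
    i <- d[from_idx]
    j <- d[from_idx + lag]
    tab <- table(factor(i, levels = seq_len(n)), factor(j, levels = seq_len(n)))
    counts <- counts + unclass(tab)
  }
  dimnames(counts) <- NULL
  structure(list(counts = counts, lag = lag, mode = mode,
                 active_set = largest_connected_set(counts),
                 n_states = n),
            class = "msm_counts")
}

# Largest strongly connected component of the directed graph with an edge
# i -> j wherever counts[i, j] > 0. States with no counts at all are excluded.
largest_connected_set <- function(counts) {
  n <- nrow(counts)
  adj <- (counts > 0) * 1
  diag(adj) <- pmax(diag(adj), (rowSums(counts) + colSums(counts) > 0) * 1)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  # restrict to states observed at all
  seen <- which(rowSums(counts) + colSums(counts) > 0)
  if (length(seen) == 0L) return(integer(0))
  memb <- comp$membership[seen]
  sizes <- table(memb)
  best <- as.integer(names(sizes)[which.max(sizes)])
  sort(seen[memb == best])
}

#' Reversible maximum-likelihood transition matrix
#'
#' Maximises the trajectory likelihood over row-stochastic matrices subject to
#' detailed balance, using the self-consistent fixed-point iteration on
#' symmetric flow variables x_ij:
#' x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j), with x_i = sum_j x_ij and
#' c_i = sum_j c_ij. The estimate is restricted to the active set.
#'
#' @param counts an `msm_counts` object, or a plain count matrix.
#' @param tol convergence tolerance on the max absolute change of T elements.
#' @param max_iter maximum fixed-point iterations.
#' @param lag lag in frames (taken from `counts` when it is an `msm_counts`).
#' @param frame_interval time per frame (ns), carried for unit conversion.
#' @return An object of class `msm_model`: `transition_matrix` (row-stochastic
#'   over the active set), `stationary`, `eigenvalues` (real, descending),
#'   `active_set`, `lag` (frames), `frame_interval` (ns).
#' @export
mle_reversible <- function(counts, tol = 1e-10, max_iter = 10000L,
                           lag = NULL, frame_interval = 1) {
  if (inherits(counts, "msm_counts")) {
    if (is.null(lag)) lag <- counts$lag
    active <- counts$active_set
    C <- counts$counts[active, active, drop = FALSE]
  } else {
    C <- as.matrix(counts)
    active <- seq_len(nrow(C))
    keep <- largest_connected_set(C)
    active <- keep
    C <- C[keep, keep, drop = FALSE]
    if (is.null(lag)) lag <- 1L
  }
  if (length(active) == 0L) stop("mle_reversible: empty active set")
  n <- nrow(C)
  if (n == 1L) {
    T1 <- matrix(1, 1, 1)
    return(new_msm_model(T1, active, lag, frame_interval))
  }
  Csym <- C + t(C)
  ci <- rowSums(C)
  # init: symmetrized counts normalized
  x <- Csym / sum(C)
  converged <- FALSE
  T_old <- x / rowSums(x)
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    x_new <- Csym / denom
    x_new[Csym == 0] <- 0
    x <- x_new
    Tm <- x / rowSums(x)
    delta <- max(abs(Tm - T_old))
    T_old <- Tm
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf("mle_reversible: fixed point not converged at %d iterations (residual %.3g)",
                    max_iter, delta))
  }
  new_msm_model(T_old, active, lag, frame_interval)
}

# Construct an msm_model from a row-stochastic matrix known (or forced) to be
# reversible; stationary vector and real spectrum via the symmetrized form.
new_msm_model <- function(Tm, active_set, lag, frame_interval) {
  pi_v <- stationary_distribution(Tm)
  ev <- reversible_eigen(Tm, pi_v)
  structure(list(transition_matrix = Tm,
                 stationary = pi_v,
                 eigenvalues = ev$values,
                 eigenvectors_right = ev$right,
                 active_set = active_set,
                 lag = lag,
                 frame_interval = frame_interval),
            class = "msm_model")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left Perron eigenvector, normalised to sum 1.
#' @param Tm row-stochastic matrix.
#' @return probability vector.
#' @export
stationary_distribution <- function(Tm) {
  n <- nrow(Tm)
  if (n == 1L) return(1)
  e <- eigen(t(Tm))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- abs(v)
  v / sum(v)
}

# Real spectrum and right eigenvectors of a reversible T via the similar
# symmetric matrix D^{1/2} T D^{-1/2}; values sorted descending.
reversible_eigen <- function(Tm, pi_v = NULL) {
  n <- nrow(Tm)
  if (is.null(pi_v)) pi_v <- stationary_distribution(Tm)
  s <- sqrt(pmax(pi_v, .Machine$double.xmin))
  S <- (s %o% (1 / s)) * Tm
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  vals <- e$values[ord]
  # right eigenvectors of T: psi = D^{-1/2} v
  right <- e$vectors[, ord, drop = FALSE] / s
  # sign convention: first nonzero entry positive
  for (k in seq_len(ncol(right))) {
    nz <- which(abs(right[, k]) > 1e-12)[1]
    if (!is.na(nz) && right[nz, k] < 0) right[, k] <- -right[, k]
  }
  list(values = vals, right = right)
}

#' Implied relaxation timescales across lag times
#'
#' For each lag, estimates a reversible model on the largest connected set and
#' reports t_i(lag) = -lag / log(lambda_i) for eigenvalues in (0, 1), in the
#' time units of `frame_interval`. Also flags the plateau lag: the first lag
#' at which every reported timescale changes by less than `plateau_rtol`
#' relative to the next lag in the list.
#'
#' @param dtrajs discrete trajectories (vector or list).
#' @param lags increasing integer lags in frames.
#' @param n_timescales number of timescales reported per lag.
#' @param frame_interval time per frame (ns).
#' @param mode counting mode passed to [count_transitions()].
#' @param plateau_rtol relative-change threshold defining the plateau.
#' @return list with `table` (data.frame lag, timescale index, timescale in
#'   ns; NA where unavailable), `plateau_lag` (frames; NA when no plateau),
#'   `frame_interval`.
#' @export
implied_timescales <- function(dtrajs, lags, n_timescales = 3,
                               frame_interval = 1, mode = "sliding",
                               plateau_rtol = 0.1) {
  lags <- sort(unique(as.integer(lags)))
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  max_len <- max(lengths(dtrajs))
  if (any(lags >= max_len)) stop("implied_timescales: lag >= trajectory length")
  ts_mat <- matrix(NA_real_, length(lags), n_timescales)
  for (li in seq_along(lags)) {
    lag <- lags[li]
    cm <- count_transitions(dtrajs, lag, mode)
    if (length(cm$active_set) < 2L) next  # disconnected at this lag: reported missing
    m <- mle_reversible(cm, frame_interval = frame_interval)
    lam <- m$eigenvalues
    lam <- lam[-1]                               # drop stationary eigenvalue
    lam <- lam[seq_len(min(n_timescales, length(lam)))]
    ts <- ifelse(lam > 0 & lam < 1, -lag * frame_interval / log(lam),
                 ifelse(lam >= 1, Inf, NA_real_))
    ts_mat[li, seq_along(ts)] <- ts
  }
  plateau <- NA_integer_
  if (length(lags) >= 2L) {
    for (li in seq_len(length(lags) - 1L)) {
      a <- ts_mat[li, ]; b <- ts_mat[li + 1L, ]
      ok <- is.finite(a) & is.finite(b)
      if (!any(ok)) next
      if (all(abs(a[ok] - b[ok]) / pmax(abs(b[ok]), .Machine$double.eps) < plateau_rtol)) {
        plateau <- lags[li]; break
      }
    }
  }
  tab <- data.frame(
    lag_frames = rep(lags, each = n_timescales),
    lag_ns = rep(lags, each = n_timescales) * frame_interval,
    index = rep(seq_len(n_timescales), length(lags)),
    timescale_ns = as.vector(t(ts_mat))
  )
  list(table = tab, plateau_lag = plateau, frame_interval = frame_interval)
}

#' Mean first-passage times by exact linear solve
#'
#' Solves (I - T_restricted) m = lag * 1 on the complement of the target set;
#' `m[i]` is the expected time to first reach the target from state i, in the
#' units implied by `lag_time` (pass the physical lag to get physical times,
#' or 1 to get times in steps).
#'
#' @param Tm row-stochastic matrix.
#' @param target integer indices of the target state set.
#' @param lag_time time per step of `Tm`.
#' @return numeric vector over all states (0 on the target set; Inf where the
#'   target is unreachable).
#' @export
mfpt_to_set <- function(Tm, target, lag_time = 1) {
  n <- nrow(Tm)
  target <- sort(unique(as.integer(target)))
  if (length(target) == 0L || any(target < 1L | target > n)) {
    stop("mfpt_to_set: invalid target set")
  }
  rest <- setdiff(seq_len(n), target)
  m <- numeric(n)
  if (length(rest) > 0L) {
    A <- diag(length(rest)) - Tm[rest, rest, drop = FALSE]
    rhs <- rep(lag_time, length(rest))
    sol <- tryCatch(solve(A, rhs), error = function(e) rep(Inf, length(rest)))
    m[rest] <- sol
  }
  m[!is.finite(m) | m < 0] <- Inf
  m[target] <- 0
  m
}

#' Full pairwise MFPT matrix for a small chain
#'
#' @param Tm row-stochastic matrix.
#' @param lag_time time per step.
#' @return matrix M with M[i, j] = MFPT(i -> j); zero diagonal.
#' @export
mfpt_matrix <- function(Tm, lag_time = 1) {
  n <- nrow(Tm)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) M[, j] <- mfpt_to_set(Tm, j, lag_time)
  M
}

#' Chapman-Kolmogorov test on metastable sets
#'
#' Compares set-to-set transition probabilities predicted by powering the
#' model at its lag, T_macro(k*tau) from T(tau)^k, against the same quantity
#' estimated directly from the data at lag k*tau. Coarse-graining onto the
#' sets uses stationary weighting within each set. Uncertainties for the
#' direct estimates come from a Bayesian transition-matrix ensemble at each
#' tested lag.
#'
#' @param model an `msm_model` estimated at lag tau.
#' @param dtrajs the discrete trajectories the model was estimated from.
#' @param sets list of integer vectors: microstate indices (in active-set
#'   numbering) of each metastable set, e.g. from [pcca_plus()] crisp maps.
#' @param ks integer multiples of the model lag to test (k = 1, 2, ...).
#' @param n_samples Bayesian samples per tested lag for error bars (0 skips).
#' @param seed RNG seed for the Bayesian ensembles.
#' @return list of per-k records: `k`, `predicted` and `estimated` set-to-set
#'   matrices, `est_sd` (NULL when `n_samples = 0`).
#' @export
ck_test <- function(model, dtrajs, sets, ks = 1:5, n_samples = 25L,
                    seed = 1L) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  tau <- model$lag
  n_sets <- length(sets)
  pi_v <- model$stationary
  coarse <- function(Tm, pv) {
    out <- matrix(0, n_sets, n_sets)
    for (a in seq_len(n_sets)) {
      wa <- pv[sets[[a]]]
      wa <- wa / sum(wa)
      for (b in seq_len(n_sets)) {
        out[a, b] <- sum(wa * rowSums(Tm[sets[[a]], sets[[b]], drop = FALSE]))
      }
    }
    out
  }
  Tk <- diag(nrow(model$transition_matrix))
  res <- list()
  for (k in sort(unique(as.integer(ks)))) {
    Tk_target <- matrix_power(model$transition_matrix, k)
    pred <- coarse(Tk_target, pi_v)
    cm <- count_transitions(dtrajs, k * tau, mode = "sliding",
                            n_states = model$active_set[length(model$active_set)])
    # map counts onto the model's active set
    C <- cm$counts[model$active_set, model$active_set, drop = FALSE]
    est <- est_sd <- NULL
    keep <- largest_connected_set(C)
    if (length(keep) == nrow(C)) {
      mk <- mle_reversible(C, lag = k * tau, frame_interval = model$frame_interval)
      est <- coarse(mk$transition_matrix, mk$stationary)
      if (n_samples > 0L) {
        ens <- bayesian_ensemble(C, n_samples = n_samples,
                                 seed = seed + k, lag = k * tau,
                                 frame_interval = model$frame_interval)
        samp <- vapply(ens$samples,
                       function(s) coarse(s$transition_matrix, s$stationary),
                       matrix(0, n_sets, n_sets))
        est_sd <- apply(samp, c(1, 2), stats::sd)
      }
    }
    res[[length(res) + 1L]] <- list(k = k, predicted = pred, estimated = est,
                                    est_sd = est_sd)
  }
  res
}

matrix_power <- function(Tm, k) {
  out <- diag(nrow(Tm))
  P <- Tm
  while (k > 0) {
    if (k %% 2 == 1) out <- out %*% P
    P <- P %*% P
    k <- k %/% 2
  }
  out
}

#' Bayesian ensemble of reversible transition matrices
#'
#' Samples reversible row-stochastic matrices from the posterior implied by
#' the transition counts, via Metropolis-within-Gibbs moves on the symmetric
#' flow parameters x_ij (log-normal proposals on edges with observed counts;
#' the likelihood delta per move is O(1)). Sliding-window counts are rescaled
#' by 1/lag before sampling to correct for overlapping, correlated count
#' pairs. Burn-in and thinning are in whole sweeps over the edge set.
#'
#' @param counts `msm_counts` or plain count matrix (already restricted to a
#'   connected set when plain).
#' @param n_samples ensemble size (default 100).
#' @param seed RNG seed (required).
#' @param burn_in sweeps discarded before collecting.
#' @param thin sweeps between collected samples.
#' @param proposal_sd log-scale proposal standard deviation.
#' @param lag,frame_interval metadata carried onto each sample.
#' @param effective_count_scale divisor applied to the counts (defaults to
#'   `lag` for sliding counts, 1 otherwise).
#' @return `msm_ensemble`: list with `samples` (list of `msm_model`),
#'   `acceptance_rate`, `seed`.
#' @export
bayesian_ensemble <- function(counts, n_samples = 100L, seed,
                              burn_in = 1000L, thin = 10L,
                              proposal_sd = 0.15,
                              lag = NULL, frame_interval = 1,
                              effective_count_scale = NULL) {
  if (missing(seed) || is.null(seed)) stop("bayesian_ensemble: seed is required")
  if (inherits(counts, "msm_counts")) {
    if (is.null(lag)) lag <- counts$lag
    if (is.null(effective_count_scale)) {
      effective_count_scale <- if (counts$mode == "sliding") counts$lag else 1
    }
    active <- counts$active_set
    C <- counts$counts[active, active, drop = FALSE]
  } else {
    C <- as.matrix(counts)
    active <- largest_connected_set(C)
    C <- C[active, active, drop = FALSE]
    if (is.null(lag)) lag <- 1L
    if (is.null(effective_count_scale)) effective_count_scale <- 1
  }
  C <- C / effective_count_scale
  n <- nrow(C)
  rng <- local_rng(seed)
  Csym <- C + t(C)
  ci <- rowSums(C)
  # start from the MLE flows
  mle <- mle_reversible(C, lag = lag, frame_interval = frame_interval)
  x <- mle$transition_matrix * mle$stationary  # pi_i T_ij, symmetric
  x <- (x + t(x)) / 2
  edges <- which(upper.tri(Csym, diag = TRUE) & Csym > 0, arr.ind = TRUE)
  # keep diagonal entries with positive self-counts as sampled too
  n_edges <- nrow(edges)
  xi <- rowSums(x)
  loglik_term <- function() sum(C[Csym > 0] * log((x / xi)[Csym > 0]))
  accepted <- 0L; proposed <- 0L
  samples <- vector("list", n_samples)
  n_sweeps <- burn_in + thin * n_samples
  collected <- 0L
  for (sweep in seq_len(n_sweeps)) {
    u_log <- rng$rnorm(n_edges, 0, proposal_sd)
    u_acc <- rng$runif(n_edges)
    for (e in seq_len(n_edges)) {
      i <- edges[e, 1L]; j <- edges[e, 2L]
      old <- x[i, j]
      new <- old * exp(u_log[e])
      # delta log-likelihood: entries (i,j),(j,i) and row sums i, j change
      if (i == j) {
        d_xi <- new - old
        dll <- C[i, i] * (log(new) - log(old)) - ci[i] * (log(xi[i] + d_xi) - log(xi[i]))
      } else {
        d <- new - old
        dll <- (C[i, j] + C[j, i]) * (log(new) - log(old)) -
          ci[i] * (log(xi[i] + d) - log(xi[i])) -
          ci[j] * (log(xi[j] + d) - log(xi[j]))
      }
      # proposal is symmetric in log space; prior ~ 1/x makes the move
      # Metropolis-balanced for the scale parameterisation
      proposed <- proposed + 1L
      if (log(u_acc[e]) < dll) {
        accepted <- accepted + 1L
        if (i == j) {
          xi[i] <- xi[i] + (new - old)
        } else {
          xi[i] <- xi[i] + (new - old); xi[j] <- xi[j] + (new - old)
          x[j, i] <- new
        }
        x[i, j] <- new
      }
    }
    if (sweep > burn_in && (sweep - burn_in) %% thin == 0L) {
      collected <- collected + 1L
      Tm <- x / xi
      pv <- xi / sum(xi)
      ev <- reversible_eigen(Tm, pv)
      samples[[collected]] <- structure(
        list(transition_matrix = Tm, stationary = pv,
             eigenvalues = ev$values, eigenvectors_right = ev$right,
             active_set = active, lag = lag, frame_interval = frame_interval),
        class = "msm_model")
    }
  }
  rate <- accepted / max(proposed, 1L)
  if (rate < 0.05 || rate > 0.95) {
    warning(sprintf("bayesian_ensemble: acceptance rate %.2f outside [0.05, 0.95]", rate))
  }
  structure(list(samples = samples, acceptance_rate = rate, seed = seed,
                 active_set = active, lag = lag, frame_interval = frame_interval),
            class = "msm_ensemble")
}
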