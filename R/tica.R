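#' Time-lagged independent component analysis
#'
#' Solves the generalized symmetric eigenproblem C_tau v = lambda C_0 v,
#' where C_0 and C_tau are the instantaneous and symmetrised time-lagged
#' covariances of the mean-removed features, pooled over all trajectories.
#' The symmetric (reversible) estimator averages statistics over the frame
#' pairs (t, t+lag) in both time directions, matching the reversible Markov
#' models estimated downstream; `symmetrized = FALSE` uses the plain
#' forward-lagged covariance (symmetrised only for numerical solvability).
#' Small-variance feature directions whose C_0 eigenvalue falls below
#' `regularization` times the largest are projected out before solving.
#'
#' @param features a [feature_trajectory()] or list of them (pooled).
#' @param lag lag time in frames.
#' @param regularization relative eigenvalue floor for C_0.
#' @param symmetrized use the reversible covariance estimator (default TRUE).
#' @return object of class `tica_model`: `lag` (frames), `lag_ns`,
#'   `mean_vector`, `eigenvalues` (descending), `components` (feature-space
#'   vectors, columns, normalised s.t. t(v) C_0 v = 1), `timescales_ns`,
#'   `kept_indices` (initially all), `frame_interval`.
#' @export
estimate_tica <- function(features, lag, regularization = 1e-10,
                          symmetrized = TRUE) {
  trajs <- as_traj_list(features)
  lag <- stopifnot_count(lag, "lag")
  if (any(vapply(trajs, function(x) nrow(x$values), 1L) <= lag)) {
    stop("estimate_tica: every trajectory must be longer than the lag")
  }
  dim_f <- ncol(trajs[[1]]$values)
  if (dim_f < 2L) stop("estimate_tica: need >= 2 features")
  frame_interval <- trajs[[1]]$frame_interval
  # pooled mean over the frames entering the covariance estimates
  s_x <- numeric(dim_f); n_tot <- 0
  for (tr in trajs) {
    X <- tr$values
    n <- nrow(X) - lag
    a <- X[seq_len(n), , drop = FALSE]
    b <- X[seq_len(n) + lag, , drop = FALSE]
    s_x <- s_x + colSums(a) + colSums(b)
    n_tot <- n_tot + n
  }
  mu <- s_x / (2 * n_tot)
  C0 <- matrix(0, dim_f, dim_f)
  Ct <- matrix(0, dim_f, dim_f)
  for (tr in trajs) {
    X <- tr$values
    n <- nrow(X) - lag
    a <- sweep(X[seq_len(n), , drop = FALSE], 2, mu)
    b <- sweep(X[seq_len(n) + lag, , drop = FALSE], 2, mu)
    if (symmetrized) {
      C0 <- C0 + (t(a) %*% a + t(b) %*% b) / 2
      Ct <- Ct + (t(a) %*% b + t(b) %*% a) / 2
    } else {
      C0 <- C0 + t(a) %*% a
      Ct <- Ct + t(a) %*% b
    }
  }
  C0 <- C0 / n_tot
  Ct <- (Ct + t(Ct)) / (2 * n_tot)
  # whiten against C0, flooring small-variance directions
  e0 <- eigen(C0, symmetric = TRUE)
  keep <- e0$values > regularization * max(e0$values)
  if (sum(keep) < 2L) stop("estimate_tica: covariance rank-deficient after flooring")
  W <- e0$vectors[, keep, drop = FALSE] %*% diag(1 / sqrt(e0$values[keep]),
                                                 sum(keep))
  M <- t(W) %*% Ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  lambda <- em$values[ord]
  comps <- W %*% em$vectors[, ord, drop = FALSE]
  lag_ns <- lag * frame_interval
  ts <- ifelse(abs(lambda) < 1 & lambda != 0, -lag_ns / log(abs(lambda)), Inf)
  structure(list(lag = lag, lag_ns = lag_ns, mean_vector = mu,
                 eigenvalues = lambda, components = comps,
                 timescales_ns = ts,
                 kept_indices = seq_along(lambda),
                 frame_interval = frame_interval),
            class = "tica_model")
}

as_traj_list <- function(features) {
  if (inherits(features, "feature_trajectory")) return(list(features))
  if (is.matrix(features)) return(list(feature_trajectory(features, 1)))
  lapply(features, function(f) {
    if (inherits(f, "feature_trajectory")) f else feature_trajectory(as.matrix(f), 1)
  })
}

#' Project feature trajectories onto tICA components
#'
#' @param model a `tica_model`.
#' @param features a [feature_trajectory()], matrix, or list of either.
#' @param components component indices (default: the model's kept indices).
#' @return list of `ic_trajectory` objects (`projections` frames x comps,
#'   `frame_interval`), or a single one if a single trajectory was given.
#' @export
project_tica <- function(model, features, components = model$kept_indices) {
  single <- inherits(features, "feature_trajectory") || is.matrix(features)
  trajs <- as_traj_list(features)
  out <- lapply(trajs, function(tr) {
    Xc <- sweep(tr$values, 2, model$mean_vector)
    structure(list(projections = Xc %*% model$components[, components, drop = FALSE],
                   frame_interval = model$frame_interval),
              class = "ic_trajectory")
  })
  if (single) out[[1]] else out
}

#' Screen tICA components for multimodality
#'
#' Discards fast components whose 1D marginal is adequately described by a
#' single Gaussian: a component is dropped when the single-Gaussian fit beats
#' a 2-component mixture by at least `bic_margin` in BIC (mclust convention:
#' larger BIC is better). The slowest two components are always retained, so
#' the retained set defines an (IC1, IC2) plane.
#'
#' @param model a `tica_model`.
#' @param projections list of `ic_trajectory` over all model components (or
#'   matrix of pooled projections).
#' @param bic_margin strong-evidence margin (default 10).
#' @param max_points subsample size for the mixture fits (seeded, for
#'   determinism and speed).
#' @param seed subsampling seed.
#' @return the model with `kept_indices` replaced; attribute `screen_table`
#'   records per-component BIC differences.
#' @export
screen_components <- function(model, projections, bic_margin = 10,
                              max_points = 10000L, seed = 1L) {
  P <- pool_projections(projections)
  n_comp <- ncol(P)
  if (n_comp < 2L) stop("screen_components: fewer than 2 components")
  rng <- local_rng(seed)
  idx <- if (nrow(P) > max_points) rng$sample_int(nrow(P), max_points) else seq_len(nrow(P))
  delta <- vapply(seq_len(n_comp), function(k) {
    x <- P[idx, k]
    b1 <- suppressWarnings(mclust::mclustBIC(x, G = 1, modelNames = "V",
                                             verbose = FALSE))[1, 1]
    b2 <- suppressWarnings(mclust::mclustBIC(x, G = 2, modelNames = "V",
                                             verbose = FALSE))[1, 1]
    if (is.null(b2) || is.na(b2)) b2 <- -Inf
    as.numeric(b1 - b2)     # >= bic_margin: unimodal, discard
  }, numeric(1))
  keep <- which(delta < bic_margin)
  keep <- sort(union(keep, 1:2))   # never discard below the slowest two
  model$kept_indices <- keep
  attr(model, "screen_table") <- data.frame(component = seq_len(n_comp),
                                            bic_single_minus_mixture = delta,
                                            kept = seq_len(n_comp) %in% keep)
  model
}

pool_projections <- function(projections) {
  if (is.matrix(projections)) return(projections)
  if (inherits(projections, "ic_trajectory")) return(projections$projections)
  do.call(rbind, lapply(projections, function(p) {
    if (inherits(p, "ic_trajectory")) p$projections else as.matrix(p)
  }))
}

#' VAMP-2 score of a discretised or continuous process
#'
#' Sum of squared top singular values of the whitened propagator
#' C00^{-1/2} C0t Ctt^{-1/2} at the given lag, estimated from the data. The
#' stationary process contributes 1, so a one-state system scores exactly 1
#' and a system with k slow processes approaches 1 + sum lambda_i^2.
#'
#' @param x discrete trajectories (integer vectors / list; indicator
#'   features are used) or [feature_trajectory()] data.
#' @param lag lag in frames.
#' @param rank number of singular values summed (default: all available).
#' @param epsilon relative covariance floor.
#' @return scalar score >= 1 (up to sampling error).
#' @export
vamp2_score <- function(x, lag, rank = NULL, epsilon = 1e-10) {
  lag <- stopifnot_count(lag, "lag")
  if (is.list(x) && !inherits(x, "feature_trajectory")) {
    dtraj_like <- all(vapply(x, function(d) is.numeric(d) && is.null(dim(d)), TRUE))
  } else {
    dtraj_like <- is.numeric(x) && is.null(dim(x))
  }
  if (dtraj_like) {
    dl <- if (is.list(x)) x else list(x)
    n_states <- max(unlist(dl, use.names = FALSE))
    trajs <- lapply(dl, function(d) {
      ind <- matrix(0, length(d), n_states)
      ind[cbind(seq_along(d), as.integer(d))] <- 1
      feature_trajectory(ind, 1)
    })
  } else {
    trajs <- as_traj_list(x)
  }
  if (any(vapply(trajs, function(tr) nrow(tr$values), 1L) <= lag)) {
    stop("vamp2_score: insufficient transitions at this lag")
  }
  dim_f <- ncol(trajs[[1]]$values)
  C00 <- C0t <- Ctt <- matrix(0, dim_f, dim_f)
  n_tot <- 0
  for (tr in trajs) {
    X <- tr$values
    n <- nrow(X) - lag
    a <- X[seq_len(n), , drop = FALSE]
    b <- X[seq_len(n) + lag, , drop = FALSE]
    C00 <- C00 + t(a) %*% a
    C0t <- C0t + t(a) %*% b
    Ctt <- Ctt + t(b) %*% b
    n_tot <- n_tot + n
  }
  C00 <- C00 / n_tot; C0t <- C0t / n_tot; Ctt <- Ctt / n_tot
  inv_sqrt <- function(C) {
    e <- eigen((C + t(C)) / 2, symmetric = TRUE)
    keep <- e$values > epsilon * max(e$values)
    e$vectors[, keep, drop = FALSE] %*%
      diag(1 / sqrt(e$values[keep]), sum(keep)) %*%
      t(e$vectors[, keep, drop = FALSE])
  }
  K <- inv_sqrt(C00) %*% C0t %*% inv_sqrt(Ctt)
  sv <- svd(K)$d
  if (!is.null(rank)) {
    if (rank > length(sv)) stop("vamp2_score: rank exceeds available dimensions")
    sv <- sv[seq_len(rank)]
  }
  sum(pmin(sv, 1)^2)
}
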