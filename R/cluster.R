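#' k-means microstate clustering in IC space
#'
#' Deterministic-under-seed k-means: greedy k-means++ seeding from a seeded
#' RNG stream, then Lloyd iterations until the maximum centre shift falls
#' below `tol` or `max_iter` is reached. Frames are assigned to the nearest
#' centre with ties broken by the lower centre index; a cluster left empty is
#' re-seeded to the point farthest from its nearest centre.
#'
#' @param projections an `ic_trajectory`, list of them, or numeric matrix.
#' @param k number of microstates.
#' @param seed integer seed (required).
#' @param max_iter Lloyd iteration cap.
#' @param tol convergence threshold on centre shift.
#' @param fit_stride fit the centres on every `fit_stride`-th pooled frame
#'   (1 = all frames); every frame is then assigned to its nearest centre.
#'   Striding the centre fit is the usual practice for large trajectory sets
#'   and leaves assignments exact.
#' @return object of class `microstate_model`: `centers` (k x dims), `k`,
#'   `seed`, `inertia`, `iterations`, plus `dtrajs`: list of integer
#'   assignment vectors (1-based), one per input trajectory.
#' @export
kmeans_cluster <- function(projections, k, seed, max_iter = 200L,
                           tol = 1e-6, fit_stride = 1L) {
  k <- stopifnot_count(k, "k")
  single <- inherits(projections, "ic_trajectory") || is.matrix(projections)
  plist <- if (single) list(projections) else projections
  mats <- lapply(plist, function(p) {
    m <- if (inherits(p, "ic_trajectory")) p$projections else as.matrix(p)
    storage.mode(m) <- "double"
    m
  })
  lens <- vapply(mats, nrow, 1L)
  X <- do.call(rbind, mats)
  n <- nrow(X)
  if (k > n) stop("kmeans_cluster: k exceeds number of frames")
  fit_stride <- max(1L, as.integer(fit_stride))
  X_all <- X
  if (fit_stride > 1L) {
    X <- X[seq(1L, n, by = fit_stride), , drop = FALSE]
    if (k > nrow(X)) stop("kmeans_cluster: k exceeds strided frame count")
  }
  rng <- local_rng(seed)
  centers <- kmeanspp_init(X, k, rng)
  assign_old <- NULL
  xsq <- rowSums(X^2)
  it <- 0L
  repeat {
    it <- it + 1L
    nearest <- assign_nearest(X, centers, xsq)
    # re-seed empty clusters to the point farthest from its nearest centre
    sizes <- tabulate(nearest$idx, nbins = k)
    for (c_id in which(sizes == 0L)) {
      far <- which.max(nearest$d2)
      centers[c_id, ] <- X[far, ]
      nearest$idx[far] <- c_id
      nearest$d2[far] <- 0
      sizes <- tabulate(nearest$idx, nbins = k)
    }
    sums <- rowsum(X, nearest$idx, reorder = TRUE)
    new_centers <- centers
    new_centers[sort(unique(nearest$idx)), ] <- sums / sizes[sizes > 0L]
    shift <- max(sqrt(rowSums((new_centers - centers)^2)))
    centers <- new_centers
    stable <- !is.null(assign_old) && identical(assign_old, nearest$idx)
    assign_old <- nearest$idx
    if (stable || shift < tol || it >= max_iter) break
  }
  nearest <- assign_nearest(X_all, centers)
  inertia <- sum(nearest$d2)
  dtrajs <- split(nearest$idx, rep(seq_along(lens), lens))
  names(dtrajs) <- NULL
  structure(list(centers = centers, k = k, seed = seed, inertia = inertia,
                 iterations = it, dtrajs = dtrajs),
            class = "microstate_model")
}

# Greedy k-means++ seeding with a seeded stream.
kmeanspp_init <- function(X, k, rng) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  first <- rng$sample_int(n, 1L)
  centers[1L, ] <- X[first, ]
  d2 <- rowSums(sweep(X, 2, centers[1L, ])^2)
  if (k > 1L) for (c_id in 2:k) {
    tot <- sum(d2)
    pick <- if (tot <= 0) {
      rng$sample_int(n, 1L)
    } else {
      u <- rng$runif(1L) * tot
      findInterval(u, cumsum(d2)) + 1L
    }
    pick <- min(pick, n)
    centers[c_id, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2, centers[c_id, ])^2))
  }
  centers
}

# Chunked nearest-centre assignment; ties go to the lower centre index
# (max.col with ties.method = "first" on negated distances).
assign_nearest <- function(X, centers, xsq = rowSums(X^2),
                           chunk = 100000L) {
  n <- nrow(X)
  csq <- rowSums(centers^2)
  idx <- integer(n)
  d2 <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    G <- X[lo:hi, , drop = FALSE] %*% t(centers)
    D <- outer(xsq[lo:hi], csq, "+") - 2 * G
    j <- max.col(-D, ties.method = "first")
    idx[lo:hi] <- j
    d2[lo:hi] <- pmax(D[cbind(seq_len(hi - lo + 1L), j)], 0)
  }
  list(idx = idx, d2 = d2)
}

#' Assign new points to existing microstate centres
#'
#' @param model a `microstate_model`.
#' @param projections matrix or `ic_trajectory`.
#' @return integer vector of 1-based microstate assignments.
#' @export
assign_microstates <- function(model, projections) {
  P <- pool_projections(projections)
  assign_nearest(P, model$centers)$idx
}
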