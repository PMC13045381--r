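#' Free-energy surface on the (IC1, IC2) plane
#'
#' F_bin = -ln(p_bin / p_max) in kT units, from a 2D histogram of the
#' projections, optionally reweighted so that each frame carries the
#' stationary weight of its microstate (pi_micro / frames-in-micro), the
#' standard way of turning adaptively sampled data into an equilibrium
#' surface. The minimum over defined bins is exactly 0; empty bins are
#' masked (NA), never 0.
#'
#' @param projections `ic_trajectory`, list of them, or n x 2 matrix.
#' @param weights optional per-frame weights (recycled over pooled frames).
#' @param bins bin counts per axis (length 1 or 2; default 100).
#' @param pad relative padding of the data extent (default 0.05).
#' @return object of class `free_energy_surface`: `x_edges`, `y_edges`,
#'   `free_energy` (matrix, kT, NA where undefined), `mask`, `probability`.
#' @export
free_energy_surface <- function(projections, weights = NULL, bins = 100,
                                pad = 0.05) {
  P <- pool_projections(projections)
  if (nrow(P) < 2L) stop("free_energy_surface: need >= 2 frames")
  if (ncol(P) < 2L) stop("free_energy_surface: need 2 components")
  P <- P[, 1:2, drop = FALSE]
  if (length(bins) == 1L) bins <- c(bins, bins)
  if (is.null(weights)) weights <- rep(1, nrow(P))
  weights <- rep_len(weights, nrow(P))
  rng_x <- range(P[, 1]); rng_y <- range(P[, 2])
  if (diff(rng_x) == 0 || diff(rng_y) == 0) {
    warning("free_energy_surface: degenerate axis (all frames in one bin)")
    rng_x <- rng_x + c(-0.5, 0.5)
    rng_y <- rng_y + c(-0.5, 0.5)
  }
  ex <- diff(rng_x) * pad; ey <- diff(rng_y) * pad
  x_edges <- seq(rng_x[1] - ex, rng_x[2] + ex, length.out = bins[1] + 1L)
  y_edges <- seq(rng_y[1] - ey, rng_y[2] + ey, length.out = bins[2] + 1L)
  ix <- findInterval(P[, 1], x_edges, rightmost.closed = TRUE)
  iy <- findInterval(P[, 2], y_edges, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), bins[1]); iy <- pmin(pmax(iy, 1L), bins[2])
  H <- matrix(0, bins[1], bins[2])
  tab <- tapply(weights, list(factor(ix, levels = seq_len(bins[1])),
                              factor(iy, levels = seq_len(bins[2]))), sum,
                default = 0)
  H[] <- as.numeric(tab)
  p <- H / sum(H)
  mask <- p > 0
  Fm <- matrix(NA_real_, bins[1], bins[2])
  Fm[mask] <- -log(p[mask] / max(p))
  structure(list(x_edges = x_edges, y_edges = y_edges, free_energy = Fm,
                 mask = mask, probability = p),
            class = "free_energy_surface")
}

#' MSM stationary reweighting factors per frame
#'
#' Weight of a frame = stationary probability of its microstate divided by
#' the number of frames in that microstate.
#'
#' @param dtrajs discrete trajectories (original microstate numbering).
#' @param model an `msm_model` (stationary over its active set).
#' @return numeric vector over pooled frames (0 for frames outside the
#'   active set).
#' @export
msm_frame_weights <- function(dtrajs, model) {
  d <- unlist(dtrajs, use.names = FALSE)
  w <- numeric(length(d))
  counts <- tabulate(d, nbins = max(d))
  for (k in seq_along(model$active_set)) {
    st <- model$active_set[k]
    if (counts[st] > 0) w[d == st] <- model$stationary[k] / counts[st]
  }
  w
}

#' Project reference structures into IC space
#'
#' Featurises reference frames with the same distance pairs used for the
#' simulation data and projects them with the fitted tICA model (no
#' refitting), so experimental reference models can be placed on the
#' free-energy landscape.
#'
#' @param reference_frames `structure_frame` or list of them.
#' @param pairs a [distance_pairs()].
#' @param tica_model a fitted `tica_model`.
#' @param components component indices (default the model's kept pair).
#' @return matrix of IC coordinates, one row per reference frame.
#' @export
project_references <- function(reference_frames, pairs, tica_model,
                               components = tica_model$kept_indices) {
  ft <- pairwise_distances(reference_frames, pairs,
                           frame_interval = tica_model$frame_interval)
  pr <- project_tica(tica_model, ft, components = components)
  pr$projections
}

#' Per-macrostate observable histograms
#'
#' One histogram per macrostate over a common set of bin edges; raw counts
#' conserve the total frame count exactly and the normalised version sums
#' to 1 per state.
#'
#' @param observable per-frame values.
#' @param macro_labels per-frame macrostate indices.
#' @param bins bin count (edges span the pooled observable range) or an
#'   explicit vector of edges.
#' @return list: `edges`, `counts` (macrostates x bins), `probability`
#'   (rows summing to 1), `state_means`.
#' @export
state_histograms <- function(observable, macro_labels, bins = 50) {
  if (length(observable) != length(macro_labels)) {
    stop("state_histograms: label/value length mismatch")
  }
  if (length(bins) == 1L) {
    r <- range(observable)
    if (diff(r) == 0) r <- r + c(-0.5, 0.5)
    edges <- seq(r[1], r[2], length.out = bins + 1L)
  } else {
    edges <- bins
  }
  nb <- length(edges) - 1L
  states <- seq_len(max(macro_labels))
  counts <- matrix(0, length(states), nb)
  for (s in states) {
    v <- observable[macro_labels == s]
    if (length(v) == 0L) next
    ib <- findInterval(v, edges, rightmost.closed = TRUE)
    ib <- pmin(pmax(ib, 1L), nb)
    counts[s, ] <- tabulate(ib, nbins = nb)
  }
  prob <- counts / pmax(rowSums(counts), 1)
  means <- vapply(states, function(s) {
    v <- observable[macro_labels == s]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  list(edges = edges, counts = counts, probability = prob,
       state_means = means)
}
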