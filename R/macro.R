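#' PCCA+ fuzzy coarse-graining of a reversible transition matrix
#'
#' Spectral clustering of the dominant right-eigenvector space into
#' `n_macro` metastable sets. The algorithm identifies simplex vertices in
#' the row space of the first `n_macro` eigenvectors (successive
#' farthest-point search), maps rows to barycentric memberships through the
#' inverse vertex matrix, repairs infeasibilities, and then refines the
#' linear transform by maximising the crispness objective
#' trace(diag(1/colsums) t(chi) diag(pi) chi) over feasible transforms.
#'
#' @param model an `msm_model` (reversible; complex dominant eigenvalues are
#'   rejected).
#' @param n_macro number of macrostates (>= 1, <= number of microstates).
#' @return matrix of memberships (microstates x macrostates), rows summing
#'   to 1, entries in [0, 1].
#' @export
pcca_plus <- function(model, n_macro) {
  n_macro <- stopifnot_count(n_macro, "n_macro")
  n <- nrow(model$transition_matrix)
  if (n_macro > n) stop("pcca_plus: n_macro exceeds number of states")
  if (n_macro == 1L) return(matrix(1, n, 1))
  # exactly decoupled blocks (degenerate unit eigenvalues): the metastable
  # sets are the connected components themselves, and memberships are
  # indicators
  g <- igraph::graph_from_adjacency_matrix((model$transition_matrix > 0) * 1,
                                           mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no == n_macro) {
    chi <- matrix(0, n, n_macro)
    chi[cbind(seq_len(n), comp$membership)] <- 1
    return(chi)
  }
  if (comp$no > n_macro) {
    stop("pcca_plus: more disconnected blocks than requested macrostates")
  }
  # reversible_eigen guarantees a real spectrum; guard against misuse with a
  # directly non-reversible matrix
  ev_direct <- eigen(model$transition_matrix, only.values = TRUE)$values
  dom <- ev_direct[order(Mod(ev_direct), decreasing = TRUE)][seq_len(n_macro)]
  if (any(abs(Im(dom)) > 1e-8)) {
    stop("pcca_plus: complex dominant eigenvalues (non-reversible input)")
  }
  evec <- model$eigenvectors_right[, seq_len(n_macro), drop = FALSE]
  # normalise the stationary eigenvector to exactly 1
  evec[, 1] <- 1
  chi <- pcca_memberships(evec, model$stationary)
  chi
}

# Inner-simplex vertex search + feasible transform + crispness refinement.
pcca_memberships <- function(evec, pi_v) {
  m <- ncol(evec)
  # inner-simplex vertex search: pick the row farthest from the origin,
  # shift it there, then repeatedly pick the farthest row and deflate its
  # direction (Gram-Schmidt)
  ortho <- evec
  verts <- integer(m)
  verts[1] <- which.max(rowSums(ortho^2))
  ortho <- sweep(ortho, 2, ortho[verts[1], ])
  for (j in 2:m) {
    norms <- sqrt(rowSums(ortho^2))
    verts[j] <- which.max(norms)
    v <- ortho[verts[j], ] / norms[verts[j]]
    ortho <- ortho - (ortho %*% v) %*% t(v)
  }
  A <- tryCatch(solve(evec[verts, , drop = FALSE]),
                error = function(e) MASS::ginv(evec[verts, , drop = FALSE]))
  A <- feasible_A(A, evec)
  crispness <- function(A_try) {
    ch <- evec %*% A_try
    w <- colSums(pi_v * ch)
    if (any(w <= 1e-12) || any(ch < -1e-9)) return(-Inf)
    sum(colSums(pi_v * ch^2) / w)
  }
  # refine the free (m-1) x (m-1) block of A, keeping feasibility exact
  if (m > 1) {
    obj <- function(par) {
      A_try <- A
      A_try[-1, -1] <- matrix(par, m - 1, m - 1)
      -crispness(feasible_A(A_try, evec))
    }
    p0 <- as.numeric(A[-1, -1])
    opt <- tryCatch(
      if (length(p0) == 1L) {
        o <- stats::optimize(obj, interval = p0 + c(-10, 10) * (abs(p0) + 1),
                             tol = 1e-12)
        list(par = o$minimum, value = o$objective)
      } else {
        stats::optim(p0, obj, method = "Nelder-Mead",
                     control = list(maxit = 500 * (m - 1)^2, reltol = 1e-12))
      },
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && -opt$value >= crispness(A)) {
      A[-1, -1] <- matrix(opt$par, m - 1, m - 1)
      A <- feasible_A(A, evec)
    }
  }
  chi <- evec %*% A
  chi <- pmin(pmax(chi, 0), 1)
  chi / rowSums(chi)
}

# Enforce the PCCA+ feasibility conditions on A given the free block
# A[2:m, 2:m] (Deuflhard-Weber fill algorithm): the first column absorbs row
# sums so non-constant eigenvector parts cancel in the row sums of chi, the
# first row is set so min_i chi_ij = 0, and A is scaled so rows of chi sum
# to 1.
feasible_A <- function(A, evec) {
  m <- ncol(A)
  if (m > 1) {
    A[-1, 1] <- -rowSums(A[-1, -1, drop = FALSE])
    for (j in seq_len(m)) {
      A[1, j] <- -min(evec[, -1, drop = FALSE] %*% A[-1, j, drop = FALSE])
    }
  }
  A / sum(A[1, ])
}

#' Crisp microstate-to-macrostate map
#'
#' Argmax membership, ties to the lower macrostate index.
#' @param memberships microstates x macrostates matrix.
#' @return integer vector of macrostate indices.
#' @export
crisp_map <- function(memberships) {
  max.col(memberships, ties.method = "first")
}

#' Macrostate stationary populations
#'
#' Population of a macrostate is the sum of the model's stationary
#' probabilities over the microstates mapped to it (not a raw frame
#' fraction). `mode = "frame"` instead counts frames of the supplied
#' discrete trajectories.
#'
#' @param model an `msm_model`.
#' @param crisp integer micro -> macro map over the active set.
#' @param mode `"stationary"` (default) or `"frame"`.
#' @param dtrajs required for `mode = "frame"`: discrete trajectories in
#'   original state numbering.
#' @return probability vector over macrostates.
#' @export
macro_populations <- function(model, crisp, mode = c("stationary", "frame"),
                              dtrajs = NULL) {
  mode <- match.arg(mode)
  n_macro <- max(crisp)
  if (length(crisp) != nrow(model$transition_matrix)) {
    stop("macro_populations: crisp map must cover the active set")
  }
  if (mode == "stationary") {
    as.numeric(tapply(model$stationary, factor(crisp, levels = seq_len(n_macro)), sum,
                      default = 0))
  } else {
    if (is.null(dtrajs)) stop("macro_populations: dtrajs needed in frame mode")
    d <- unlist(dtrajs, use.names = FALSE)
    d <- d[d %in% model$active_set]
    micro <- match(d, model$active_set)
    tab <- tabulate(crisp[micro], nbins = n_macro)
    tab / sum(tab)
  }
}

#' Macrostate mean first-passage time
#'
#' Exact linear solve on the microstate transition matrix: solves
#' (I - T_restricted) m = lag * 1 over the non-target microstates, then
#' averages m over the source macrostate with stationary weights restricted
#' to the source. Reported in microseconds using the model's frame interval
#' (ns).
#'
#' @param model an `msm_model`.
#' @param source,target macrostate indices (distinct).
#' @param crisp micro -> macro map over the active set.
#' @return MFPT in microseconds (Inf when unreachable).
#' @export
macro_mfpt <- function(model, source, target, crisp) {
  if (source == target) stop("macro_mfpt: source and target must differ")
  src <- which(crisp == source)
  tgt <- which(crisp == target)
  if (length(src) == 0L || length(tgt) == 0L) {
    stop("macro_mfpt: empty source or target macrostate")
  }
  lag_ns <- model$lag * model$frame_interval
  m <- mfpt_to_set(model$transition_matrix, tgt, lag_ns)
  w <- model$stationary[src] / sum(model$stationary[src])
  sum(w * m[src]) / 1e3
}

#' Full macrostate MFPT matrix
#'
#' @param model an `msm_model`.
#' @param crisp micro -> macro map.
#' @return n_macro x n_macro matrix in microseconds, zero diagonal.
#' @export
macro_mfpt_matrix <- function(model, crisp) {
  n_macro <- max(crisp)
  M <- matrix(0, n_macro, n_macro)
  for (a in seq_len(n_macro)) for (b in seq_len(n_macro)) {
    if (a != b) M[a, b] <- macro_mfpt(model, a, b, crisp)
  }
  M
}

#' Bayesian uncertainties of macrostate observables
#'
#' Evaluates macrostate populations or the MFPT matrix for every sample of a
#' Bayesian transition-matrix ensemble, holding the crisp map fixed, and
#' returns the across-sample mean and standard deviation. Samples for which
#' an observable is undefined (unreachable target) are excluded and counted.
#'
#' @param ensemble an `msm_ensemble`.
#' @param crisp micro -> macro map over the ensemble's active set.
#' @param observable `"population"` or `"mfpt"`.
#' @return list: `mean`, `sd` (vector for populations, matrix for MFPTs, in
#'   microseconds), `n_excluded`.
#' @export
macro_uncertainty <- function(ensemble, crisp,
                              observable = c("population", "mfpt")) {
  observable <- match.arg(observable)
  if (length(ensemble$samples) == 0L) stop("macro_uncertainty: empty ensemble")
  vals <- lapply(ensemble$samples, function(s) {
    if (observable == "population") macro_populations(s, crisp)
    else macro_mfpt_matrix(s, crisp)
  })
  finite <- vapply(vals, function(v) all(is.finite(v)), TRUE)
  n_excl <- sum(!finite)
  vals <- vals[finite]
  if (length(vals) == 0L) stop("macro_uncertainty: observable undefined in all samples")
  arr <- simplify2array(vals)
  if (observable == "population") {
    list(mean = rowMeans(arr), sd = apply(arr, 1, stats::sd), n_excluded = n_excl)
  } else {
    list(mean = apply(arr, c(1, 2), mean), sd = apply(arr, c(1, 2), stats::sd),
         n_excluded = n_excl)
  }
}

#' Order macrostates by a per-frame openness observable
#'
#' Macrostates are labelled Closed/Ic/Io/Eo by ascending mean openness
#' (e.g. catalytic-site accessibility or the summed-distance reward), since
#' the raw PCCA+ output order is arbitrary.
#'
#' @param observable per-frame openness values.
#' @param macro_labels per-frame macrostate indices (same length).
#' @return integer permutation: `order` such that `order[1]` is the most
#'   closed macrostate; also returned as `rank` (old index -> rank).
#' @export
openness_order <- function(observable, macro_labels) {
  if (length(observable) != length(macro_labels)) {
    stop("openness_order: length mismatch")
  }
  means <- tapply(observable, macro_labels, mean)
  ord <- as.integer(names(sort(means)))
  rank <- match(seq_len(max(macro_labels)), ord)
  list(order = ord, rank = rank, state_means = means[as.character(ord)])
}
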