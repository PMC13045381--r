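#' Distance pair set
#'
#' Ordered list of atom-index pairs, optionally tagged by the interdomain
#' interface each pair spans (the opening reward of the sampling campaign
#' sums 127 such pairs spread over the four interfaces between the catalytic
#' domain and the neighbouring cysteine-rich / stalk regions).
#'
#' @param pairs 2-column integer matrix of atom indices.
#' @param interface_tags optional per-pair labels.
#' @return object of class `distance_pairs`.
#' @export
distance_pairs <- function(pairs, interface_tags = NULL) {
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("pairs must have two columns")
  storage.mode(pairs) <- "integer"
  if (any(pairs[, 1] == pairs[, 2])) stop("pair indices must be distinct within a pair")
  if (!is.null(interface_tags) && length(interface_tags) != nrow(pairs)) {
    stop("interface_tags length must equal pair count")
  }
  structure(list(pairs = pairs, interface_tags = interface_tags,
                 count = nrow(pairs)),
            class = "distance_pairs")
}

#' Read a distance pair set from delimited text
#'
#' Two columns (atom i, atom j) or three (atom i, atom j, interface tag),
#' whitespace- or comma-separated, `#` comments allowed.
#' @param path file path.
#' @return a [distance_pairs()].
#' @export
read_distance_pairs <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           sep = "", stringsAsFactors = FALSE)
  tags <- if (ncol(tab) >= 3L) as.character(tab[[3]]) else NULL
  distance_pairs(cbind(as.integer(tab[[1]]), as.integer(tab[[2]])), tags)
}

#' Feature trajectory container
#'
#' @param values frames x features numeric matrix (Angstrom for distances).
#' @param frame_interval ns per frame.
#' @param feature_names optional column labels.
#' @return object of class `feature_trajectory`.
#' @export
feature_trajectory <- function(values, frame_interval, feature_names = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("feature values must be finite")
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length must equal column count")
  }
  structure(list(values = values, frame_interval = frame_interval,
                 feature_names = feature_names),
            class = "feature_trajectory")
}

#' Pairwise atom distances over frames
#'
#' @param frames a `structure_frame` or list of them.
#' @param pairs a [distance_pairs()].
#' @param frame_interval ns per frame for the resulting trajectory.
#' @return a [feature_trajectory()] of Euclidean distances in Angstrom.
#' @export
pairwise_distances <- function(frames, pairs, frame_interval = 1) {
  if (inherits(frames, "structure_frame")) frames <- list(frames)
  if (length(frames) == 0L) stop("pairwise_distances: zero frames")
  vals <- t(vapply(frames, function(fr) {
    n <- nrow(fr$coords)
    if (any(pairs$pairs > n) || any(pairs$pairs < 1L)) {
      stop("pairwise_distances: atom index out of range")
    }
    d <- fr$coords[pairs$pairs[, 1], , drop = FALSE] -
      fr$coords[pairs$pairs[, 2], , drop = FALSE]
    sqrt(rowSums(d^2))
  }, numeric(pairs$count)))
  if (pairs$count == 1L) vals <- matrix(vals, ncol = 1L)
  feature_trajectory(vals, frame_interval,
                     paste0("d_", pairs$pairs[, 1], "_", pairs$pairs[, 2]))
}

#' Summed-distance opening reward
#'
#' Per-frame sum of selected distance features, reported in nanometres
#' (features are Angstrom; 1 nm = 10 A).
#'
#' @param features a [feature_trajectory()] of distances (Angstrom).
#' @param pair_subset feature column indices to sum (default: all).
#' @return numeric vector, one reward per frame, nm.
#' @export
reward_sum <- function(features, pair_subset = NULL) {
  vals <- if (inherits(features, "feature_trajectory")) features$values else as.matrix(features)
  if (is.null(pair_subset)) pair_subset <- seq_len(ncol(vals))
  if (length(pair_subset) == 0L) stop("reward_sum: empty pair subset")
  if (any(pair_subset < 1L | pair_subset > ncol(vals))) {
    stop("reward_sum: subset index out of range")
  }
  rowSums(vals[, pair_subset, drop = FALSE]) / 10
}

#' Count lipid contacts with a protein domain
#'
#' A lipid molecule is in contact when any of its atoms lies within `cutoff`
#' of any atom of the domain (the criterion is any lipid-protein atom pair
#' within the cutoff; counting is per distinct lipid molecule by default).
#' `per_residue = TRUE` returns, per domain residue, the number of contacting
#' lipid molecules. `count_atom_pairs = TRUE` switches to counting atom pairs
#' within the cutoff instead of molecules.
#'
#' @param frame a `structure_frame`.
#' @param domain molecule-class label of the protein domain.
#' @param species_filter `"any"` (default), `"POPC"`, or `"POPS"`.
#' @param cutoff contact cutoff, Angstrom (pair counted when distance <= cutoff).
#' @param per_residue logical.
#' @param count_atom_pairs logical; count atom pairs instead of molecules.
#' @return integer count, or named integer vector in per-residue mode.
#' @export
count_lipid_contacts <- function(frame, domain, species_filter = "any",
                                 cutoff = 4.0, per_residue = FALSE,
                                 count_atom_pairs = FALSE) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  prot <- select_atoms(frame, domain = domain)
  if (length(prot) == 0L) stop(sprintf("unknown domain '%s'", domain))
  species <- c("POPC", "POPS")
  if (!identical(species_filter, "any")) {
    if (!species_filter %in% species) {
      stop(sprintf("unknown species '%s'", species_filter))
    }
    species <- species_filter
  }
  lip <- which(frame$atoms$molecule_class %in% species)
  if (length(lip) == 0L) {
    if (per_residue) {
      res <- sort(unique(frame$atoms$residue_id[prot]))
      return(stats::setNames(integer(length(res)), res))
    }
    return(0L)
  }
  # all-pairs distances protein-domain atoms x lipid atoms
  pc <- frame$coords[prot, , drop = FALSE]
  lc <- frame$coords[lip, , drop = FALSE]
  d2 <- outer(rowSums(pc^2), rowSums(lc^2), "+") - 2 * pc %*% t(lc)
  close <- d2 <= cutoff^2 + 1e-12
  lip_mol <- frame$atoms$molecule_id[lip]
  if (per_residue) {
    res_ids <- frame$atoms$residue_id[prot]
    res <- sort(unique(res_ids))
    out <- vapply(res, function(r) {
      hit <- close[res_ids == r, , drop = FALSE]
      if (count_atom_pairs) sum(hit) else length(unique(lip_mol[colSums(hit) > 0]))
    }, integer(1))
    return(stats::setNames(out, res))
  }
  if (count_atom_pairs) return(sum(close))
  length(unique(lip_mol[colSums(close) > 0]))
}

#' Centre-of-mass distance between two residue selections
#'
#' @param frame a `structure_frame`.
#' @param residue_set_a,residue_set_b residue ids.
#' @param weights `"uniform"` (default; pseudo-atoms carry no masses) or a
#'   numeric per-atom weight vector covering all atoms of the frame.
#' @return distance between the weighted centroids, Angstrom.
#' @export
com_distance <- function(frame, residue_set_a, residue_set_b,
                         weights = "uniform") {
  centroid <- function(res) {
    idx <- which(frame$atoms$residue_id %in% res)
    if (length(idx) == 0L) stop("com_distance: empty residue selection")
    w <- if (identical(weights, "uniform")) rep(1, length(idx)) else weights[idx]
    colSums(frame$coords[idx, , drop = FALSE] * w) / sum(w)
  }
  sqrt(sum((centroid(residue_set_a) - centroid(residue_set_b))^2))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation + translation minimising the RMSD of the
#' `align_on` selection of `mobile` onto the corresponding selection of
#' `reference` (matched by residue id order), applies it to every mobile
#' atom, and reports the post-fit RMSD over the aligned atoms.
#'
#' @param mobile,reference `structure_frame`s.
#' @param align_on residue ids used for the fit; the two selections must have
#'   equal atom counts in corresponding order.
#' @return list: `frame` (transformed mobile), `rmsd` (Angstrom), `rotation`
#'   (3 x 3), `translation` (length 3).
#' @export
superimpose <- function(mobile, reference, align_on) {
  mi <- which(mobile$atoms$residue_id %in% align_on)
  ri <- which(reference$atoms$residue_id %in% align_on)
  if (length(mi) != length(ri)) stop("superimpose: mismatched selection sizes")
  if (length(mi) < 3L) stop("superimpose: need at least 3 aligned atoms")
  X <- mobile$coords[mi, , drop = FALSE]
  Y <- reference$coords[ri, , drop = FALSE]
  xc <- colMeans(X); yc <- colMeans(Y)
  X0 <- sweep(X, 2, xc); Y0 <- sweep(Y, 2, yc)
  s <- svd(t(X0) %*% Y0)
  if (min(s$d) < 1e-10 && sum(s$d > 1e-10) < 2L) {
    stop("superimpose: degenerate (collinear) alignment selection")
  }
  d <- sign(det(s$v %*% t(s$u)))
  Rmat <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)   # proper rotation, no reflection
  trans <- yc - as.numeric(Rmat %*% xc)
  new_coords <- t(Rmat %*% t(mobile$coords)) +
    matrix(trans, nrow(mobile$coords), 3, byrow = TRUE)
  out <- mobile
  out$coords <- new_coords
  rmsd <- sqrt(mean(rowSums((new_coords[mi, , drop = FALSE] - Y)^2)))
  list(frame = out, rmsd = rmsd, rotation = Rmat, translation = trans)
}

#' Membrane-clash test for a rigid body
#'
#' A clash is called when at least one atom of the body lies inside the
#' membrane slab deeper than `penetration_min` from the nearer slab face
#' (grazing contacts shallower than that are not clashes).
#'
#' @param frame a `structure_frame`.
#' @param body molecule-class label(s) of the body (e.g. the Fab chains
#'   `c("H", "L")`).
#' @param slab optional z-interval list; defaults to the frame's slab.
#' @param penetration_min minimum penetration depth, Angstrom.
#' @return list: `clash` (logical), `n_clashing` (atom count).
#' @export
membrane_clash <- function(frame, body = c("H", "L"), slab = NULL,
                           penetration_min = 1.0) {
  if (is.null(slab)) slab <- frame$slab
  if (is.null(slab)) stop("membrane_clash: no slab available")
  if (slab$z_lo >= slab$z_hi) stop("membrane_clash: inverted slab bounds")
  idx <- select_atoms(frame, class = body)
  if (length(idx) == 0L) stop("membrane_clash: no body atoms present")
  z <- frame$coords[idx, 3]
  depth <- pmin(z - slab$z_lo, slab$z_hi - z)   # negative outside the slab
  n <- sum(depth > penetration_min)
  list(clash = n > 0L, n_clashing = n)
}
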