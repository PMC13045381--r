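#' Simulate hidden-macrostate trajectories with Gaussian emissions
#'
#' Samples the fixture's macrostate jump chain (initial states from the
#' stationary distribution) and emits, per frame, a feature vector equal to
#' the current state's emission mean plus an AR(1)-correlated Gaussian
#' deviation: a_t = ar * a_(t-1) + sqrt(1 - ar^2) * sd(s_t) * eps_t. The
#' deviation construction keeps per-state sample means unbiased at the
#' emission means while giving intra-state frame-to-frame correlation `ar`.
#' Output is bit-for-bit reproducible for identical arguments.
#'
#' @param fixture a [kinetic_fixture()].
#' @param n_frames frames per trajectory (>= 2).
#' @param n_traj number of trajectories.
#' @param seed integer seed (required); trajectory i uses stream `seed + i - 1`
#'   when `seeds` is not given.
#' @param feature_dim number of emitted dimensions (>= 2, at most the
#'   fixture's emission columns).
#' @param seeds optional explicit per-trajectory seeds (length `n_traj`).
#' @return list of `latent_trajectory` objects: `features` (frames x dims),
#'   `macrostate_labels` (1-based), `frame_interval`, `seed`.
#' @export
simulate_latent <- function(fixture, n_frames, n_traj = 1L, seed,
                            feature_dim = ncol(fixture$emission_means),
                            seeds = NULL) {
  if (missing(seed) && is.null(seeds)) stop("simulate_latent: seed is required")
  n_frames <- stopifnot_count(n_frames, "n_frames")
  n_traj <- stopifnot_count(n_traj, "n_traj")
  if (n_frames < 2L) stop("n_frames must be >= 2")
  if (feature_dim < 2L) stop("feature_dim must be >= 2")
  if (feature_dim > ncol(fixture$emission_means)) {
    stop("feature_dim exceeds fixture emission dimensions")
  }
  if (is.null(seeds)) seeds <- seed + seq_len(n_traj) - 1L
  if (length(seeds) != n_traj) stop("seeds must have length n_traj")
  lapply(seq_len(n_traj), function(ti) {
    simulate_latent_one(fixture, n_frames, as.integer(seeds[ti]), feature_dim)
  })
}

simulate_latent_one <- function(fixture, n_frames, seed, feature_dim) {
  rng <- local_rng(seed)
  n <- fixture$n_states
  cumT <- t(apply(fixture$transition_matrix, 1, cumsum))
  u <- rng$runif(n_frames)
  s <- integer(n_frames)
  s[1] <- findInterval(u[1], cumsum(fixture$stationary)) + 1L
  if (s[1] > n) s[1] <- n
  for (t in 2L:n_frames) {
    k <- findInterval(u[t], cumT[s[t - 1L], ]) + 1L
    s[t] <- if (k > n) n else k
  }
  mu <- fixture$emission_means[, seq_len(feature_dim), drop = FALSE]
  sd_m <- fixture$emission_sds[, seq_len(feature_dim), drop = FALSE]
  ar <- fixture$ar_coefficient
  eps <- matrix(rng$rnorm(n_frames * feature_dim), n_frames, feature_dim)
  innov <- sqrt(1 - ar^2) * sd_m[s, , drop = FALSE] * eps
  innov[1L, ] <- sd_m[s[1L], ] * eps[1L, ]   # start at per-state stationary sd
  dev <- apply(innov, 2, function(col) {
    as.numeric(stats::filter(col, ar, method = "recursive"))
  })
  feats <- mu[s, , drop = FALSE] + dev
  structure(list(features = feats, macrostate_labels = s,
                 frame_interval = fixture$frame_interval, seed = seed),
            class = "latent_trajectory")
}

#' Toy 2D energy landscape for Brownian dynamics
#'
#' Potential built from inverted Gaussian wells:
#' U(x) = -sum_k depth_k * exp(-|x - c_k|^2 / (2 w_k^2)), in kT-like energy
#' units.
#'
#' @param well_centers list (or 2-column matrix) of 2D well centres.
#' @param well_depths positive depths, energy units.
#' @param barrier_widths per-well Gaussian widths (length units).
#' @param diffusion_coefficient mobility/diffusion scale.
#' @param timestep integration step.
#' @return object of class `toy_landscape` with `potential(x)` and
#'   `gradient(x)` closures.
#' @export
toy_landscape <- function(well_centers, well_depths, barrier_widths,
                          diffusion_coefficient = 1, timestep = 1e-3) {
  if (is.list(well_centers)) well_centers <- do.call(rbind, well_centers)
  well_centers <- as.matrix(well_centers)
  if (nrow(well_centers) < 2L) stop("toy_landscape: need >= 2 wells")
  if (any(well_depths <= 0)) stop("toy_landscape: well depths must be > 0")
  if (length(barrier_widths) == 1L) {
    barrier_widths <- rep(barrier_widths, nrow(well_centers))
  }
  potential <- function(x) {
    d2 <- colSums((t(well_centers) - x)^2)
    -sum(well_depths * exp(-d2 / (2 * barrier_widths^2)))
  }
  gradient <- function(x) {
    d <- t(x - t(well_centers))               # wells x 2, x - c_k
    d2 <- rowSums(d^2)
    w <- well_depths * exp(-d2 / (2 * barrier_widths^2)) / barrier_widths^2
    colSums(w * d)
  }
  structure(list(well_centers = well_centers, well_depths = well_depths,
                 barrier_widths = barrier_widths,
                 diffusion_coefficient = diffusion_coefficient,
                 timestep = timestep,
                 potential = potential, gradient = gradient),
            class = "toy_landscape")
}

#' Overdamped Brownian dynamics on a toy landscape
#'
#' Euler-Maruyama integration of dx = -D grad U dt + sqrt(2 D kT dt) xi,
#' whose stationary density is proportional to exp(-U / kT). With `kT = 0`
#' the dynamics is pure gradient descent.
#'
#' @param landscape a [toy_landscape()].
#' @param n_steps number of steps.
#' @param kT thermal energy (same units as well depths).
#' @param seed integer seed (required).
#' @param start 2D start position.
#' @return matrix (n_steps + 1) x 2 of positions, including the start.
#' @export
simulate_brownian <- function(landscape, n_steps, kT, seed, start) {
  n_steps <- stopifnot_count(n_steps, "n_steps")
  rng <- local_rng(seed)
  D <- landscape$diffusion_coefficient
  dt <- landscape$timestep
  # drift-step bound: the steepest Gaussian-well gradient is
  # depth * exp(-1/2) / width; require the resulting step << barrier width
  max_grad <- max(landscape$well_depths * exp(-0.5) / landscape$barrier_widths)
  if (max_grad * D * dt >= min(landscape$barrier_widths)) {
    stop("simulate_brownian: timestep too large (max drift per step exceeds barrier width)")
  }
  noise_sd <- sqrt(2 * D * kT * dt)
  xi <- matrix(rng$rnorm(n_steps * 2), n_steps, 2)
  pos <- matrix(0, n_steps + 1L, 2)
  pos[1L, ] <- start
  x <- as.numeric(start)
  for (t in seq_len(n_steps)) {
    x <- x - D * landscape$gradient(x) * dt + noise_sd * xi[t, ]
    if (any(!is.finite(x))) {
      stop(sprintf("simulate_brownian: divergent step at t = %d (position %s)",
                   t, paste(signif(x, 4), collapse = ", ")))
    }
    pos[t + 1L, ] <- x
  }
  pos
}

#' Build a labelled toy protein/membrane/lipid complex
#'
#' Emits a single [structure_frame()]: protein pseudo-atoms grouped into named
#' domains, lipid pseudo-molecules of declared species at declared in-plane
#' positions (head-group atoms placed at the slab faces), and optionally a
#' rigid Fab pseudo-body at a declared offset. Atom placement jitters
#' deterministically under `seed`.
#'
#' @param domains list of `list(name =, n_atoms =, center = c(x, y, z))`;
#'   `residue_start` optionally sets the first residue id.
#' @param lipids optional list of `list(species = "POPC"|"POPS",
#'   position = c(x, y), leaflet = "upper"|"lower", n_atoms =)`.
#' @param slab list `list(z_lo =, z_hi =, half_width =)`.
#' @param fab optional list `list(offset = c(x, y, z), n_atoms =)`; two chains
#'   H and L are placed around the offset.
#' @param seed integer seed (required).
#' @param jitter placement jitter scale, Angstrom.
#' @return a `structure_frame`.
#' @export
build_toy_complex <- function(domains, lipids = list(), slab, fab = NULL,
                              seed, jitter = 1.5) {
  rng <- local_rng(seed)
  coords <- NULL
  atoms <- NULL
  mol_id <- 0L
  res_id <- 0L
  add <- function(xyz, res_ids, res_name, m_id, m_class) {
    coords <<- rbind(coords, xyz)
    atoms <<- rbind(atoms, data.frame(residue_id = res_ids,
                                      residue_name = res_name,
                                      molecule_id = m_id,
                                      molecule_class = m_class))
  }
  seen_names <- character(0)
  for (d in domains) {
    mol_id <- mol_id + 1L
    if (d$name %in% seen_names) stop("overlapping molecule ids: duplicate domain name")
    seen_names <- c(seen_names, d$name)
    n <- d$n_atoms
    start <- if (!is.null(d$residue_start)) d$residue_start else res_id + 1L
    res_id <- start + n - 1L
    xyz <- matrix(rep(d$center, each = n), n, 3) +
      matrix(rng$rnorm(n * 3, 0, jitter), n, 3)
    add(xyz, seq(start, length.out = n), d$name, mol_id, d$name)
  }
  for (lp in lipids) {
    mol_id <- mol_id + 1L
    res_id <- res_id + 1L
    n <- if (!is.null(lp$n_atoms)) lp$n_atoms else 4L
    leaflet <- if (!is.null(lp$leaflet)) lp$leaflet else "upper"
    z_head <- if (leaflet == "upper") slab$z_hi else slab$z_lo
    z_dir <- if (leaflet == "upper") -1 else 1
    z <- z_head + z_dir * seq(0, 4 * (n - 1L), length.out = n)
    xyz <- cbind(lp$position[1] + rng$rnorm(n, 0, 0.5),
                 lp$position[2] + rng$rnorm(n, 0, 0.5),
                 z)
    if (!lp$species %in% c("POPC", "POPS")) {
      stop(sprintf("unknown lipid species '%s'", lp$species))
    }
    add(xyz, rep(res_id, n), lp$species, mol_id, lp$species)
  }
  if (!is.null(fab)) {
    for (chain in c("H", "L")) {
      mol_id <- mol_id + 1L
      n <- max(2L, fab$n_atoms %/% 2L)
      side <- if (chain == "H") -3 else 3
      ctr <- fab$offset + c(side, 0, 0)
      xyz <- matrix(rep(ctr, each = n), n, 3) +
        matrix(rng$rnorm(n * 3, 0, jitter), n, 3)
      add(xyz, seq(res_id + 1L, length.out = n), paste0("FAB_", chain),
          mol_id, chain)
      res_id <- res_id + n
    }
  }
  structure_frame(coords, atoms, slab = slab)
}
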