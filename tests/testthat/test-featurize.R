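make_frame <- function(coords) {
  n <- nrow(coords)
  structure_frame(coords,
                  data.frame(residue_id = seq_len(n),
                             residue_name = "GLY",
                             molecule_id = 1L,
                             molecule_class = "MpD"))
}

test_that("pairwise distances are Euclidean, rigid-motion invariant and match brute force", {
  fr <- make_frame(rbind(c(0, 0, 0), c(3, 4, 0)))
  ft <- pairwise_distances(fr, distance_pairs(cbind(1L, 2L)))
  expect_equal(as.numeric(ft$values), 5)
  # random frame, many pairs, vs an independent full distance matrix
  set.seed(20)
  X <- matrix(rnorm(60, sd = 10), 20, 3)
  pr <- distance_pairs(cbind(sample(1:20, 30, TRUE),
                             (sample(1:19, 30, TRUE))))
  pr$pairs[pr$pairs[, 1] == pr$pairs[, 2], 2] <-
    pr$pairs[pr$pairs[, 1] == pr$pairs[, 2], 2] + 1L
  fr <- make_frame(X)
  got <- pairwise_distances(fr, pr)$values
  D <- as.matrix(stats::dist(X))
  expect_equal(as.numeric(got), D[pr$pairs], tolerance = 1e-12)
  # any rigid motion leaves the feature row unchanged to 1e-9
  for (sd_rot in 1:3) {
    Q <- random_rotation(sd_rot)
    shift <- c(5, -2, 9) * sd_rot
    fr_rot <- make_frame(t(Q %*% t(X)) + matrix(shift, 20, 3, byrow = TRUE))
    expect_equal(pairwise_distances(fr_rot, pr)$values, got,
                 tolerance = 1e-9)
  }
  expect_error(pairwise_distances(list(), pr), "zero frames")
  expect_error(pairwise_distances(fr, distance_pairs(cbind(1L, 99L))),
               "out of range")
})

test_that("pair tables load from delimited text with interface tags", {
  path <- system.file("extdata", "example_reward_pairs.tsv",
                      package = "openmsm")
  pr <- read_distance_pairs(path)
  expect_equal(pr$count, 127L)           # the full opening-reward set size
  expect_length(unique(pr$interface_tags), 4L)
  expect_true(all(pr$pairs[, 1] != pr$pairs[, 2]))
  # two-column files load without tags
  p2 <- tempfile()
  writeLines(c("1 2", "3 4"), p2)
  pr2 <- read_distance_pairs(p2)
  expect_equal(pr2$count, 2L)
  expect_null(pr2$interface_tags)
})

test_that("the opening reward sums selected distances in nm and is homogeneous", {
  ft <- feature_trajectory(matrix(c(30, 40, 50), 1, 3), 1)
  expect_equal(reward_sum(ft), 12.0)
  expect_equal(reward_sum(ft, c(1, 3)), 8.0)
  expect_error(reward_sum(ft, integer(0)), "empty")
  # uniform coordinate scaling x2 doubles the reward
  set.seed(4)
  X <- matrix(rnorm(30, sd = 8), 10, 3)
  pr <- distance_pairs(cbind(1:5, 6:10))
  r1 <- reward_sum(pairwise_distances(make_frame(X), pr))
  r2 <- reward_sum(pairwise_distances(make_frame(2 * X), pr))
  expect_equal(r2, 2 * r1, tolerance = 1e-12)
  # a visibly opened complex scores strictly higher than a compact one
  closed <- make_frame(rbind(c(0, 0, 0), c(5, 0, 0)))
  open <- make_frame(rbind(c(0, 0, 0), c(40, 0, 0)))
  p1 <- distance_pairs(cbind(1L, 2L))
  expect_gt(reward_sum(pairwise_distances(open, p1)),
            reward_sum(pairwise_distances(closed, p1)))
})

test_that("lipid contacts count molecules, respect the cutoff and match the all-pairs oracle", {
  slab <- list(z_lo = -20, z_hi = 0, half_width = 40)
  # one lipid with two atoms both within 3 A: one molecule, two atom pairs
  fr <- build_toy_complex(list(list(name = "CrD", n_atoms = 1, center = c(0, 0, 10))),
                          list(list(species = "POPS", position = c(0, 0), n_atoms = 2)),
                          slab, seed = 1, jitter = 0)
  fr$coords[2, ] <- c(0, 0, 7.5)
  fr$coords[3, ] <- c(0, 0, 7.0)
  expect_equal(count_lipid_contacts(fr, "CrD"), 1L)
  expect_equal(count_lipid_contacts(fr, "CrD", count_atom_pairs = TRUE), 2L)
  expect_error(count_lipid_contacts(fr, "CrD", species_filter = "CHOL"),
               "unknown species")
  # randomized 50-lipid complex vs brute-force double loop, both modes,
  # plus monotonicity in the cutoff
  lips <- lapply(1:50, function(i) {
    list(species = if (i %% 3 == 0) "POPS" else "POPC",
         position = c(stats::runif(1, -15, 15), stats::runif(1, -15, 15)),
         n_atoms = 3)
  })
  fr <- build_toy_complex(list(list(name = "CrD", n_atoms = 12, center = c(0, 0, 2))),
                          lips, slab, seed = 77)
  prev <- 0L
  for (cut in c(2, 4, 6, 9)) {
    got <- count_lipid_contacts(fr, "CrD", cutoff = cut)
    expect_identical(got, brute_contacts(fr, "CrD", cutoff = cut))
    expect_gte(got, prev)
    prev <- got
  }
  expect_identical(count_lipid_contacts(fr, "CrD", species_filter = "POPS"),
                   brute_contacts(fr, "CrD", species = "POPS"))
  expect_identical(count_lipid_contacts(fr, "CrD", count_atom_pairs = TRUE),
                   brute_contacts(fr, "CrD", atom_pairs = TRUE))
  # per-residue mode: counts per residue sum >= molecule count and each
  # residue's count equals the oracle restricted to that residue
  per_res <- count_lipid_contacts(fr, "CrD", per_residue = TRUE)
  expect_named(per_res)
  one_res <- fr
  keep <- fr$atoms$residue_id == as.integer(names(per_res)[1]) |
    fr$atoms$molecule_class %in% c("POPC", "POPS")
  one_res$coords <- fr$coords[keep, ]
  one_res$atoms <- fr$atoms[keep, ]
  expect_equal(unname(per_res[1]), brute_contacts(one_res, "CrD"))
})

test_that("centre-of-mass distances reduce to centroid geometry", {
  fr <- make_frame(rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_equal(com_distance(fr, 1, 2), 6)
  # symmetric two-atom groups mirrored about the origin: distance is twice
  # the centroid offset
  fr2 <- make_frame(rbind(c(1, 2, 0), c(3, -2, 0), c(-1, -2, 0), c(-3, 2, 0)))
  expect_equal(com_distance(fr2, c(1, 2), c(3, 4)), 2 * 2)
  # mass weights match an independent centroid computation
  set.seed(9)
  X <- matrix(rnorm(24), 8, 3)
  fr3 <- make_frame(X)
  w <- stats::runif(8, 0.5, 3)
  got <- com_distance(fr3, 1:4, 5:8, weights = w)
  c1 <- colSums(X[1:4, ] * w[1:4]) / sum(w[1:4])
  c2 <- colSums(X[5:8, ] * w[5:8]) / sum(w[5:8])
  expect_equal(got, sqrt(sum((c1 - c2)^2)), tolerance = 1e-12)
  expect_error(com_distance(fr, 99, 1), "empty")
})

test_that("superposition recovers known rigid motions and is optimal", {
  set.seed(15)
  X <- matrix(rnorm(36, sd = 5), 12, 3)
  ref <- make_frame(X)
  self <- superimpose(ref, ref, align_on = 1:12)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  expect_equal(self$rotation, diag(3), tolerance = 1e-8)
  for (sd_rot in 4:6) {
    Q <- random_rotation(sd_rot)
    moved <- make_frame(t(Q %*% t(X)) + matrix(c(3, -7, 2), 12, 3, byrow = TRUE))
    fit <- superimpose(moved, ref, align_on = 1:12)
    expect_lt(fit$rmsd, 1e-8)
    expect_equal(fit$rotation %*% Q, diag(3), tolerance = 1e-6)
    # optimality: fitted RMSD never exceeds the unfitted one
    rmsd_before <- sqrt(mean(rowSums((moved$coords - X)^2)))
    expect_lte(fit$rmsd, rmsd_before + 1e-12)
  }
  # noisy correspondence still decreases RMSD
  noisy <- make_frame(X + matrix(rnorm(36, sd = 0.3), 12, 3))
  Q <- random_rotation(8)
  noisy_rot <- noisy
  noisy_rot$coords <- t(Q %*% t(noisy$coords))
  fit <- superimpose(noisy_rot, ref, align_on = 1:12)
  expect_lte(fit$rmsd,
             sqrt(mean(rowSums((noisy_rot$coords - X)^2))) + 1e-12)
  expect_error(superimpose(ref, make_frame(X[1:5, ]), align_on = 1:12),
               "mismatched")
  degenerate <- make_frame(cbind(1:12, 0, 0))
  expect_error(superimpose(degenerate, degenerate, align_on = 1:2), "3 aligned")
})

test_that("membrane clash calls use penetration depth and match the per-atom oracle", {
  slab <- list(z_lo = -18, z_hi = 18, half_width = 50)
  doms <- list(list(name = "DD", n_atoms = 4, center = c(0, 0, 40)))
  base <- build_toy_complex(doms, slab = slab,
                            fab = list(offset = c(0, 0, 60), n_atoms = 8),
                            seed = 3)
  expect_false(membrane_clash(base)$clash)
  # one atom at the slab midpoint clashes with count 1
  hit <- base
  fab_idx <- which(hit$atoms$molecule_class %in% c("H", "L"))
  hit$coords[fab_idx[1], 3] <- 0
  res <- membrane_clash(hit)
  expect_true(res$clash)
  expect_identical(res$n_clashing, 1L)
  # grazing penetration below 1 A is not a clash
  graze <- base
  graze$coords[fab_idx[1], 3] <- slab$z_hi - 0.5
  expect_false(membrane_clash(graze)$clash)
  expect_error(membrane_clash(base, slab = list(z_lo = 5, z_hi = -5)),
               "inverted")
  # randomized poses: flag equals a direct per-atom depth test
  for (sd_i in 1:10) {
    set.seed(sd_i)
    pose <- base
    pose$coords[fab_idx, 3] <- pose$coords[fab_idx, 3] - stats::runif(1, 0, 90)
    z <- pose$coords[fab_idx, 3]
    oracle <- sum(pmin(z - slab$z_lo, slab$z_hi - z) > 1.0)
    got <- membrane_clash(pose)
    expect_identical(got$n_clashing, as.integer(oracle))
    expect_identical(got$clash, oracle > 0)
  }
})
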