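test_that("paper-anchored fixtures satisfy their structural invariants", {
  for (nm in c("popc", "pops")) {
    fx <- build_fixture(nm)
    expect_equal(sum(fx$stationary), 1, tolerance = 1e-13)
    flux <- fx$stationary * fx$transition_matrix
    expect_lt(max(abs(flux - t(flux))), 1e-10)
    expect_true(all(diff(fx$emission_means[, 1]) > 0))
    expect_equal(rowSums(fx$transition_matrix), rep(1, 4), tolerance = 1e-12)
  }
  popc <- build_fixture("popc")
  expect_equal(popc$stationary,
               c(0.199, 0.195, 0.532, 0.073) / 0.999, tolerance = 1e-12)
  pops <- build_fixture("pops")
  expect_equal(pops$stationary,
               c(0.005, 0.003, 0.398, 0.592) / 0.998, tolerance = 1e-12)
  expect_error(build_fixture("dppc"), "unknown|arg")
  expect_error(build_fixture("popc", time_scale = -1), "time_scale")
})

test_that("fixture ground-truth MFPTs honour the reported kinetic anchors", {
  popc <- fixture_mfpt(build_fixture("popc"))
  # entries into the expanded-open state on the order of 20 us
  expect_true(all(popc[1:3, 4] > 20 / 1.5 & popc[1:3, 4] < 20 * 1.5))
  # exchanges among the three compact states within 4.1 us
  off <- popc[1:3, 1:3][row(popc[1:3, 1:3]) != col(popc[1:3, 1:3])]
  expect_true(all(off <= 4.11))
  pops <- fixture_mfpt(build_fixture("pops"))
  expect_lt(max(pops[3, 4], pops[4, 3]), 0.5)   # Io <-> Eo fast
  expect_lt(min(pops[1:2, 3:4]), 0.2)           # fast entries ~0.1 us
  expect_true(all(pops[pops > 0] <= 300))       # nothing beyond 300 us
})

test_that("time_scale multiplies MFPTs exactly and preserves populations", {
  for (s in c(0.5, 1, 3.7)) {
    base <- build_fixture("popc", time_scale = 1)
    scl <- build_fixture("popc", time_scale = s)
    expect_equal(scl$stationary, base$stationary, tolerance = 1e-12)
    M0 <- fixture_mfpt(base)
    Ms <- fixture_mfpt(scl)
    expect_equal(Ms, M0 * s, tolerance = 1e-9)
  }
})

test_that("fixtures round-trip through JSON", {
  fx <- build_fixture("pops", time_scale = 2)
  path <- tempfile(fileext = ".json")
  write_fixture_json(fx, path)
  back <- read_fixture_json(path)
  expect_equal(back$transition_matrix, fx$transition_matrix, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$stationary, fx$stationary, tolerance = 1e-12)
  expect_equal(back$emission_means, fx$emission_means, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$frame_interval, fx$frame_interval)
})

test_that("latent simulation is seeded, stationary and mean-faithful", {
  fx <- build_fixture("popc")
  # identity chain: labels never change
  fid <- make_test_fixture(diag(4), stationary = rep(0.25, 4))
  tr <- simulate_latent(fid, 200, 1, seed = 7)[[1]]
  expect_equal(length(unique(tr$macrostate_labels)), 1L)
  # bit-for-bit determinism
  a <- simulate_latent(fx, 500, 2, seed = 42)
  b <- simulate_latent(fx, 500, 2, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, simulate_latent(fx, 500, 2, seed = 43)))
  expect_error(simulate_latent(fx, 500, 1), "seed")
  # occupancy converges to the stationary vector at ~1/sqrt(n):
  # within 3 binomial standard errors at each of two depths
  for (n in c(20000L, 80000L)) {
    tr <- simulate_latent(fx, n, 1, seed = 11)[[1]]
    occ <- tabulate(tr$macrostate_labels, 4) / n
    # effective sample size reduced by label autocorrelation; bound it with
    # the slowest relaxation time of the chain (in frames)
    lam2 <- reversible_eigen(fx$transition_matrix, fx$stationary)$values[2]
    n_eff <- n / (2 * (-1 / log(lam2)))
    se <- sqrt(fx$stationary * (1 - fx$stationary) / n_eff)
    expect_true(all(abs(occ - fx$stationary) < 3 * se + 2 / n_eff))
  }
  # per-state emission means recovered within 3 standard errors
  tr <- simulate_latent(fx, 50000, 1, seed = 5)[[1]]
  for (s in 1:4) {
    sel <- tr$macrostate_labels == s
    n_s <- sum(sel)
    ar <- fx$ar_coefficient
    n_eff <- n_s * (1 - ar) / (1 + ar)
    for (d in 1:2) {
      se <- fx$emission_sds[s, d] / sqrt(n_eff)
      expect_lt(abs(mean(tr$features[sel, d]) - fx$emission_means[s, d]), 3 * se)
    }
  }
})

test_that("Brownian dynamics obeys the zero-temperature and equipartition limits", {
  # two wells; the second is distant and shallow so the first is effectively
  # an isolated harmonic well near its centre (stiffness depth / width^2)
  land <- toy_landscape(rbind(c(0, 0), c(100, 0)), well_depths = c(5, 0.1),
                        barrier_widths = c(2, 2),
                        diffusion_coefficient = 1, timestep = 0.01)
  frozen <- simulate_brownian(land, 500, kT = 0, seed = 1, start = c(0, 0))
  expect_equal(frozen[nrow(frozen), ], c(0, 0), tolerance = 1e-12)
  expect_identical(simulate_brownian(land, 100, kT = 1, seed = 9, start = c(0, 0)),
                   simulate_brownian(land, 100, kT = 1, seed = 9, start = c(0, 0)))
  # equipartition: positional variance = kT / stiffness within 5%
  kT <- 0.1
  stiff <- 5 / 2^2
  pos <- simulate_brownian(land, 200000, kT = kT, seed = 3, start = c(0, 0))
  v <- mean(c(stats::var(pos[-(1:1000), 1]), stats::var(pos[-(1:1000), 2])))
  expect_equal(v, kT / stiff, tolerance = 0.05)
  # a timestep so large that drift exceeds the barrier width is refused
  bad <- toy_landscape(rbind(c(0, 0), c(10, 0)), c(50, 50), c(0.5, 0.5),
                       diffusion_coefficient = 1, timestep = 1)
  expect_error(simulate_brownian(bad, 10, kT = 1, seed = 1, start = c(0, 0)),
               "timestep")
})

test_that("double-well escape times agree with the Kramers estimate in order of magnitude", {
  # wells at +-a; barrier height ~ depth difference at the midpoint
  a <- 3; depth <- 4; width <- 1.2; kT <- 1
  land <- toy_landscape(rbind(c(-a, 0), c(a, 0)), c(depth, depth),
                        c(width, width), diffusion_coefficient = 1,
                        timestep = 5e-3)
  barrier <- land$potential(c(-a, 0)) * -1 + land$potential(c(0, 0))
  # Kramers: tau ~ (2 pi / sqrt(k_well * k_barrier)) * exp(dU / kT) / D
  h <- 1e-4
  curv <- function(x0) {
    (land$potential(c(x0 + h, 0)) - 2 * land$potential(c(x0, 0)) +
       land$potential(c(x0 - h, 0))) / h^2
  }
  tau_kramers <- 2 * pi / sqrt(abs(curv(-a)) * abs(curv(0))) * exp(barrier / kT)
  escapes <- vapply(1:12, function(i) {
    pos <- simulate_brownian(land, 100000, kT = kT, seed = 100 + i,
                             start = c(-a, 0))
    hit <- which(pos[, 1] > 0)[1]
    if (is.na(hit)) nrow(pos) else hit
  }, numeric(1)) * land$timestep
  ratio <- mean(escapes) / tau_kramers
  expect_gt(ratio, 0.1)
  expect_lt(ratio, 10)
})

test_that("toy complexes are deterministic and place contacts as declared", {
  slab <- list(z_lo = -20, z_hi = 20, half_width = 60)
  doms <- list(list(name = "CrD", n_atoms = 10, center = c(0, 0, 30)),
               list(name = "MpD", n_atoms = 8, center = c(25, 0, 45)))
  lips <- list(list(species = "POPS", position = c(2, 0)),
               list(species = "POPC", position = c(40, 40)))
  fr <- build_toy_complex(doms, lips, slab,
                          fab = list(offset = c(0, 0, 80), n_atoms = 10),
                          seed = 5)
  expect_identical(fr$coords,
                   build_toy_complex(doms, lips, slab,
                                     fab = list(offset = c(0, 0, 80), n_atoms = 10),
                                     seed = 5)$coords)
  # a lipid atom placed 3.9 A from a CrD atom is a contact under the 4 A rule
  fr2 <- build_toy_complex(list(list(name = "CrD", n_atoms = 1, center = c(0, 0, 0))),
                           list(list(species = "POPS", position = c(0, 0), n_atoms = 1)),
                           slab = list(z_lo = -30, z_hi = -10, half_width = 50),
                           seed = 1, jitter = 0)
  fr2$coords[2, ] <- c(3.9, 0, 0)
  expect_equal(count_lipid_contacts(fr2, "CrD"), 1L)
  fr2$coords[2, ] <- c(4.1, 0, 0)
  expect_equal(count_lipid_contacts(fr2, "CrD"), 0L)
  # all Fab atoms far above the slab: no membrane clash
  clash <- membrane_clash(fr, body = c("H", "L"))
  expect_false(clash$clash)
  expect_identical(clash$n_clashing, 0L)
  expect_error(
    build_toy_complex(list(list(name = "CrD", n_atoms = 2, center = c(0, 0, 0)),
                           list(name = "CrD", n_atoms = 2, center = c(9, 0, 0))),
                      slab = slab, seed = 2),
    "duplicate")
})
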