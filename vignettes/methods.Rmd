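---
title: "Markov state modelling of membrane-protein opening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state modelling of membrane-protein opening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`openmsm` re-implements, as a tested pipeline, the analysis chain used to
characterise the opening transition of the membrane-anchored sheddase ADAM10
and its modulation by phosphatidylserine (PS): adaptive-sampling bookkeeping,
time-lagged independent component analysis (tICA), k-means microstate
definition, reversible Markov state model (MSM) estimation with Bayesian
uncertainties, PCCA+ coarse-graining into four macrostates (Closed,
intermediate-closed Ic, intermediate-open Io, expanded-open Eo), and the
structural observables used to interpret those states (lipid contacts,
catalytic-site accessibility, antibody–membrane clash).

Since tens of microseconds of all-atom molecular dynamics cannot be
regenerated at desk scale, the pipeline's inputs come from a synthetic
dynamics module that is itself first-class, tested code: a reversible
four-macrostate jump process whose ground truth encodes the published
summary statistics, with state-conditioned Gaussian feature emissions. Every
estimator in the chain can therefore be checked against exact linear-solve
oracles on the generating process.

## The kinetic fixtures

A fixture is a reversible row-stochastic matrix $T$ over the four
macrostates, with stationary vector $\pi$ fixed *exactly* at the reported
macrostate percentages:

* pure POPC: 19.9 / 19.5 / 53.2 / 7.3 % (Closed / Ic / Io / Eo),
* 7:3 POPC:POPS: 0.5 / 0.3 / 39.8 / 59.2 %.

Both vectors are renormalised to sum to one (they print as 99.9 % and
99.8 %). Reversibility is guaranteed by construction: $T$ is parameterised
through symmetric flows $s_{ij} = \pi_i T_{ij} = s_{ji}$, and the six free
off-diagonal flows are fitted by least squares on log mean-first-passage
times (MFPTs, computed by the exact solve
$(I - T_\mathrm{restricted})\,m = \tau \mathbf{1}$) toward the reported
kinetic anchors: entries into Eo near 20 µs and sub-4.1 µs exchange among
the compact states in POPC; sub-0.5 µs Io↔Eo exchange and 0.1–0.3 µs
entries from the rare compact states in POPC:POPS.

A four-state reversible chain cannot satisfy twelve MFPTs and four
populations simultaneously, and the POPS anchors are jointly infeasible
with the printed populations in a stronger sense: with $\pi(\mathrm{Closed})
= 0.5\,\%$ and ~0.1 µs exits, a flux (Kac recurrence) argument bounds every
MFPT *into* Closed near 20–30 µs, so the reported "up to 300 µs" return is
treated as an upper bound rather than a target. Populations are never
distorted; the log-MFPT residual is carried in the fixture's `fit` field.

**Time mapping.** Fixture time is compressed so the slowest process spans a
few hundred frames: 25 ns/frame (POPC) and 4 ns/frame (POPC:POPS). Two
considerations fix these values. First, the slowest relaxation should be
well-sampled by 20,000-frame trajectories (POPC relaxations: 69/37/20
frames; POPS: 34/19/14). Second, every hidden-state relaxation must be
*slower* than the emission memory (below), or the top MSM eigenvectors
would reflect emission noise rather than state exchange. Physical MFPTs are
always reported through the declared frame interval, so the µs-scale
anchors are preserved exactly; ground truth is always the linear-solve
oracle on the fixture matrix, never an assumed value.

**Emissions.** Each state emits a Gaussian feature vector; dimension 1 is
the catalytic-site accessibility (Å) with means 20/27.5/65/100 (POPC) and
18/22/50/75 (POPC:POPS — both compact states sit "around 20 Å" in the
source data; we separate them slightly because strictly increasing
accessibility is what makes openness-based state identification well
defined). Remaining dimensions are interface-distance-like observables
rising with openness. Per-state standard deviations are 0.15 × the mean
adjacent inter-state gap per dimension, giving overlapping-but-separable
states. Within a state, deviations follow an AR(1) process with coefficient
0.9 (memory −1/ln 0.9 ≈ 9.5 frames); the autoregression acts on the
*deviation* from the state mean, so state switches appear immediately in
the features and per-state sample means are unbiased estimators of the
emission means.

**What the generator does not emulate.** Real trajectories have continuous,
multiscale dynamics, anharmonic and non-Gaussian feature distributions,
state-dependent diffusion, and discretisation error that varies over the
landscape. Passing recovery tests here demonstrates that the estimator
chain is correct and internally consistent — not that four states, a given
lag, or Gaussian separability hold for any particular protein system.

## Pipeline parameters

* **tICA** (lag 5 frames by default): symmetrised (reversible) covariance
  estimator, matching the reversible MSMs downstream; plain forward
  covariances behind a flag. Small-variance directions below a relative
  floor of 1e-10 are projected out. No kinetic-map scaling: free-energy
  surfaces are invariant to per-component scaling after binning.
* **Component screening**: a component is discarded when a single Gaussian
  beats a two-component mixture by ΔBIC ≥ 10 (strong-evidence convention;
  mixtures fitted with mclust on a seeded 10,000-frame subsample). The
  slowest two components are never discarded.
* **k-means** (k = 50 at this scale; 200 microstates would need far more
  frames than desk-scale fixtures provide): greedy k-means++ seeding from a
  seeded stream, Lloyd iterations to a centre-shift below 1e-6 (or until
  assignments stabilise), nearest-centre assignment with ties to the lower
  index, empty clusters re-seeded to the farthest frame. Centres are fitted
  on every 10th frame by default — the usual practice for large trajectory
  sets — and all frames are then assigned exactly.
* **MSM lag**: chosen by the implied-timescale plateau rule — the first lag
  in 1/2/3/5/8/12/20 frames at which the top three timescales change by
  less than 10 % against the next lag. On fixture data the timescales are
  flat from lag 1, the fixture analogue of validating a 10 ns lag on a
  0.1–50 ns scan.
* **Reversible MLE**: self-consistent fixed-point iteration on symmetric
  flows, tolerance 1e-10 on transition-matrix elements.
* **Bayesian ensemble** (n = 100 samples): Metropolis-within-Gibbs on the
  symmetric flows with log-normal proposals (σ = 0.15), burn-in 1000
  sweeps, thinning 10 — stated once, not tuned per run. Sliding-window
  counts are divided by the lag before sampling, the standard correction
  for overlapping, correlated count pairs; the likelihood is used with a
  scale-invariant (1/x) prior on each sampled flow. Acceptance rates
  outside [0.05, 0.95] raise a warning.
* **PCCA+** (4 macrostates): inner-simplex vertex search on the dominant
  right eigenvectors, the Deuflhard–Weber feasibility fill, then
  Nelder–Mead refinement of the free (m−1)² block of the transform
  maximising crispness. Crisp assignment is argmax membership, ties to the
  lower index.
* **Macrostate conventions**: populations are stationary-weighted sums over
  microstates (a raw frame-fraction mode exists behind a flag); MFPTs use
  the microstate-level linear solve with stationary weights restricted to
  the source macrostate (the source-weighting convention is not stated in
  the source analysis; this is the natural equilibrium choice). Because
  PCCA+ output order is arbitrary, macrostates are identified by ascending
  mean openness (accessibility or summed-distance reward): Closed < Ic <
  Io < Eo.
* **Observables**: lipid contacts count distinct lipid *molecules* with any
  atom within 4.0 Å (inclusive) of the domain — molecule counting matches
  the reported ~10–15 contact magnitudes; an atom-pair mode exists behind a
  flag. Membrane clash requires at least one body atom deeper than 1 Å
  inside the slab, avoiding grazing-contact false positives. Centre-of-mass
  selections default to uniform weights (pseudo-atoms carry no masses).
* **FAST campaigns**: seed score = α · normalised(reward) + (1−α) ·
  normalised(1/(1+visits)) with α = 1 by default (pure directed ranking,
  the literal reading of the source protocol; the original balance term is
  available with α < 1). Per-generation clustering uses k = 100 on all
  accumulated frames (granularity unstated in the source; this is a
  middle-of-the-road choice), seeds are drawn from cluster members — not
  centres — so they are valid simulator states, and the 20 seeds per
  generation come from 20 distinct clusters.

## Numerical choices and degenerate inputs

Eigen-decompositions of reversible matrices go through the symmetrised
similar matrix $D_\pi^{1/2} T D_\pi^{-1/2}$, which keeps the spectrum real;
estimated eigenvalues outside [−1, 1] indicate covariance conditioning bugs
and are asserted against. Disconnected count graphs are restricted to the
largest strongly connected component; implied timescales at lags where the
graph disconnects are reported missing rather than fatal. Unreachable MFPT
targets report Inf, and Bayesian samples for which an observable is
undefined are excluded and counted. All stochastic operations require an
explicit integer seed and draw from an isolated stream that never touches
the global RNG state; identical inputs reproduce results bit-for-bit.

## Problem sizes

The recovery analyses (scripts `analysis/03_msm_pipeline.R`,
`scripts/acceptance.R`, and the acceptance tests) use 50 trajectories ×
20,000 frames per membrane system — 10⁶ frames, roughly 160 slow
transitions for the slowest fixture process — with k = 50 microstates.
These sizes give rare-state populations (0.3–0.5 %) a few thousand frames
and a few hundred entry/exit events, enough for sub-0.1-percentage-point
estimator noise. The demonstration scripts 01–02 and the unit tests use
smaller sizes chosen to exercise the same code paths quickly.

## Known limitations

* The fixtures encode four metastable states by construction; the pipeline
  does not address choosing the number of macrostates.
* The Bayesian sampler targets the reversible-likelihood posterior with a
  per-edge scale-invariant prior; other priors (e.g. sparse or
  neighbour-informed) are not implemented.
* The PCCA+ refinement is a local optimisation from the inner-simplex
  start; for strongly non-metastable inputs the memberships (though always
  feasible) may be a local optimum.
* No transition-path-theory fluxes, hidden Markov models, or multi-ensemble
  estimators; structural I/O is limited to multi-model PDB plus the flat
  feature container.
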