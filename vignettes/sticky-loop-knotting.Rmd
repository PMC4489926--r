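---
title: "Loop-mediated knotting of a coarse-grained DNA chain: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Loop-mediated knotting of a coarse-grained DNA chain: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(stickyknots)
```

## The question and the model

A long polymer knots spontaneously; a short one essentially never does,
unless specific interactions help it along.  This package studies one
minimal helping mechanism: a self-avoiding chain — a coarse-grained
double-stranded DNA filament — that carries **two pairs of adhesive
monomers**.  The terminal pair (beads 1 and N) circularizes the chain and
thereby freezes its topology; an internal pair at beads
`x = l_x + 1` and `y = N - l_y + 1` can close a *sticky loop* before the
termini meet.  The quantity of interest is how the location
`{l_x, l_y}` of the internal pair changes the probability that the
circularized ring is knotted.

The chain is a Kremer–Grest bead–spring polymer in reduced units
(`sigma = epsilon = m = 1`, `tau = sigma * sqrt(m / epsilon)`,
`k_B T = epsilon`):

* **WCA excluded volume** between *all* bead pairs (bonded neighbours
  included):
  `V(r) = 4 eps [ (sigma/r)^12 - (sigma/r)^6 + 1/4 ]` for
  `r <= 2^(1/6) sigma`, zero beyond.  Both the potential and its force
  vanish continuously at the cutoff.
* **FENE bonds** between consecutive beads,
  `U(d) = -(kappa_fene/2) (R0/sigma)^2 ln[1 - (d/R0)^2]` with
  `kappa_fene = 30 eps`, `R0 = 1.5 sigma`.  The combined FENE+WCA bond
  minimum sits at `b0 = 0.9609 sigma` (the conventional Kremer–Grest
  "0.97").
* **Adhesion**: a Gaussian well
  `G(r) = -U0 exp[-(r - 2^(1/6) sigma)^2 / (2 lambda^2)]`, active for
  `2^(1/6) sigma <= r <= (2^(1/6)+5) sigma`, with `U0 = 100 eps` and
  `lambda = 2.5 sigma`.  Exactly two pairs feel it — termini with
  termini, internal bead with internal bead; there is no cross-pair
  attraction.  The well is flat at its inner boundary; at the outer
  boundary the potential steps by `-100 exp(-2) eps * exp(...)`,
  a ~1.3 eps jump that we keep as written (the formula is implemented
  literally).
* **Bending**, `U = (kappa_bend/2)(theta - pi)^2` per bead triplet.
  `kappa_bend = 0` is the fully flexible regime ("L", a chain much
  longer than its persistence length); `kappa_bend = 10 k_B T` is the
  semiflexible regime ("S", persistence length about 10 sigma, which
  maps a 500-bead chain onto roughly 7.5 kbp of dsDNA).

## Dynamics and the circularization protocol

Runs integrate the underdamped Langevin equation with the BAOAB
splitting at `dt = 0.005 tau` and friction `gamma = 1/tau` — standard
stable choices for Kremer–Grest chains; with the thermostat off the
update reduces exactly to velocity Verlet, which is how the
energy-conservation checks run.  The noise stream is an internal
xoshiro256++ generator seeded per run, so every trajectory is bitwise
reproducible from `(config, seed)` on any platform.

Each run starts from an open, straight chain at the bond minimum with
sub-0.01-sigma transverse jitter and Maxwell–Boltzmann velocities.
Adhesion is checked every step: the first time a sticky pair comes
within the capture distance its flag is set permanently and a real FENE
bond (backbone constants) is added, so "permanently stick" is a hard
contract rather than a deep-well hope.  Terminal capture is the
circularization event and ends the run; internal capture does not.
Runs that exceed `max_steps` are recorded as *censored* and excluded
from numerator and denominator of every probability (their count is
reported); the step cap and this censoring policy are repository
policy, not part of the physical model.

**Capture distance.**  The default is `1.3 sigma`.  An earlier draft
used `1.5 sigma`, but that equals the FENE maximum extension `R0`:
adding a permanent FENE bond at its own divergence length injects a
near-singular force, and in pilot runs a large fraction of internal
captures aborted with overstretched bonds within a few steps.  At
`1.3 sigma` the added bond starts well inside its range (force about
160 eps/sigma) and the instability disappears, while the adhesive well
is still more than 99 eps deep there — far beyond thermal energy, so
which threshold in the 1.3–1.5 range is used has no physical bearing on
the permanence contract.  The parameter remains configurable.

## Knot identification

Knots are only defined for closed curves; because every completed run
ends circularized, the final frame *is* a closed polygon (the terminal
bond provides the closing edge) and no auxiliary closure construction is
ever needed.

Identification proceeds in two stages:

1. **Geometric simplification.**  A vertex is deleted whenever the
   triangle spanned by it and its two neighbours is pierced by no other
   edge of the polygon — an ambient isotopy, so the knot type is
   untouched.  Deletion sweeps repeat until a fixed point.  Ambiguous
   (near-degenerate) piercing tests conservatively keep the vertex;
   coplanar configurations get an exact 2D overlap test so planar
   polygons still collapse to a triangle.  Marked vertices (the sticky
   pair) are never deleted when the loop decomposition is still needed.
2. **Alexander determinants.**  The reduced polygon is rotated into a
   uniformly random orientation and projected; crossings and their
   over/under assignments are read off, and the Alexander matrix is
   evaluated.  Projections with tangencies, near-collinear crossings or
   endpoint hits are rejected and retried with a fresh rotation (up to
   50 attempts).

The determinant of the Alexander minor equals `±t^k Delta(t)` with an
unknown power shift `k`, which is the classical nuisance of this
invariant.  We remove it exactly rather than by convention: sampling the
determinant `P(t)` on the complex unit circle gives
`|P(e^{i theta})|^2 = Delta(e^{i theta}) Delta(e^{-i theta})` — the
unit factor `t^k` drops out — and a discrete Fourier transform of those
magnitudes reconstructs the integer Laurent coefficients of
`R(t) = Delta(t) Delta(1/t)`.  Since a knot's Alexander polynomial is
palindromic, `Delta(-2)^2 = R(-2) * 2^(deg R)`, and `Delta(-1)^2 = R(-1)`.
The pair `(|Delta(-1)|, |Delta(-2)|)` is therefore projection
independent, and classification is a table lookup:
`(1,1) -> 0_1`, `(3,7) -> 3_1`, `(5,11) -> 4_1`, `(5,31) -> 5_1`,
`(7,16) -> 5_2`; everything else, including composites and knots with
six or more crossings, is reported as `other`.  This pair separates all
knot types the spectrum analysis needs — in particular `5_1` from `5_2`,
and `5_2` (16) from `7_1` (127), which share `|Delta(-1)| = 7`.
Chirality is invisible to the Alexander polynomial and is not reported.
Reconstruction is abandoned (and the polygon classified `other`) when
the polynomial is too large to recover exactly in double precision;
that only happens far outside the table anyway.

Fixture curves validate the chain end to end: circle, torus knots
`3_1` and `5_1`, the standard figure-eight curve, and `5_2` built as the
polygonal closure of the twist-knot braid `s1^3 s2 s1^-1 s2`.  The braid
constructor is itself cross-validated by rebuilding `3_1`, `4_1` and
`5_1` from their braid words and checking them against the independent
parametric curves.

## Sticky-loop relevance

For a knotted ring with a closed sticky loop we ask whether the loop
matters for the knot.  Cutting the ring at the two (adhered, hence
nearly coincident) sticky beads and bridging them with a short direct
edge yields two sub-rings: the *excised ring* (chain outside the loop)
and the *loop ring*.  The loop is **irrelevant** when the knot is
completely localized in one of them: the excised ring still carries the
full knot type, or the loop ring carries it while the excised ring is
unknotted.  In every other case excision changed the topology without
the knot being localized — loop and knot are entangled — and the loop
is **relevant**.  Because the closing edge is shorter than the capture
distance, it cannot introduce entanglement at the scale of the chain.
The two-sub-ring construction is the minimal operational form of this
excision test; border cases it cannot represent (both sub-rings
knotted, outside the localization dichotomy) would classify as
relevant.

## The placement grid and the statistics

Internal sites live on a grid: arm lengths `l_x, l_y` in multiples of a
spacing (50 beads for the 500-bead study chain), excluding coincident
sites (`l_x + l_y = N`), requiring at least one spacing of loop, and
canonicalized to `l_x <= l_y` under chain-reversal symmetry — exactly
20 placements for `(N = 500, spacing = 50)`, four for the demo grid
`(N = 100, spacing = 20)`.

Per placement, against a shared reference chain with sticky termini
only:

* `P_K` — knotted fraction of non-censored runs (Wilson interval);
* `RKP = P_K / P_K^0` — relative knotting probability (Katz log-ratio
  interval; undefined when the reference has no knots, which at desk
  scale it typically does not);
* `FCSL` — fraction of knotted runs whose sticky loop is closed;
* `FTRSL` — fraction of knotted runs whose closed loop is relevant
  (`FTRSL <= FCSL` by construction);
* the knot spectrum over knotted runs.

The reference `P_K^0` is simulated once per regime and shared across
placements, matching the placement-independent denominator of the RKP
definition.  Uncertainty conventions (Wilson, Katz) are this package's
choice.

## Persistence length

An open chain without any sticky interaction is equilibrated and the
bond-vector correlation `<cos theta(s)>` is averaged over beads and
frames.  The estimator fits `exp(-s b / l_p)` over the *initial* decay
only — separations where the correlation stays above `c(1) e^{-1/2}` —
for two measured reasons: at larger separations excluded-volume
swelling makes the decay slower than exponential (a bias of roughly
+15% when fitting down to a 0.05 floor), and the long-separation
correlations are dominated by slowly relaxing chain-scale modes, which
inflates the seed-to-seed scatter of a wide-window fit several-fold.
For the discrete worm-like chain the expectation is
`l_p/b ≈ kappa_bend/k_B T` (more precisely `(kappa - 1/2) b` for the
harmonic hinge); the semiflexible chain recovers `l_p` of 9.5-10 sigma
across seeds, the flexible chain sits at the excluded-volume baseline
of a couple of bead diameters.

## Problem sizes, what the tests show, and what they cannot

The full-scale campaign is cluster-sized: 104,000 (L) and 24,000 (S)
runs for *each* of 20 placements at `N = 500`, because spontaneous
knotting of chains this short is a rare event.  The package
expresses that campaign directly — the configuration files, ledgers,
seed blocks and resumable batches are all built for it — but the
shipped test suite and the acceptance script run a desk-scale analogue:
`N = 100`, the spacing-20 grid (4 placements) plus the reference, tens
of runs per batch, single CPU.  The persistence-length check uses a
48-bead chain over 5 million steps; the equipartition check a
4-bead chain over 2 million steps.

Two consequences are worth stating plainly.  First, at `N = 100` and
desk-scale run counts the expected number of knotted rings per batch is
of order 0.1 or less (we observed none in several hundred pilot runs),
so the RKP assertions can only check *consistency* with loop-enhanced
knotting — the ratio intervals are wide and contain 1 — and the FCSL
gradient among knotted runs is usually not measurable at all.  The
suite therefore always asserts the underlying closure mechanism, which
is well powered: the fraction of runs whose sticky loop is closed at
circularization decreases strictly with the sequence separation of the
sticky beads; whenever enough knotted runs exist, the FCSL restriction
of the same gradient is asserted on top.  Second, the synthetic
trajectories share the idealizations of the model itself — no
electrostatics or salt dependence, no twist rigidity, no hydrodynamics,
Langevin kinetics rather than solvent dynamics — so passing tests
validate the pipeline and the topological machinery, not the mapping of
reduced units onto any particular experimental DNA.

## Numerical choices collected

* `dt = 0.005 tau`, `gamma = 1/tau` (BAOAB); stability margin against
  the stiffest force (FENE near `b0`, effective `omega dt ≈ 0.2`).
* Capture distance `1.3 sigma` (see above); adhesion checked every step.
* Verlet neighbour list, skin `0.35 sigma`, rebuilt on half-skin
  displacement; all-pairs WCA within the list.
* Angle forces use the `atan2` form with the sine clamped away from
  zero, so the straight configuration (`theta = pi`), which is the
  potential minimum the chain actually occupies, is handled without
  loss of precision.
* Projection degeneracy thresholds: crossing parameters within `1e-9`
  of an edge end, z-separation below `1e-9` of the projected span, or
  non-integral Fourier coefficients all trigger a retry with a fresh
  random rotation (at most 50).
* KMT piercing tests resolve ambiguity conservatively (keep the
  vertex); degenerate triangles are removed only in the exact collinear
  case.
* Censored runs: `max_steps` default `1e9`; desk-scale campaigns use
  `1.5e7` and report censoring counts.

## Known limitations

* Knot types beyond five crossings collapse into `other`; composite
  knots are not decomposed.  For the spectra of interest their
  abundance is marginal.
* The relevance classifier cannot express "knotted on both sides of
  the excision"; such cases (none observed in testing) would be called
  relevant.
* RKP at desk scale is an existence/consistency statement, not a
  measurement; resolving the placement dependence of the RKP requires
  the full cluster campaign the configuration supports.
* The S regime costs roughly an order of magnitude more steps per
  circularization than the L regime at the same `N`; the shipped demo
  campaign is therefore L-only.
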