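---
title: "Lattice Monte Carlo of a two-block copolymer in a tight nanochannel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice Monte Carlo of a two-block copolymer in a tight nanochannel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polychan)
```

## The model

`polychan` simulates one coarse-grained linear chain of `N` beads as a
self-avoiding walk (SAW) on a simple cubic lattice with lattice constant
`b = 1`. The chain lives in a nanochannel: the two transverse axes are
confined between impenetrable walls, with allowed planes `1..D` and the
walls being the excluded planes `0` and `D+1`; the longitudinal axis x is
periodic with period `L`. All observables use unwrapped x coordinates;
wrapping enters only occupancy and contact tests, so excluded volume is
respected across the periodic images.

The chain is a two-block copolymer. Bead indices `1..N/2` form block P1 and
the rest block P2; the labels are attached to indices, never to physical
beads, so the blocks always remain contiguous halves. Contact energies (in
units of `kB*T`) act between non-bonded beads occupying nearest-neighbour
sites. In the default configuration P1 is self-attracting,
`eps(P1,P1) = -1`, and everything else — P2 self-contacts, mixed contacts,
and all solvent terms — is zero. On the cubic lattice with effective
coordination `z - 2 = 4` this corresponds to a Flory coefficient `chi = 2`
for P1 (a compact, poor-solvent block) and `chi = 0` for P2 (an athermal,
loose block); see `flory_chi()`. Mixed contacts are kept at zero by default
because the athermal block should remain athermal at the junction; the
value is configurable in `energy_model()`.

Dynamics are Metropolis Monte Carlo over the classical Verdier–Stockmayer
move set:

* **kink-jump** — a 90° corner flip of one interior bead,
* **crankshaft** — rigid rotation (quarter, half, or three-quarter turn) of
  a two-bead U-segment about the axis through its flanking beads,
* **end move** — an end bead jumps to a neighbour site of its bonded
  neighbour,
* **reptation** — one end bead is removed, a new bead is appended at the
  other end, and all coordinates shift one index along the chain so that P1
  and P2 remain the first and second index halves.

Move kinds are drawn with frequency proportional to the number of objects
they can act on (`N-2` interior beads, `N-3` segment pairs, 2 ends, 2
directions), which fixes the simulation timescale. The clock counts
elementary attempts `t_E` (accepted or not); one MC cycle is `N` attempts.
Each run starts from a deterministic centred rod (or biased random growth)
and is burnt in for `n_equil` attempts under a hyperbolic cooling schedule
`T(k) = T_final (1 + cK/(k+K))` with defaults `c = 4` and
`K = n_equil/10`: the burn-in starts a few times above the target
temperature and the decay is substantially complete by half the burn-in.
These two schedule constants are the package's own choice; both are
configurable and the burn-in is never recorded.

### The acceptance weight: energy vs free energy

Two acceptance weights are implemented (`run_config(weight = )`):

* `"U"` (default): the standard Metropolis rule on the internal contact
  energy, `P_acc = min(1, exp(-dU/T))`. This samples the canonical
  distribution `exp(-U/T)` exactly — the package's enumeration oracle
  verifies this to chi-square precision on tiny systems.
* `"A"`: the rule applied to the Helmholtz free energy `A = U - T*S`, with
  `S` the phantom-chain SCM entropy of the trial and current
  conformations. This "free-energy dynamics" is stationary on
  `exp(S - U/T)` (also verified against exhaustive enumeration); it
  up-weights conformations with many open continuations and roughly
  doubles the cost per attempted move.

The distinction matters because descriptions of this class of model are
ambiguous about which state function feeds the Boltzmann factor while
forces and impulses are explicitly computed from `A`. The package treats
`"U"` as the physically canonical default and exposes `"A"` as a documented
variant; every sampling test states which weight it uses.

## Measurement-side thermodynamics

`entropy_scm()` estimates conformational entropy by the statistical
counting method with a phantom rebuild: the whole chain is removed, bead 1
is put back, and at each step `i = 1..N-1` the effective coordination
`omega_i` counts the neighbour sites of bead `i` that are not walls and not
occupied by an already-replaced bead — beads not yet replaced do not block.
Then `S/kB = sum(ln omega_i)`. Because the site of bead `i+1` is free at
count time, `omega_i >= 1` always. On tiny systems the rebuild counts equal
the exact continuation counts of the enumeration oracle, and any
conformation obeys `S <= ln 6 + (N-2) ln 5`; confinement only lowers the
sum. SCM values are estimators of relative entropy: only fluctuations and
gradients along a trajectory are meaningful, not absolute values across
different `N`.

Per-block values split the rebuild sum by index range, with the junction
step (bead `N/2` to `N/2 + 1`) assigned to P2, and mixed contacts split
50/50 for the per-block internal energy. These conventions are the
package's own (any split is defensible); they are configurable only in the
sense that the whole-chain values are always reported alongside.

`helmholtz()` applies `A = U - T*S`, exact at every record.
`force_profile()` bins `A` against an unwrapped longitudinal coordinate
(default bin width `0.5b`: the mass centre is quantised at resolution
`1/N`, so sub-lattice bins below 0.5 carry no information), averages per
bin, and differentiates by central finite differences. The sign convention
is `F = +dA/dx` as printed in this literature; a `"mechanics"` flag flips
it. `impulse()` integrates the force by the trapezoid rule over a window
`[t, t + dt]` and divides by the window *start* time (the printed
convention, which ties the value to the time origin); a `"window"`
normalisation dividing by the window length — the mean force — is available
because the printed prefactor is origin-dependent.

## Observables

* `autocorr_g()` — mean squared displacement of the whole-chain centre over
  lag `dt`, averaged over all overlapping time origins; x-only by default,
  3D variant available. The overlap maximises statistics at the cost of
  correlated origins; ensemble averaging over seeds (`run_ensemble()`)
  before fitting suppresses the resulting bias.
* `autocorr_gB()` — per-bead squared displacements averaged over origins
  and over the beads of one block; beads are tracked by monomer slot, which
  is the natural identity under the index-shifting reptation.
* `orientation_M()` — the mutual orientation parameter:
  `+1/0/-1` as `x_P1 - x_P2` exceeds `+delta`, sits inside the dead band,
  or falls below `-delta` (`delta = 0.01b`). A 3D magnitude-comparing
  variant is provided for completeness but is exactly degenerate for
  equal-mass halves (the two block centres are mirror vectors about the
  whole-chain centre), so the longitudinal form is the operative
  definition.
* `detect_swaps()` — block-order reversals. The default hysteresis
  definition records an event only when the signed separation enters the
  saturated state of the opposite sign, so dead-band chatter does not
  count; a plain zero-crossing variant is available. Periods between
  events feed `swap_period_density()`, a histogram over `log10(period)`
  with an optional 3-component Gaussian mixture (EM via the mclust
  package, unequal variances, with a k-means fallback for heavily tied
  samples) whose component means locate the characteristic swap modes.

`fit_exponent()` fits the anomalous-diffusion exponent `nu` of
`<r^2> ~ t^nu` by OLS on the log-log curve. `segment_regimes()` finds
scaling regimes automatically: local slopes over half-decade sliding
windows, greedy merging of contiguous points whose local slope stays
within 0.15 of the running regime mean (matching the visual discrimination
of regimes on log-log plots; configurable), dropping crossover stretches
shorter than 0.3 decades, and pooled refits per regime.

## Numerical and design choices

* **Wall convention.** "Width D" = number of habitable transverse planes.
  This keeps `D = 3` habitable by crankshaft moves; the narrower reading
  (D minus the wall planes) would essentially freeze the tightest channel.
* **Bonded contacts are excluded** from energy sums (including the
  junction bond): their adjacency is structural and would only shift `U`
  by a constant.
* **Reptation proposal.** The new end site is drawn uniformly among all 6
  neighbours of the growing end and rejected if blocked. Drawing only
  among *free* neighbours would bias forward/reverse proposal
  probabilities by the local free-site counts and break detailed balance —
  the enumeration oracle detects exactly this class of error.
* **Incremental energy bookkeeping** is local for single- and two-bead
  moves; reptation slides the block boundary over a lattice site (the bead
  type at the junction site changes), so its `dU` comes from a full O(N)
  recompute — reptation is ~1% of attempts, so this costs little. A debug
  mode (`validate_every`) recomputes `U` (and cached `S` in A-mode) from
  scratch at a fixed cadence and aborts on any mismatch.
* **Determinism.** A single RNG stream (R's generator, consumed by the
  compiled engine) drives move kind, object, geometry, and the Metropolis
  draw in a fixed order; identical config + seed gives bit-identical
  trajectories.
* **Recording cadences.** 1e3 t_E for long coarse trajectories and 1 t_E
  for single-event analyses. The scaling study in `scripts/acceptance.R`
  measures g at two resolutions and splices them (the standard
  multi-resolution MSD construction): 8 fine-cadence replicas (4e7
  attempts, every 20 t_E) resolve the short-time branch, and 8 long
  replicas (2e8 attempts, every 2e3 t_E) reach the long-time branch, with
  lags capped at 1/8 of the span to keep origin statistics healthy. These
  problem sizes are the package's choices for desk-scale reproduction.

## What the simulator does and does not reproduce

The enumeration oracle (`enumerate_saws()`, `boltzmann_distribution()`,
`exact_continuation_counts()`) guarantees the *equilibrium* correctness of
the sampler: on tiny channels the visited-state frequencies match the
exact Boltzmann distribution (chi-square), the incremental energy matches
full recomputation exactly, and SCM entropy matches exact continuation
counts. The athermal symmetric chain shows clean diffusion of the mass
centre (a single regime with `nu` near 1) and balanced occupancy of both
chain orientations.

The *kinetics* of the asymmetric copolymer at the study conditions are
another matter, and the package's own measurements are reported honestly:

* With either acceptance weight, the two blocks of an `N = 100` chain in a
  `D = 3..8` channel never exchange order within feasible runs (up to 2e8
  attempts). Swap counts at `D = 3` fall roughly exponentially with chain
  length (hundreds of events per 1e7 attempts at `N = 20`, none at
  `N >= 60`), as expected for a barrier that grows with the number of
  beads that must thread past the compact block. Swap-period statistics
  are therefore only accessible for short chains, and the swap-mode width
  sweep at `N = 100` has no events to analyse.
* The mass-centre curve g shows a near-diffusive short-time branch, an
  *antipersistent* intermediate dip (local slopes down to ~0.45, driven by
  back-and-forth slithering of the chain against the compact P1 block),
  and a recovery toward diffusive scaling at long lags. No superdiffusive
  (`nu > 1.2`) window appears anywhere up to lags of 4e7 t_E, although a
  persistent M-correlated drift (with P1 leading) is present and measurable.
* Bead curves g_B show Rouse-like subdiffusion (local slopes ~0.4–0.5)
  in the intermediate window — the expected exponent family for local
  stochastic dynamics without hydrodynamic interactions, which this model
  deliberately omits.

Tests that encode published quasi-ballistic (`nu = 5/3`) and Zimm-like
(`nu = 2/3`) intermediate regimes, and the swap-mode width power, fail
against this implementation at these problem sizes; they are kept failing
rather than weakened, as an explicit record of the discrepancy. Everything
the tests *do* show — exact sampling, exact bookkeeping, entropy bounds,
diffusive nulls, symmetry properties — holds at the stated tolerances.

## Known limitations

* No hydrodynamic (Zimm-type) dynamics and no inertia: the model is
  activation-only lattice MC by construction.
* SCM entropy is an estimator; absolute values are not comparable across
  chain lengths.
* The 3D orientation variant is degenerate for equal halves (see above).
* Enumeration oracles are guarded to `N <= 9` and cross-sections up to
  3×3; they exist for validation, not production.
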