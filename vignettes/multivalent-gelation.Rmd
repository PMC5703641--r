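---
title: "Lattice models of gelation and phase separation in multivalent proteins"
author: "latticegel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice models of gelation and phase separation in multivalent proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticegel)
```

## The model

Linear multivalent proteins -- poly-SH3 and poly-PRM chains whose
interaction domains are joined by intrinsically disordered linkers --
can form system-spanning physically crosslinked networks (gels) either
*with* or *without* an accompanying density transition (phase
separation into a dense droplet coexisting with a dilute solution).
`latticegel` implements a coarse-grained model of this physics on a
3-dimensional cubic lattice with periodic boundaries:

* Every SH3 domain and every PRM occupies one lattice site. A bound 1:1
  S-P complex between *face-adjacent* domains carries an energy
  `u_SP = -2 kB*T` by default (reproducing the measured SH3/PRM
  affinity scale); all other contact energies are zero. Crucially,
  adjacency alone carries no energy -- two domains interact only when
  their bound flag is set, which is itself a degree of freedom of the
  simulation.
* Linkers of `n` lattice sites come in three flavors controlled by the
  number `e` of explicitly modeled beads. `e = 0` is the
  Flory-random-coil (FRC) limit of a linker with near-zero effective
  solvation volume: the linker occupies no volume and only tethers its
  two domains inside a cubic square well (Chebyshev distance at most
  `n`). `e = n` is the self-avoiding (SARC) limit of a linker with
  positive effective solvation volume: `n` excluded-volume beads, each
  face-adjacent to its chain neighbors. Intermediate `0 < e < n` gives
  hybrid linkers whose effective solvation volume is proportional to
  `e`; the explicit beads sit contiguously adjacent to the upstream
  domain and the remaining span is a single square well of width
  `n - e`. (Whether the square-well cap should apply per implicit run
  or to the whole linker is not determined by the model description; we
  treat each implicit run as an independent well and record the choice
  here.)
* Linkers with *negative* effective solvation volume (self-attractive)
  are out of scope: they act as additional interaction domains rather
  than passive tethers.

One lattice site corresponds to roughly seven linker residues (the
spatial dimension of an SH3 domain), so a five-site linker models a
~35-residue disordered region (`residuesToLattice()` /
`latticeToResidues()`).

## The Monte Carlo kernel

Five moves evolve the system, accepted by the modified Metropolis rule
`min{1, w exp(-dE)}` with `dE` in units of `kB*T`:

1. **binding_flip** -- redraw the interaction state of a random domain
   among its admissible assignments (unbound, or bound to any adjacent
   free complementary domain); `w = 1`.
2. **end_pivot** -- move a singly-tethered end domain to a uniform
   position in its tether range and redraw its interaction state;
   `w = Np/Nc`, the ratio of admissible binding-state counts at the
   proposed and current positions (both counts include the unbound
   state).
3. **crankshaft** -- move a doubly-tethered module uniformly over the
   intersection of its two tether ranges (for two square wells this
   intersection factorizes per dimension, which the kernel exploits);
   interaction state redrawn if the module is a domain; `w = Np/Nc`.
4. **cluster_translate** -- rigid unit-vector translation of one
   connected bound network; always accepted unless it collides
   (`dE = 0`, `w = 1`).
5. **reptation** -- remove an end domain together with its linker and
   append it to the other end at a uniformly chosen valid placement,
   redrawing the interaction state; `w = (Np*Vp)/(Nc*Vc)` where
   `Vc`/`Vp` count the valid segment placements at the two ends.

Any proposal that lands on an occupied site is rejected outright. The
Hastings factors exactly cancel the proposal-density asymmetries, which
we verify not by inspection but by *exhaustive enumeration*:
`exactEnumeration()` lists every microstate of systems with a few
thousand placements, and the test suite checks that long MC runs
reproduce the Boltzmann distribution state by state. That test -- not
the formula's typography -- is the ground truth for the reptation
weight's grouping.

A *step* is one attempted elementary move. The move schedule is uniform
over applicable move types by default and configurable per type; it
affects mixing only, never the stationary distribution (again verified
by enumeration). Reptation deserves two remarks. First, it is the fast
transport move: condensation that takes more than `1e8` attempts with
the other four moves completes within a few `1e6` when reptation is
active, so implicit-linker sweeps keep it at full weight. Second, its
exhaustive placement count grows as `6^e` with the explicit bead count,
so the sweep driver's default schedule down-weights it for hybrid
linkers and omits it for heavily explicit ones; pivot, crankshaft and
cluster translations are ergodic on their own.

## Order parameters

* Gelation is tracked by `phi_c`, the fraction of molecules in the
  single largest cluster of the binding network (molecules are nodes;
  an edge requires an intermolecular bound S-P pair). The percolation
  threshold `phi_cc` is calibrated with a random bipartite network
  model (below); the operational gel point `c_g` is the lowest
  concentration with `phi_c > phi_cc` (default threshold 0.17).
* Phase separation is tracked by `rho`, the ratio of the
  uniform-dispersion reference radius to the measured radius of
  gyration of all protein beads; `rho > 1.08` flags a two-phase state.
  The center of mass is computed by the circular-mean method so
  droplets spanning the periodic boundary are measured correctly.

Two reference-radius definitions are provided. `latticeRadius(L)` is
the closed-form radius of gyration of a uniform distribution over the
`L^3` lattice sites, `sqrt(3 (L^2 - 1)/12)`. `dispersedRadius()`
instead *measures* the reference on random dispersions of the actual
molecules. The distinction matters only for small systems: the
periodic Rg estimator adapts its center to density fluctuations, so a
dispersed system of ~50 molecules measures a few percent below the
analytic reference and its apparent `rho` sits near 1.08 before any
condensation happens. The measured reference restores the defining
calibration `rho ~ 1` for uniform states at every system size and
converges to the analytic value at production scale; sweeps use it by
default.

Coexistence concentrations come from a two-uniform-density ansatz: the
dense phase is a sphere of radius `r` holding the `NN` molecules of the
largest network, the remaining `NT - NN` molecules are uniform over the
rest of the box. Equating the mixture's second moment to the measured
`Rg^2` gives the quintic

$$-\tfrac{4\pi}{5} N_T r^5 + \tfrac{4\pi}{3} N_T R_g^2 r^3 +
  \tfrac{3}{5} N_N L^3 r^2 + \tfrac{(N_T-N_N) L^5}{4} - N_T R_g^2 L^3 = 0,$$

whose unique admissible real root is the droplet radius
(`dropletRadius()`; residuals are checked below `1e-8` after rescaling
by the leading coefficient). The boundaries follow as
`c_sh = 3 N_N / (4 pi r^3)` and, by exact molecule conservation,
`c_sl = (N_T - N_N) / (L^3 - 4/3 pi r^3)`. The derivation is accepted
against a construction oracle (a synthetic dense ball in a dilute
background with known radius) rather than against any printed
coefficients. For that oracle the dilute background is sampled with
per-dimension (Latin hypercube) stratification: the root is sensitive
to the background's second moment, which is additive over dimensions,
so marginal stratification realizes the uniform-density assumption with
very low variance while every marginal remains exactly uniform.

## Percolation theory and the cooperativity ratio

For two species of valences `Va`, `Vb` with bound fractions `xa`, `xb`,
the Flory-Stockmayer branching parameter is
`epsilon = (Va-1) xa (Vb-1) xb`; `epsilon >= 1` cascades into a
system-spanning cluster. Bound fractions follow mass action
(`solveBinding()`, the physical root of the binding quadratic), and
setting `epsilon = 1` gives the gel point: in equal-concentration mode
the closed form `[a]_c = Kd sqrt(lambda) / (sqrt(lambda)-1)^2` with
`lambda = (Va-1)(Vb-1)`. Both modes are validated against a numeric
root-find of `epsilon([a]) = 1`, since the algebra was rederived from
mass action here.

The dissociation constant matched to a lattice affinity is *derived*
from the lattice itself rather than assumed: enumerating a single S + P
pair gives the bound probability in a finite box, and in the dilute
limit `Kd = 1/(6 exp(-u_SP))` domains per site -- six being the number
of bound orientations per site under face connectivity
(`latticeKd()`). It can also be set directly.

`phi_cc` is calibrated by the random bipartite network model: 2400
domains split stoichiometrically into molecules of valence `V` per
side, each A domain bound with probability `x` to a uniformly chosen
free B domain, clusters read off the molecule graph. Reading the
`phi_c(x)` sigmoid at the critical bound fraction `x_c = 1/(V-1)` gives
`phi_cc`. With 2400 domains we obtain 0.16/0.15/0.15 for valences
3/5/7 -- valence-independent and consistent with the canonical 0.17
within its tolerance (the quantity is a finite-size critical value, so
a spread of this order is expected; the V = 5 value converges to
~0.145, about 0.025 below the nominal figure). 2400 domains do not
divide into whole valence-7 molecules, so V = 7 uses the nearest whole
count (2394).

The cooperativity ratio `c* = c_g,sim / c_g,FS` compares the simulated
gel point to the Flory-Stockmayer prediction: `c* < 1` means positive
global cooperativity (phase separation drives gelation below the
mean-field threshold, the FRC regime at intermediate linker lengths),
`c* > 1` negative (SARC linkers suppress phase separation and delay
gelation).

## Sequence-level linker metrics

`chargeMetrics()` computes the fraction of charged residues
`FCR = f+ + f-` and net charge per residue `NCPR = f+ - f-`, with
`f+` counting Arg/Lys and `f-` counting Asp/Glu (histidine neutral --
the convention that reproduces the reference linker table exactly).
`deltaParameter()` quantifies the deviation of an inter-residue
distance profile from an FRC reference,
`Delta = (1/N) sum_k (<R_k> - <R_k^FRC>) / <R_k^FRC>`; regimes split at
`Delta < -0.1` (negative effective solvation volume),
`-0.1 <= Delta <= 0.1` (near zero; the interval is closed on both
sides) and `Delta > 0.1` (positive, approaching ~0.5 in the
self-avoiding limit). The conventional normalizer is the residue count
`N` although `N - 1` separations are summed; both conventions are
available and the output records which was used. Reference profiles
come from external ensemble calculations and are supplied as input
files; `idealChainProfile()` is a synthetic `k^0.5` stand-in for tests
only.

## Simulation scales, defaults, and what the tests do (and do not) show

Production-scale studies of this model use 2.4e3 interaction domains,
boxes of 50-340 lattice units and 5e9 attempted moves per state point,
averaging over the final half of each trajectory. That scale is
preserved here as explicit parameters, but the packaged tests and
examples run scaled-down versions: at most 240 domains (24+24 chains of
valence 5), boxes of 23-44 sites and 1e7-1e8 attempted moves, with
ensemble averages over the final half and a split-half drift check on
`phi_c` flagging non-equilibrated points. These sizes keep the full
suite within minutes on one CPU while preserving every qualitative
contrast (FRC versus SARC, sol-gel versus two-phase).

Two finite-size effects of the scaled-down conditions are worth
stating plainly:

* With ~50 molecules the sol-gel and density transitions are smeared
  over roughly 1 kB*T of affinity, and the apparent critical affinity
  of the hybrid-linker system reads about one grid step (0.5-1 kB*T)
  *above* the production-scale value of ~3 kB*T. The scaled-down
  affinity scan therefore brackets rather than pinpoints the critical
  point.
* Raising concentration by shrinking the box at fixed molecule count
  lowers the reference radius itself; the sweep tables record the box
  size next to `rho` so this documented artifact stays attributable.

The synthetic generators used by the tests (random bipartite networks,
dense-ball constructions, uniformly dispersed gases, enumerable
two-monomer boxes) emulate the *model's* statistics, not real data: a
passing suite certifies the machinery -- detailed balance, cluster
analysis, the coexistence algebra, the percolation analytics -- and
says nothing about how well the lattice model itself describes any
particular protein.

Dense-phase-initialized runs are supported by building a small-box
equilibrated state and re-wrapping it into a larger box; molecules
spanning the boundary are re-wrapped by minimum image from their first
domain.

## Numerical choices

* Coordinates are integer triples wrapped modulo `L`; all distances use
  the minimum-image convention. Contacts and explicit-chain
  connectivity use face (6-neighbor) adjacency; implicit tethers use
  the Chebyshev metric (a cubic well).
* Energies are exact multiples of the configured contact energies, so
  the cached energy is required to equal a from-scratch recomputation
  exactly (tolerance 0 in spirit; 1e-9 in floating point) after any
  run.
* The binding-state counts `Nc`/`Np` include the unbound assignment;
  neighbor sites are deduplicated so boxes as small as `L = 2` are
  handled exactly.
* `polyroot()` solves the droplet quintic; admissible roots must be
  real, positive and inside the lattice, and if several qualify the
  root whose dense phase is denser than its dilute phase is preferred.
* Random placement inserts molecules sequentially with bounded retries
  and raises an explicit capacity error when the requested density
  cannot be placed.
* All randomness flows through R's RNG, so every run, sweep and test is
  bit-reproducible under `set.seed()`.

## Known limitations

Only linear topologies and 1:1 domain binding are modeled; linker-linker
or linker-domain attractions (negative effective solvation volumes) are
excluded by design. Move kinetics are not physical dynamics: nothing
here speaks to the rheology or aging of the networks. The coexistence
ansatz assumes a single spherical droplet; multi-droplet coarsening
statistics are out of scope. Scaled-down sweeps bracket, rather than
resolve, critical points (see above).
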