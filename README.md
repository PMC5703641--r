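# latticegel

Coarse-grained lattice Monte Carlo simulation and percolation theory for
the phase behavior of **linear multivalent proteins** — poly-SH3 /
poly-PRM bead-tether polymers whose folded interaction domains are joined
by intrinsically disordered linkers. The package is built for one
question: when does a system-spanning, physically crosslinked network (a
*gel*) form **with** phase separation (a dense droplet that is itself a
gel) versus **without** it (a network spanning the whole volume), and how
do the linkers decide?

## Who it is for

Computational biophysicists studying biomolecular condensates and
stickers-and-spacers models; anyone wanting a small, fully tested,
exactly reversible lattice MC engine for multivalent associative
polymers with an analytic percolation baseline.

## The model in brief

Domains occupy single sites of a periodic cubic lattice; bound
face-adjacent SH3–PRM pairs carry energy `u_SP = −2 k_BT` (binding is an
explicit degree of freedom — adjacency alone contributes nothing).
Linkers of `n` sites with `e` explicit beads interpolate between the
Flory-random-coil limit (`e = 0`, a volume-less cubic square-well tether;
effective solvation volume v_es ≈ 0) and the self-avoiding limit
(`e = n`, excluded-volume beads; v_es > 0). Five Metropolis–Hastings
moves (binding flips, end pivots, crankshafts, cluster translations,
reptation) evolve the system under `min{1, w·exp(−ΔE)}`, with Hastings
weights `w` that make every move microscopically reversible — verified
against exhaustive enumeration of tiny systems, not taken on faith.

Two order parameters classify each state point:

* `φ_c` — fraction of molecules in the largest bound cluster;
  `φ_c > φ_cc ≈ 0.17` marks a gel (threshold calibrated by a random
  bipartite network model at the Flory–Stockmayer critical bound
  fraction `x_c = 1/(V−1)`);
* `ρ` — uniform-dispersion reference radius over the measured radius of
  gyration; `ρ > 1.08` marks a two-phase (condensed) state. Coexistence
  concentrations `c_sl`, `c_sh` follow from a two-uniform-density
  droplet ansatz (a quintic in the droplet radius).

The cooperativity ratio `c* = c_g,sim / c_g,FS` compares the simulated
gel point to the Flory–Stockmayer prediction
(`[a]_c = K_d√λ/(√λ−1)²`, `λ = (V_a−1)(V_b−1)`): `c* < 1` means phase
separation drives gelation below the mean-field threshold (FRC linkers
of intermediate length); `c* > 1` means suppression (SARC linkers).
Sequence-level metrics (`FCR`, `NCPR`, the Δ deviation from an FRC
distance profile with regime boundaries at ±0.1, and the `N ≈ 7n`
residue↔site mapping) connect real disordered linkers to the model's
linker classes.

## Worked example

```r
library(latticegel)

## a 5:5 system with implicit (FRC) five-site linkers, 48 chains
st  <- buildSystem(latticeConfig(23),
                   list(polySH3(5, linkerN = 5, linkerE = 0),
                        polyPRM(5, linkerN = 5, linkerE = 0)),
                   c(24, 24), interactionModel(uSP = -2), seed = 1)
run <- runMC(st, 5e6, sampleStride = 5e4, seed = 2)
tail(run$samples, 3)
#>        step energy      phiC NN       Rg      rho
#> 98  4900000    -58 0.3333333 16 10.82205 1.061641
#> 99  4950000    -50 0.2083333 10 10.14505 1.132486
#> 100 5000000    -62 0.5416667 26 10.12440 1.134796

trajectoryMeans(run$samples)
#>        phiC      rho   NN       Rg energy equilibrated nSamples
#> 1 0.2770833 1.095004 13.3 10.49912 -61.24         TRUE       50

c(concentrations(st)["domainsPerSite"] / 2,   # per species of domains
  fsGelPoint(5, 5, latticeKd(-2)))
#> [1] 0.009862744 0.010024845
```

The per-species domain concentration here (0.00986 per site) sits just
*below* the Flory–Stockmayer gel point (0.01002 per site, from the
lattice-derived `Kd = 1/(6e²) ≈ 0.0226`), yet the ensemble-averaged
largest-cluster fraction over the final half of the trajectory is
`phiC ≈ 0.28 > 0.17` — the system is already a gel below the mean-field
threshold, the signature of positive global cooperativity (`c* < 1`)
that FRC linkers of this length produce. The same sweep with
`linkerE = 5` (SARC linkers) stays unpercolated and dispersed at this
concentration; its transitions sit at substantially higher
concentration. (At ~50 molecules, `rho` against the analytic reference
radius carries a finite-size offset of about +0.08; sweeps therefore
measure the dispersed reference with `dispersedRadius()` — see the
methods vignette.)

Theory-side, in seconds:

```r
estimatePhiCc(c(3, 5, 7), nDomains = 2400, replicates = 200, seed = 1)$mean
#> [1] 0.155774
chargeMetrics("EDEDSEKEEEEEDKEMEELQEEKECEKPQGDEEEEEEEEE")[, c("FCR", "NCPR")]
#>   FCR NCPR
#> 1 0.8 -0.6
```

A thin command-line wrapper lives in `inst/scripts/latticegel-cli.R`
(`simulate`, `analyze`, `theory`, `seqmetrics` subcommands over YAML
configs and plain-text snapshots).

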