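## experiment_runner: concentration sweeps at fixed molecule count (box
## resizing), affinity sweeps, phase-diagram assembly and test fixtures.

#' Specification of a simulation sweep
#'
#' Concentration is titrated at fixed molecule number by changing the
#' box side length. Affinities are magnitudes in kB*T (the bound-pair
#' energy is `-affinity`).
#'
#' @param valence symmetric valence of the poly-SH3/poly-PRM pair.
#' @param linkerN,linkerE linker geometry (sites / explicit beads).
#' @param moleculesPerSpecies copies of each species (total molecules =
#'   2x this).
#' @param boxLengths increasing vector of box sides.
#' @param affinity affinity magnitudes in kB*T.
#' @param steps MC attempts per state point.
#' @param sampleStride sampling stride.
#' @param replicates independent runs per point.
#' @param seed base seed (replicate r at box i uses a derived seed).
#' @param phiCC,rhoCutoff classification thresholds.
#' @param init initial condition: `"dispersed"` (random insertion) or
#'   `"dense"` (equilibrate a gel in a small `denseBoxL` box for
#'   `denseSteps` attempts, then expand it into each target box via
#'   [expandState()]). The dense start circumvents nucleation-limited
#'   equilibration inside the two-phase region.
#' @param denseBoxL,denseSteps dense-start parameters.
#' @param schedule move-type weights (see [runMC()]). `NULL` (default)
#'   picks a cost-aware schedule: uniform over binding flips, pivots,
#'   crankshafts and cluster translations, plus reptation at full
#'   weight for implicit linkers (where it is cheap and dramatically
#'   accelerates condensation), at weight 0.02 for lightly explicit
#'   linkers, and omitted for heavily explicit linkers whose exhaustive
#'   placement count (6^e per attempt) would dominate the runtime. The
#'   schedule never changes the stationary distribution (verified
#'   against exhaustive enumeration), only the mixing rate.
#' @return classed list (`"SweepSpec"`).
#' @export
sweepSpec <- function(valence = 5, linkerN = 5, linkerE = 0,
                      moleculesPerSpecies = 24,
                      boxLengths = c(24, 29, 34, 42, 52),
                      affinity = 2, steps = 1e6,
                      sampleStride = max(1, floor(steps / 400)),
                      replicates = 1, seed = 1,
                      phiCC = 0.17, rhoCutoff = 1.08,
                      rhoReference = c("dispersed", "lattice"),
                      init = c("dispersed", "dense"), denseBoxL = 17,
                      denseSteps = 5e6, schedule = NULL) {
  rhoReference <- match.arg(rhoReference)
  init <- match.arg(init)
  if (is.null(schedule)) {
    wRept <- if (linkerE == 0) 1 else if (linkerE <= 3) 0.02 else 0
    schedule <- c(binding_flip = 1, end_pivot = 1, crankshaft = 1,
                  cluster_translate = 1, reptation = wRept)
    schedule <- schedule[schedule > 0]
  }
  stopifnot(!is.unsorted(boxLengths), length(boxLengths) >= 1,
            !is.unsorted(affinity))
  out <- list(valence = valence, linkerN = linkerN, linkerE = linkerE,
              moleculesPerSpecies = moleculesPerSpecies,
              boxLengths = as.integer(boxLengths), affinity = affinity,
              steps = steps, sampleStride = sampleStride,
              replicates = replicates, seed = seed, phiCC = phiCC,
              rhoCutoff = rhoCutoff, rhoReference = rhoReference,
              init = init, denseBoxL = denseBoxL, denseSteps = denseSteps,
              schedule = schedule)
  class(out) <- "SweepSpec"
  out
}

.specSpecies <- function(spec) {
  list(polySH3(spec$valence, spec$linkerN, spec$linkerE),
       polyPRM(spec$valence, spec$linkerN, spec$linkerE))
}

.refRadius <- function(spec, L) {
  if (identical(spec$rhoReference, "lattice")) latticeRadius(L)
  else dispersedRadius(latticeConfig(L), .specSpecies(spec),
                       rep(spec$moleculesPerSpecies, 2),
                       seed = spec$seed + L)
}

.runPoint <- function(spec, L, affinity, replicate, refRadius,
                      denseState = NULL) {
  seed <- (spec$seed * 7919L + which(spec$boxLengths == L) * 104729L +
             round(affinity * 1000) + replicate * 13L) %% .Machine$integer.max
  st <- if (is.null(denseState)) {
    buildSystem(latticeConfig(L), .specSpecies(spec),
                rep(spec$moleculesPerSpecies, 2),
                interactionModel(uSP = -affinity), seed = seed)
  } else {
    set.seed(seed)
    expandState(denseState, L)
  }
  run <- runMC(st, spec$steps, schedule = spec$schedule,
               sampleStride = spec$sampleStride)
  tm <- trajectoryMeans(run$samples)
  ## rho is the reference radius over the ensemble-averaged Rg (not the
  ## average of per-frame ratios)
  tm$rho <- refRadius / tm$Rg
  cc <- concentrations(st)
  cbind(data.frame(boxL = L, affinity = affinity, replicate = replicate,
                   concDomains = cc["domainsPerSite"],
                   concDomainsA = cc["domainsPerSite"] / 2,  # per species
                   concPolymers = cc["polymersPerSite"],
                   NT = nMolecules(st), row.names = NULL),
        tm)
}

#' Concentration sweep at fixed molecule count
#'
#' Runs the MC model at every box length of the spec (largest box =
#' lowest concentration), averages phi_c and rho over the final half of
#' each trajectory, averages replicates, and classifies each point.
#' Points failing the split-half equilibration check are flagged, never
#' silently averaged away.
#'
#' @param spec a [sweepSpec()].
#' @param affinity affinity magnitude to use (default: first of the
#'   spec's grid).
#' @return data.frame ordered by increasing concentration with columns
#'   boxL, concDomains, concPolymers, phiC, rho, NN, gel, twoPhase,
#'   equilibrated.
#' @export
sweepConcentration <- function(spec, affinity = spec$affinity[1]) {
  denseState <- NULL
  if (identical(spec$init, "dense")) {
    ## equilibrate a gel in a small box once, then expand it to every
    ## target box (the dense-phase initialization protocol)
    st0 <- buildSystem(latticeConfig(spec$denseBoxL), .specSpecies(spec),
                       rep(spec$moleculesPerSpecies, 2),
                       interactionModel(uSP = -affinity),
                       seed = spec$seed + 271L)
    denseState <- runMC(st0, spec$denseSteps, schedule = spec$schedule,
                        sampleStride = 0, seed = spec$seed + 272L)$state
  }
  rows <- list()
  for (L in spec$boxLengths) {
    refR <- .refRadius(spec, L)
    for (r in seq_len(spec$replicates))
      rows[[length(rows) + 1L]] <- .runPoint(spec, L, affinity, r, refR,
                                             denseState)
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per, per$boxL), function(d) {
    data.frame(boxL = d$boxL[1], affinity = affinity,
               concDomains = d$concDomains[1],
               concDomainsA = d$concDomainsA[1],
               concPolymers = d$concPolymers[1], NT = d$NT[1],
               phiC = mean(d$phiC), rho = mean(d$rho), NN = mean(d$NN),
               Rg = mean(d$Rg), energy = mean(d$energy),
               equilibrated = all(d$equilibrated),
               nReplicates = nrow(d))
  }))
  agg <- agg[order(agg$concDomains), ]
  agg$gel <- agg$phiC > spec$phiCC
  agg$twoPhase <- agg$rho > spec$rhoCutoff
  rownames(agg) <- NULL
  agg
}

#' Assemble a two-parameter phase diagram
#'
#' Sweeps concentration at every affinity on the grid, detects two-phase
#' points by `rho > rhoCutoff`, converts them to coexistence
#' concentrations via the droplet-radius quintic, extracts the gel line
#' from the phi_c crossings, and estimates the critical point as the
#' lowest affinity with a detected two-phase interval. A warning is
#' issued if the width of the two-phase interval fails to grow with
#' affinity.
#'
#' @param spec a [sweepSpec()] whose `affinity` spans the candidate
#'   critical region.
#' @return a [PhaseDiagram-class].
#' @export
mapPhaseDiagram <- function(spec) {
  grids <- lapply(spec$affinity, function(a) sweepConcentration(spec, a))
  grid <- do.call(rbind, grids)
  bounds <- do.call(rbind, lapply(grids, function(g) {
    a <- g$affinity[1]
    cg <- gelPointFromSweep(g$concPolymers, g$phiC, spec$phiCC)
    two <- g[g$twoPhase, , drop = FALSE]
    if (nrow(two)) {
      cs <- t(vapply(seq_len(nrow(two)), function(i) {
        rn <- dropletRadius(two$NT[i], round(two$NN[i]), two$boxL[i],
                            two$Rg[i])
        phaseBoundaries(two$NT[i], round(two$NN[i]), two$boxL[i], rn)
      }, numeric(2)))
      data.frame(affinity = a, cg = cg, csl = mean(cs[, "csl"]),
                 csh = mean(cs[, "csh"]), nTwoPhase = nrow(two))
    } else data.frame(affinity = a, cg = cg, csl = NA_real_,
                      csh = NA_real_, nTwoPhase = 0L)
  }))
  width <- bounds$csh - bounds$csl
  wd <- width[!is.na(width)]
  if (length(wd) > 1 && any(diff(wd) < 0))
    warning("two-phase interval width is not monotone in affinity")
  iCrit <- which(bounds$nTwoPhase > 0)
  critical <- if (length(iCrit)) {
    a <- bounds$affinity[min(iCrit)]
    cc <- mean(grid$concPolymers[grid$affinity == a & grid$twoPhase])
    c(affinity = a, concentration = cc)
  } else c(affinity = NA_real_, concentration = NA_real_)
  new("PhaseDiagram", grid = grid, boundaries = bounds,
      critical = critical,
      thresholds = c(phiCC = spec$phiCC, rhoCutoff = spec$rhoCutoff))
}

#' @export
setMethod("show", "PhaseDiagram", function(object) {
  cat("PhaseDiagram:", nrow(object@grid), "state points,",
      nrow(object@boundaries), "affinities\n")
  if (is.finite(object@critical["affinity"]))
    cat(sprintf("  critical point: %.2f kB*T at %.3g polymers/site\n",
                object@critical["affinity"],
                object@critical["concentration"]))
  else cat("  no two-phase point detected on the grid\n")
})

#' Re-embed a state into a larger box
#'
#' Expands the lattice boundary around an equilibrated (typically
#' dense) configuration to reach a lower concentration, the
#' dense-phase initialization protocol. Each molecule keeps the
#' periodic image selected by its first domain: the chain is unwrapped
#' bead-by-bead by minimum image from the first domain and re-wrapped
#' in the new box. Bonds whose partners end up non-adjacent after
#' re-imaging are dissolved (they re-form during equilibration);
#' molecules that collide after unwrapping are shifted to free
#' positions.
#'
#' @param state a `SystemState`.
#' @param newL new box side (>= current).
#' @param maxTries relocation attempts per colliding molecule.
#' @return a valid `SystemState` in the larger box.
#' @export
expandState <- function(state, newL, maxTries = 200L) {
  L <- state@config@L
  newL <- as.integer(newL)
  stopifnot(newL >= L)
  co <- state@coords
  nm <- nMolecules(state)
  out <- co
  for (m in seq_len(nm)) {
    idx <- which(state@beadMol == m)
    for (k in seq_along(idx)[-1]) {
      i <- idx[k]; p <- idx[k - 1]
      d <- co[i, ] - co[p, ]
      d <- ((d + L %/% 2) %% L) - L %/% 2      # minimum-image step
      out[i, ] <- out[p, ] + d
    }
  }
  out <- out %% newL
  ## resolve rare collisions by translating whole molecules
  occ <- new.env(hash = TRUE)
  key <- function(v) paste(v, collapse = ",")
  placed <- rep(FALSE, nrow(out))
  for (m in seq_len(nm)) {
    idx <- which(state@beadMol == m)
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      shift <- if (t == 1) c(0L, 0L, 0L)
               else sample.int(newL, 3, replace = TRUE) - 1L
      cand <- sweep(out[idx, , drop = FALSE], 2, -shift) %% newL
      keys <- apply(cand, 1, key)
      if (!any(vapply(keys, function(k) !is.null(occ[[k]]), logical(1))) &&
          !anyDuplicated(keys)) {
        out[idx, ] <- cand
        for (k in keys) occ[[k]] <- TRUE
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not re-embed molecule ", m)
  }
  state@coords <- out
  state@config <- latticeConfig(newL)
  ## dissolve bonds broken by re-imaging
  p <- state@partner
  bi <- which(!is.na(p) & seq_along(p) < p)
  for (i in bi) {
    j <- p[i]
    if (!.isAdjacent(out[i, ], out[j, ], newL)) {
      p[i] <- NA_integer_; p[j] <- NA_integer_
    }
  }
  state@partner <- p
  state@energy <- totalEnergy(state)
  methods::validObject(state)
  state
}

#' Deterministic miniature fixtures
#'
#' Small systems with known answers, used throughout the test suites:
#' * `"tiny-enumerable"`: one S and one P monomer on an L = 2 box
#'   (exhaustively enumerable; P(bound) closed form).
#' * `"dense-ball"`: 1000 point molecules, 900 uniform in a ball of
#'   radius 10 centered in an L = 100 box, 100 uniform outside - the
#'   construction oracle for the droplet-radius quintic. Coordinates
#'   are continuous (synthetic geometry, not a lattice state).
#' * `"uniform-gas"`: 200 monomers placed uniformly at random on an
#'   L = 20 lattice (rho ~ 1 calibration).
#' * `"bound-chain"`: 10 molecules of which a divalent PRM bridges two
#'   SH3 monomers, so phi_c = 0.3 exactly.
#'
#' @param kind fixture name.
#' @param seed integer seed.
#' @return fixture-specific list or `SystemState`.
#' @export
generateFixture <- function(kind = c("tiny-enumerable", "dense-ball",
                                     "uniform-gas", "bound-chain"),
                            seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  switch(kind,
    "tiny-enumerable" = {
      species <- list(moleculeTopology("S1", 1L, domainKind = "S"),
                      moleculeTopology("P1", 1L, domainKind = "P"))
      list(config = latticeConfig(2), species = species, counts = c(1L, 1L),
           interactions = interactionModel(uSP = -2),
           state = buildSystem(latticeConfig(2), species, c(1L, 1L),
                               interactionModel(uSP = -2), seed = seed))
    },
    "dense-ball" = {
      NT <- 1000L; NN <- 900L; L <- 100; r <- 10
      ctr <- c(L, L, L) / 2
      inBall <- matrix(NA_real_, 0, 3)
      while (nrow(inBall) < NN) {
        cand <- matrix(stats::runif(3 * NN, -r, r), ncol = 3)
        cand <- cand[rowSums(cand^2) <= r^2, , drop = FALSE]
        inBall <- rbind(inBall, cand)
      }
      inBall <- sweep(inBall[seq_len(NN), ], 2, ctr, "+")
      ## dilute phase: Latin-hypercube stratification per dimension. The
      ## droplet-radius root is sensitive to the background's second
      ## moment, which is additive across dimensions, so marginal
      ## stratification realizes the uniform-density ansatz with very
      ## low variance while every marginal stays exactly uniform.
      nOut <- NT - NN
      lhsDim <- function() (sample.int(nOut) - 1 + stats::runif(nOut)) / nOut * L
      outside <- cbind(lhsDim(), lhsDim(), lhsDim())
      inside <- rowSums(sweep(outside, 2, ctr)^2) <= r^2
      while (any(inside)) {     # the ball is 0.4% of the box; rare
        outside[inside, ] <- matrix(stats::runif(3 * sum(inside), 0, L),
                                    ncol = 3)
        inside <- rowSums(sweep(outside, 2, ctr)^2) <= r^2
      }
      coords <- rbind(inBall, outside)
      list(coords = coords, NT = NT, NN = NN, L = L, rTrue = r,
           Rg = rgPeriodic(coords, L))
    },
    "uniform-gas" = {
      cfg <- latticeConfig(20)
      buildSystem(cfg, list(moleculeTopology("S1", 1L, domainKind = "S")),
                  200L, seed = seed)
    },
    "bound-chain" = {
      cfg <- latticeConfig(12)
      species <- list(moleculeTopology("S1", 1L, domainKind = "S"),
                      moleculeTopology("P2", 2L, linkerN = 1L,
                                       domainKind = "P"))
      st <- buildSystem(cfg, species, c(9L, 1L), seed = seed)
      ## rebuild deterministic coordinates: P2 dimer at the center with
      ## two S monomers face-adjacent to its domains; spares far away
      co <- st@coords
      nb <- nBeads(st)
      pIdx <- which(st@beadKind == 2L)        # the two P domains
      co[pIdx[1], ] <- c(5L, 5L, 5L); co[pIdx[2], ] <- c(6L, 5L, 5L)
      sIdx <- which(st@beadKind == 1L)
      co[sIdx[1], ] <- c(4L, 5L, 5L); co[sIdx[2], ] <- c(7L, 5L, 5L)
      spare <- sIdx[-(1:2)]
      co[spare, ] <- cbind(seq_along(spare), 1L, 9L)
      st@coords <- co
      p <- rep(NA_integer_, nb)
      p[pIdx[1]] <- sIdx[1]; p[sIdx[1]] <- pIdx[1]
      p[pIdx[2]] <- sIdx[2]; p[sIdx[2]] <- pIdx[2]
      st@partner <- p
      st@energy <- totalEnergy(st)
      methods::validObject(st)
      st
    })
}
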