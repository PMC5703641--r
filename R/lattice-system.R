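## lattice_system: the cubic-lattice world, molecule topologies, the
## interaction model and the system energy.

#' Create a lattice configuration
#'
#' @param L box side length in lattice units (integer >= 2).
#' @param connectivity neighbor definition for contacts; `"face"`
#'   (6-neighbor) adjacency is the lattice-standard contact rule.
#' @return a [LatticeConfig-class].
#' @examples
#' latticeConfig(10)
#' @export
latticeConfig <- function(L, connectivity = "face") {
  new("LatticeConfig", L = as.integer(L), periodic = TRUE,
      connectivity = connectivity)
}

#' Define a multivalent species
#'
#' @param species label, e.g. `"polySH3"`.
#' @param valence number of interaction domains.
#' @param linkerN linker length(s) in lattice sites; recycled to
#'   `valence - 1`.
#' @param linkerE explicit bead count(s) per linker, `0 <= e <= n`;
#'   recycled. `e = 0` gives an implicit (FRC-like) linker, `e = n` a
#'   fully explicit (SARC-like) linker.
#' @param domainKind `"S"` or `"P"`, or a vector of length `valence`.
#' @return a [MoleculeTopology-class].
#' @examples
#' moleculeTopology("polySH3", valence = 5, linkerN = 5, linkerE = 0,
#'                  domainKind = "S")
#' @export
moleculeTopology <- function(species, valence, linkerN = integer(),
                             linkerE = 0L, domainKind = "S") {
  valence <- as.integer(valence)
  nl <- max(valence - 1L, 0L)
  new("MoleculeTopology", species = species, valence = valence,
      domainKinds = rep_len(domainKind, valence),
      linkerN = rep_len(as.integer(linkerN), nl),
      linkerE = rep_len(as.integer(linkerE), nl))
}

#' @rdname moleculeTopology
#' @export
polySH3 <- function(valence, linkerN = 5L, linkerE = 0L)
  moleculeTopology("polySH3", valence, linkerN, linkerE, "S")

#' @rdname moleculeTopology
#' @export
polyPRM <- function(valence, linkerN = 5L, linkerE = 0L)
  moleculeTopology("polyPRM", valence, linkerN, linkerE, "P")

#' Contact-energy model
#'
#' @param uSP S-P bound-pair energy in kB*T (default -2, the intrinsic
#'   SH3/PRM affinity).
#' @param uSS,uPP,uLL,uSL,uPL nonspecific adjacency energies (default 0).
#' @return an [InteractionModel-class].
#' @export
interactionModel <- function(uSP = -2, uSS = 0, uPP = 0, uLL = 0,
                             uSL = 0, uPL = 0) {
  en <- matrix(c(uSS, uSP, uSL,
                 uSP, uPP, uPL,
                 uSL, uPL, uLL), 3, 3,
               dimnames = list(.KIND_LEVELS, .KIND_LEVELS))
  new("InteractionModel", energies = en)
}

## chain layout of one molecule: bead kinds plus the tether constraint
## from each bead to the next (1 = face adjacency, 2 = Chebyshev cap)
.beadLayout <- function(top) {
  V <- top@valence
  kind <- integer(0); linkType <- integer(0); linkCap <- integer(0)
  dk <- match(top@domainKinds, .KIND_LEVELS)
  for (i in seq_len(V)) {
    kind <- c(kind, dk[i])
    if (i < V) {
      n <- top@linkerN[i]; e <- top@linkerE[i]
      if (e > 0L) {
        linkType <- c(linkType, 1L); linkCap <- c(linkCap, 0L)   # domain -> L1
        if (e > 1L) {
          linkType <- c(linkType, rep(1L, e - 1L))
          linkCap <- c(linkCap, rep(0L, e - 1L))
        }
        kind <- c(kind, rep(3L, e))
        if (e == n) { linkType <- c(linkType, 1L); linkCap <- c(linkCap, 0L) }
        else { linkType <- c(linkType, 2L); linkCap <- c(linkCap, n - e) }
      } else {
        linkType <- c(linkType, 2L); linkCap <- c(linkCap, n)
      }
    }
  }
  linkType <- c(linkType, 0L); linkCap <- c(linkCap, 0L)  # last bead: none
  list(kind = kind, linkType = linkType, linkCap = linkCap)
}

.siteIndex <- function(coords, L) {
  coords[, 1] + L * (coords[, 2] + L * coords[, 3]) + 1L
}

#' Build a randomly dispersed system
#'
#' Places `counts[i]` copies of each species on the lattice by sequential
#' random insertion (all domains unbound), mirroring initial conditions in
#' which the multivalent proteins are randomly dispersed. Placement is
#' reproducible under `seed`.
#'
#' @param config a [LatticeConfig-class].
#' @param species list of [MoleculeTopology-class].
#' @param counts integer vector, molecules per species.
#' @param interactions an [InteractionModel-class].
#' @param seed optional integer seed.
#' @param maxTries placement retries per molecule before giving up.
#' @return a valid [SystemState-class] with energy 0.
#' @examples
#' st <- buildSystem(latticeConfig(10),
#'                   list(polySH3(2, 3), polyPRM(2, 3)), c(2, 2))
#' nBeads(st)
#' @export
buildSystem <- function(config, species, counts,
                        interactions = interactionModel(), seed = NULL,
                        maxTries = 500L) {
  stopifnot(length(species) == length(counts))
  if (!is.null(seed)) set.seed(seed)
  L <- config@L
  layouts <- lapply(species, .beadLayout)
  beadsPer <- vapply(layouts, function(l) length(l$kind), integer(1))
  totalBeads <- sum(beadsPer * counts)
  if (totalBeads > L^3)
    stop("capacity error: ", totalBeads, " beads requested on ", L^3, " sites")

  molSpecies <- rep(seq_along(species), counts)
  nm <- length(molSpecies)
  coords <- matrix(0L, totalBeads, 3)
  occ <- logical(L^3)
  row <- 0L
  for (m in seq_len(nm)) {
    lay <- layouts[[molSpecies[m]]]
    nb <- length(lay$kind)
    placed <- FALSE
    for (tries in seq_len(maxTries)) {
      pos <- matrix(0L, nb, 3)
      pos[1, ] <- sample.int(L, 3, replace = TRUE) - 1L
      ok <- !occ[.siteIndex(pos[1, , drop = FALSE], L)]
      if (ok) {
        for (b in seq_len(nb - 1L)) {
          lt <- lay$linkType[b]; cap <- lay$linkCap[b]
          good <- FALSE
          for (sub in 1:25) {
            if (lt == 1L) {
              d <- diag(3)[sample.int(3, 1), ] * sample(c(-1L, 1L), 1)
              cand <- (pos[b, ] + d) %% L
            } else {
              cand <- (pos[b, ] + sample.int(2L * cap + 1L, 3, replace = TRUE) -
                         cap - 1L) %% L
            }
            si <- .siteIndex(matrix(cand, 1), L)
            if (!occ[si] &&
                !any(pos[seq_len(b), 1] == cand[1] & pos[seq_len(b), 2] == cand[2] &
                     pos[seq_len(b), 3] == cand[3])) {
              pos[b + 1L, ] <- as.integer(cand); good <- TRUE; break
            }
          }
          if (!good) { ok <- FALSE; break }
        }
      }
      if (ok) {
        occ[.siteIndex(pos, L)] <- TRUE
        coords[row + seq_len(nb), ] <- pos
        row <- row + nb
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("capacity error: could not place molecule ", m, " after ",
           maxTries, " tries (density too high)")
  }
  new("SystemState", config = config, interactions = interactions,
      species = species, moleculeSpecies = as.integer(molSpecies),
      coords = coords,
      beadKind = unlist(lapply(molSpecies, function(i) layouts[[i]]$kind)),
      beadMol = rep(seq_len(nm), beadsPer[molSpecies]),
      partner = rep(NA_integer_, totalBeads),
      energy = 0)
}

## accessors -----------------------------------------------------------

#' @rdname nBeads
#' @export
setMethod("nBeads", "SystemState", function(object) nrow(object@coords))

#' @rdname nBeads
#' @export
setMethod("nMolecules", "SystemState",
          function(object) length(object@moleculeSpecies))

#' Bead table of a system state
#'
#' @param state a `SystemState`.
#' @return data.frame with molecule, bead, kind, x, y, z, partner
#'   (1-based global bead index or `NA`).
#' @export
beadTable <- function(state) {
  data.frame(molecule = state@beadMol,
             bead = seq_len(nBeads(state)),
             kind = .KIND_LEVELS[state@beadKind],
             x = state@coords[, 1], y = state@coords[, 2],
             z = state@coords[, 3],
             partner = state@partner)
}

#' @export
setMethod("show", "SystemState", function(object) {
  nb <- nBeads(object); nm <- nMolecules(object)
  nbonds <- sum(!is.na(object@partner)) / 2
  cat("SystemState:", nm, "molecules,", nb, "beads on L =",
      object@config@L, "lattice\n")
  cat("  bonds:", nbonds, " cached energy:", object@energy, "kB*T\n")
})

#' @export
setMethod("show", "MoleculeTopology", function(object) {
  cat("MoleculeTopology", object@species, ": valence", object@valence)
  if (object@valence > 1)
    cat(", linkers n =", paste(object@linkerN, collapse = ","),
        "(explicit e =", paste(object@linkerE, collapse = ","), ")")
  cat("\n")
})

#' @export
setMethod("show", "LatticeConfig", function(object) {
  cat("LatticeConfig: L =", object@L, "(", object@L^3,
      "sites ), periodic,", object@connectivity, "connectivity\n")
})

## distances under the minimum image convention -------------------------

.mdist <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}

.isAdjacent <- function(p, q, L) {
  sum(.mdist(p, q, L)) == 1L
}

.chebDist <- function(p, q, L) {
  max(.mdist(p, q, L))
}

## energy ---------------------------------------------------------------

#' Total system energy
#'
#' Sums the configured bound-pair energies over all bound, face-adjacent
#' complementary (S-P) pairs, plus any nonzero nonspecific adjacency
#' energies among other bead-kind pairs (all zero under defaults).
#' Deterministic; raises an integrity error if a bound pair is not
#' adjacent or the binding map is asymmetric.
#'
#' @param object a `SystemState`.
#' @return energy in kB*T.
#' @export
setMethod("totalEnergy", "SystemState", function(object, ...) {
  L <- object@config@L
  en <- object@interactions@energies
  p <- object@partner
  E <- 0
  bi <- which(!is.na(p) & seq_along(p) < p)
  for (i in bi) {
    j <- p[i]
    if (is.na(p[j]) || p[j] != i)
      stop("integrity error: binding map is not symmetric at bead ", i)
    if (!.isAdjacent(object@coords[i, ], object@coords[j, ], L))
      stop("integrity error: bound pair ", i, "-", j, " is not adjacent")
    E <- E + en[object@beadKind[i], object@beadKind[j]]
  }
  ## nonspecific adjacency terms (non S-P pairs only; S-P is bound-state
  ## specific). Defaults are all zero, so skip the scan entirely then.
  nonspec <- en
  nonspec["S", "P"] <- nonspec["P", "S"] <- 0
  if (any(nonspec != 0)) {
    nb <- nBeads(object)
    occ <- integer(L^3)
    occ[.siteIndex(object@coords, L)] <- seq_len(nb)
    for (i in seq_len(nb)) {
      for (dim in 1:3) for (sgn in c(-1L, 1L)) {
        q <- object@coords[i, ]
        q[dim] <- (q[dim] + sgn) %% L
        j <- occ[.siteIndex(matrix(q, 1), L)]
        if (j > i) {
          ki <- object@beadKind[i]; kj <- object@beadKind[j]
          pair <- !((ki == 1 && kj == 2) || (ki == 2 && kj == 1))
          if (pair) E <- E + nonspec[ki, kj]
        }
      }
    }
  }
  E
})

## diagnostics ----------------------------------------------------------

#' Validate a system state
#'
#' Diagnostic check of every SystemState invariant: single occupancy,
#' tether constraints (face adjacency for explicit segments, Chebyshev
#' square well for implicit segments), binding-map symmetry, bound-pair
#' adjacency and complementarity, and energy-cache consistency.
#'
#' @param object a `SystemState`.
#' @return data.frame of violations (zero rows for a valid state) with
#'   columns `check` and `detail`.
#' @export
setMethod("validateState", "SystemState", function(object, ...) {
  bad <- list()
  note <- function(check, detail)
    bad[[length(bad) + 1L]] <<- data.frame(check = check, detail = detail)
  L <- object@config@L
  co <- object@coords
  if (nrow(co)) {
    key <- .siteIndex(co, L)
    dup <- which(duplicated(key))
    for (d in dup) note("double-occupancy", paste("bead", d))
    p <- object@partner
    for (i in which(!is.na(p))) {
      j <- p[i]
      if (is.na(p[j]) || p[j] != i) note("asymmetric-bond", paste("bead", i))
      else if (i < j) {
        if (!.isAdjacent(co[i, ], co[j, ], L))
          note("non-adjacent-bond", paste(i, j))
        ks <- sort(object@beadKind[c(i, j)])
        if (!identical(ks, c(1L, 2L)))
          note("non-complementary-bond", paste(i, j))
      }
    }
    ## tether contract per molecule
    start <- 1L
    for (m in seq_len(nMolecules(object))) {
      lay <- .beadLayout(object@species[[object@moleculeSpecies[m]]])
      nb <- length(lay$kind)
      for (b in seq_len(nb - 1L)) {
        i <- start + b - 1L
        lt <- lay$linkType[b]
        if (lt == 1L && !.isAdjacent(co[i, ], co[i + 1L, ], L))
          note("tether-break", paste("molecule", m, "link", b, "(adjacency)"))
        if (lt == 2L && .chebDist(co[i, ], co[i + 1L, ], L) > lay$linkCap[b])
          note("tether-break", paste("molecule", m, "link", b, "(square well)"))
      }
      start <- start + nb
    }
  }
  Efresh <- tryCatch(totalEnergy(object), error = function(e) NA_real_)
  if (is.na(Efresh)) note("energy-integrity", "totalEnergy failed")
  else if (abs(Efresh - object@energy) > 1e-9)
    note("energy-drift", sprintf("cached %.6g vs recomputed %.6g",
                                 object@energy, Efresh))
  if (length(bad)) do.call(rbind, bad)
  else data.frame(check = character(), detail = character())
})

## conversion to the C kernel representation ---------------------------

.stateToC <- function(state) {
  nm <- nMolecules(state)
  layouts <- lapply(state@species, .beadLayout)
  beadsPer <- vapply(layouts, function(l) length(l$kind), integer(1))
  nPer <- beadsPer[state@moleculeSpecies]
  molEnd <- cumsum(nPer)
  molStart <- molEnd - nPer
  linkType <- unlist(lapply(state@moleculeSpecies,
                            function(i) layouts[[i]]$linkType))
  linkCap <- unlist(lapply(state@moleculeSpecies,
                           function(i) layouts[[i]]$linkCap))
  homo <- vapply(state@species, function(tp) {
    tp@valence >= 2L && length(unique(tp@linkerN)) == 1L &&
      length(unique(tp@linkerE)) == 1L
  }, logical(1))
  molLinkN <- ifelse(homo[state@moleculeSpecies],
                     vapply(state@species, function(tp)
                       if (tp@valence >= 2L) tp@linkerN[1] else -1L,
                       integer(1))[state@moleculeSpecies], -1L)
  molLinkE <- ifelse(homo[state@moleculeSpecies],
                     vapply(state@species, function(tp)
                       if (tp@valence >= 2L) tp@linkerE[1] else -1L,
                       integer(1))[state@moleculeSpecies], -1L)
  en <- state@interactions@energies
  nonspec <- en; nonspec["S", "P"] <- nonspec["P", "S"] <- 0
  if (any(nonspec != 0))
    stop("the MC kernel supports only the specific S-P bound-pair energy; ",
         "nonspecific adjacency energies must be zero")
  list(L = state@config@L, coords = state@coords,
       kind = state@beadKind - 1L, mol = state@beadMol - 1L,
       partner = ifelse(is.na(state@partner), -1L, state@partner - 1L),
       molStart = as.integer(molStart), molEnd = as.integer(molEnd),
       linkType = as.integer(linkType), linkCap = as.integer(linkCap),
       molLinkN = as.integer(molLinkN), molLinkE = as.integer(molLinkE),
       uSP = en["S", "P"])
}

.updateStateFromC <- function(state, coords, partner, energy) {
  state@coords <- coords
  state@partner <- ifelse(partner < 0L, NA_integer_, partner + 1L)
  state@energy <- energy
  state
}

#' Domain concentration of a state
#'
#' @param state a `SystemState`.
#' @return named numeric: `domainsPerSite` and `polymersPerSite`
#'   ("polymers/voxel").
#' @export
concentrations <- function(state) {
  V3 <- as.numeric(state@config@L)^3
  c(domainsPerSite = sum(state@beadKind != 3L) / V3,
    polymersPerSite = nMolecules(state) / V3)
}
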