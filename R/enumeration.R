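## Exhaustive enumeration of tiny systems: the independent oracle used to
## validate microscopic reversibility of the Monte Carlo kernel.

#' Exhaustively enumerate all microstates of a tiny system
#'
#' Enumerates every valid bead placement (respecting excluded volume and
#' all tether constraints) combined with every admissible binding
#' assignment (a partial matching of face-adjacent complementary S-P
#' domain pairs), and returns Boltzmann probabilities proportional to
#' `exp(-E)` together with derived observables. Intended for systems
#' with at most a few thousand placements; refuses to enumerate beyond
#' `cap` microstates.
#'
#' @param config a [LatticeConfig-class].
#' @param species list of [MoleculeTopology-class].
#' @param counts molecules per species.
#' @param interactions an [InteractionModel-class]; only the specific
#'   S-P bound-pair energy may be nonzero.
#' @param cap hard cap on the number of microstates.
#' @param keepStates if `TRUE` (default) return the per-microstate table
#'   (key, energy, weight, probability) for distribution-level
#'   comparisons against sampled trajectories.
#' @return list: `nStates`, `Z`, `meanEnergy`, `meanBonds`, `pBound`
#'   (probability of at least one bond), and `states` (or `NULL`).
#' @examples
#' # one S and one P monomer on a 2^3 box: Z = 56 + 24*exp(2)
#' en <- exactEnumeration(latticeConfig(2),
#'         list(moleculeTopology("S1", 1, domainKind = "S"),
#'              moleculeTopology("P1", 1, domainKind = "P")), c(1, 1))
#' en$pBound
#' @export
exactEnumeration <- function(config, species, counts,
                             interactions = interactionModel(),
                             cap = 1e7, keepStates = TRUE) {
  L <- config@L
  en <- interactions@energies
  nonspec <- en; nonspec["S", "P"] <- nonspec["P", "S"] <- 0
  if (any(nonspec != 0))
    stop("enumeration supports only the specific S-P bound-pair energy")
  uSP <- en["S", "P"]

  molSpecies <- rep(seq_along(species), counts)
  layouts <- lapply(species, .beadLayout)
  kind <- unlist(lapply(molSpecies, function(i) layouts[[i]]$kind))
  linkType <- unlist(lapply(molSpecies, function(i) layouts[[i]]$linkType))
  linkCap <- unlist(lapply(molSpecies, function(i) layouts[[i]]$linkCap))
  beadsPer <- vapply(layouts, function(l) length(l$kind), integer(1))[molSpecies]
  firstBead <- cumsum(beadsPer) - beadsPer + 1L
  nb <- sum(beadsPer)

  allSites <- as.matrix(expand.grid(x = 0:(L - 1), y = 0:(L - 1),
                                    z = 0:(L - 1)))[, c("x", "y", "z")]
  storage.mode(allSites) <- "integer"

  nStates <- 0; Z <- 0; sumE <- 0; sumB <- 0; Zbound <- 0
  keys <- character(); eng <- numeric(); wts <- numeric()

  pos <- matrix(0L, nb, 3)
  occ <- logical(L^3)

  candidateSites <- function(prev, lt, capn) {
    if (lt == 1L) {
      d <- rbind(c(1L,0L,0L), c(-1L,0L,0L), c(0L,1L,0L), c(0L,-1L,0L),
                 c(0L,0L,1L), c(0L,0L,-1L))
      s <- sweep(d, 2, prev, "+") %% L
      s[!duplicated(.siteIndex(s, L)), , drop = FALSE]
    } else {
      off <- as.matrix(expand.grid(-capn:capn, -capn:capn, -capn:capn))
      s <- sweep(off, 2, prev, "+") %% L
      storage.mode(s) <- "integer"
      s[!duplicated(.siteIndex(s, L)), , drop = FALSE]
    }
  }

  ## binding assignments of one complete placement
  enumBindings <- function() {
    pairs <- list()
    for (i in seq_len(nb)) {
      if (kind[i] == 3L) next
      for (j in seq_len(nb)) {
        if (j <= i || kind[j] == 3L) next
        if (kind[i] + kind[j] == 3L && .isAdjacent(pos[i, ], pos[j, ], L))
          pairs[[length(pairs) + 1L]] <- c(i, j)
      }
    }
    partner <- rep(-1L, nb)
    recB <- function(k, nbonds) {
      if (k > length(pairs)) {
        E <- nbonds * uSP
        wt <- exp(-E)
        nStates <<- nStates + 1
        if (nStates > cap) stop("enumeration cap exceeded")
        Z <<- Z + wt; sumE <<- sumE + E * wt; sumB <<- sumB + nbonds * wt
        if (nbonds > 0) Zbound <<- Zbound + wt
        if (keepStates) {
          keys[[length(keys) + 1L]] <<-
            paste(c(t(pos), partner), collapse = ",")
          eng[[length(eng) + 1L]] <<- E
          wts[[length(wts) + 1L]] <<- wt
        }
        return(invisible())
      }
      recB(k + 1L, nbonds)                       # pair k unbound
      i <- pairs[[k]][1]; j <- pairs[[k]][2]
      if (partner[i] < 0L && partner[j] < 0L) {  # pair k bound
        partner[i] <<- j - 1L; partner[j] <<- i - 1L
        recB(k + 1L, nbonds + 1L)
        partner[i] <<- -1L; partner[j] <<- -1L
      }
      invisible()
    }
    recB(1L, 0L)
  }

  recP <- function(b) {
    if (b > nb) { enumBindings(); return(invisible()) }
    cands <- if (b %in% firstBead) allSites
             else candidateSites(pos[b - 1L, ], linkType[b - 1L],
                                 linkCap[b - 1L])
    for (r in seq_len(nrow(cands))) {
      si <- .siteIndex(cands[r, , drop = FALSE], L)
      if (occ[si]) next
      pos[b, ] <<- cands[r, ]
      occ[si] <<- TRUE
      recP(b + 1L)
      occ[si] <<- FALSE
    }
    invisible()
  }
  recP(1L)

  states <- NULL
  if (keepStates)
    states <- data.frame(key = unlist(keys), energy = unlist(eng),
                         weight = unlist(wts),
                         prob = unlist(wts) / Z)
  list(nStates = nStates, Z = Z, meanEnergy = sumE / Z,
       meanBonds = sumB / Z, pBound = Zbound / Z, states = states)
}

#' Canonical microstate key of a trajectory frame
#'
#' Converts a frame recorded by [runMC()] (`keepFrames = TRUE`) into the
#' same key format produced by [exactEnumeration()], so sampled state
#' frequencies can be compared to exact probabilities.
#'
#' @param frame integer matrix (beads x 4: x, y, z, 0-based partner or
#'   -1).
#' @return character key.
#' @export
frameKey <- function(frame) {
  paste(c(t(frame[, 1:3, drop = FALSE]), frame[, 4]), collapse = ",")
}

#' Lattice-unit dissociation constant of the S-P contact
#'
#' Derives the dissociation constant (domains per site) implied by a
#' bound-pair energy `uSP` from the statistics of a single S + P domain
#' pair on the lattice: for a finite box the exhaustive enumerator gives
#' the bound probability directly, and in the dilute (large-L) limit
#' `Kd = 1 / (6 * exp(-uSP))`, six being the number of distinct bound
#' orientations per site under face connectivity.
#'
#' @param uSP bound-pair energy in kB*T (default -2).
#' @param L box side, or `Inf` (default) for the dilute-limit value.
#' @return Kd in domains per site.
#' @examples
#' latticeKd(-2)            # 1 / (6 e^2)
#' @export
latticeKd <- function(uSP = -2, L = Inf) {
  if (is.infinite(L)) return(1 / (6 * exp(-uSP)))
  enres <- exactEnumeration(latticeConfig(L),
    list(moleculeTopology("S1", 1L, domainKind = "S"),
         moleculeTopology("P1", 1L, domainKind = "P")),
    c(1L, 1L), interactionModel(uSP = uSP), keepStates = FALSE)
  P <- enres$pBound
  (1 - P)^2 / (P * L^3)
}
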