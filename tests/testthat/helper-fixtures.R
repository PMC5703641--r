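## shared helpers: independent oracles kept deliberately naive

## O(B^2) energy oracle: double loop over all bead pairs
energyOracle <- function(state) {
  co <- state@coords
  L <- state@config@L
  en <- state@interactions@energies
  E <- 0
  nb <- nrow(co)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    if (j <= i) next
    d <- abs(co[i, ] - co[j, ]) %% L
    d <- pmin(d, L - d)
    adjacent <- sum(d) == 1
    ki <- state@beadKind[i]; kj <- state@beadKind[j]
    bound <- !is.na(state@partner[i]) && state@partner[i] == j
    if (ki + kj == 3L && ki != kj) {     # S-P pair
      if (bound && adjacent) E <- E + en["S", "P"]
    } else if (adjacent) {
      E <- E + en[ki, kj]
    }
  }
  E
}

## breadth-first-search component oracle on the molecule bond graph
bfsClusterOracle <- function(beadMol, partner, nm) {
  adj <- vector("list", nm)
  bi <- which(!is.na(partner) & seq_along(partner) < partner)
  for (i in bi) {
    a <- beadMol[i]; b <- beadMol[partner[i]]
    if (a != b) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  seen <- logical(nm)
  sizes <- integer(0)
  for (m0 in seq_len(nm)) {
    if (seen[m0]) next
    queue <- m0; seen[m0] <- TRUE; sz <- 0L
    while (length(queue)) {
      m <- queue[1]; queue <- queue[-1]; sz <- sz + 1L
      for (nb in adj[[m]]) if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
    sizes <- c(sizes, sz)
  }
  sizes
}

## scramble a valid state with random accepted bonds between adjacent
## complementary monomers (for cluster/energy oracle comparisons)
randomBondedMonomers <- function(nS = 15, nP = 15, L = 8, pBond = 0.6,
                                 seed = 1) {
  set.seed(seed)
  st <- buildSystem(latticeConfig(L),
                    list(moleculeTopology("S1", 1L, domainKind = "S"),
                         moleculeTopology("P1", 1L, domainKind = "P")),
                    c(nS, nP))
  co <- st@coords
  p <- st@partner
  for (i in seq_len(nS)) {
    if (!is.na(p[i])) next
    for (j in nS + seq_len(nP)) {
      j <- as.integer(j)
      if (!is.na(p[j])) next
      d <- abs(co[i, ] - co[j, ]) %% L; d <- pmin(d, L - d)
      if (sum(d) == 1 && runif(1) < pBond) { p[i] <- j; p[j] <- i; break }
    }
  }
  st@partner <- p
  st@energy <- totalEnergy(st)
  st
}

tinySpecies <- function() {
  list(moleculeTopology("S1", 1L, domainKind = "S"),
       moleculeTopology("P1", 1L, domainKind = "P"))
}
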