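test_that("acceptMove implements min(1, w exp(-dE))", {
  expect_true(acceptMove(-1, 1))                    # downhill always accepted
  set.seed(1)
  f <- mean(replicate(1e5, acceptMove(2, 1)))
  expect_lt(abs(f - exp(-2)), 3 * sqrt(exp(-2) / 1e5))
  set.seed(2)
  f2 <- mean(replicate(1e5, acceptMove(0, 0.5)))
  expect_lt(abs(f2 - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_error(acceptMove(0, 0), "positive")
  expect_error(acceptMove(Inf, 1), "finite")
})

test_that("proposals do not mutate the state they are drawn from", {
  st <- buildSystem(latticeConfig(8), list(polySH3(3, 3, 1), polyPRM(3, 3, 1)),
                    c(3, 3), seed = 1)
  run <- runMC(st, 5e3, sampleStride = 0, seed = 2)  # create some bonds
  st <- run$state
  before <- list(st@coords, st@partner, st@energy)
  set.seed(3)
  for (mv in c("binding_flip", "end_pivot", "crankshaft",
               "cluster_translate", "reptation")) {
    for (k in 1:20) proposeMove(st, mv)
    expect_identical(list(st@coords, st@partner, st@energy), before,
                     label = mv)
  }
})

test_that("applying then reverting a proposal restores the state bit-exactly", {
  st <- buildSystem(latticeConfig(8), list(polySH3(3, 3, 1), polyPRM(3, 3, 1)),
                    c(3, 3), seed = 4)
  st <- runMC(st, 5e3, sampleStride = 0, seed = 5)$state
  set.seed(6)
  tested <- character()
  for (k in 1:200) {
    mv <- sample(c("binding_flip", "end_pivot", "crankshaft",
                   "cluster_translate"), 1)
    pr <- proposeMove(st, mv)
    if (!pr@feasible) next
    tested <- union(tested, mv)
    s2 <- applyProposal(st, pr)
    expect_equal(nrow(validateState(s2)), 0, label = mv)
    ## build the inverse proposal by swapping old/new
    inv <- pr
    inv@dE <- -pr@dE
    inv@oldPartner <- pr@newPartner; inv@newPartner <- pr@oldPartner
    inv@oldPos <- pr@newPos; inv@newPos <- pr@oldPos
    if (mv == "cluster_translate")
      inv@details$delta <- -pr@details$delta
    s3 <- applyProposal(s2, inv)
    expect_identical(s3@coords, st@coords, label = mv)
    expect_identical(s3@partner, st@partner, label = mv)
    expect_equal(s3@energy, st@energy, label = mv)
    ## keep evolving so many distinct situations are covered
    st <- s2
  }
  expect_setequal(tested, c("binding_flip", "end_pivot", "crankshaft",
                            "cluster_translate"))
})

test_that("Hastings weights follow the interacting-state counts", {
  ## an isolated molecule translated into free space: dE = 0, w = 1
  st <- buildSystem(latticeConfig(10),
                    list(moleculeTopology("S1", 1, domainKind = "S")), 1L,
                    seed = 1)
  pr <- proposeMove(st, "cluster_translate")
  expect_true(pr@feasible)
  expect_equal(pr@dE, 0)
  expect_equal(pr@w, 1)

  ## binding flip between an adjacent unbound S-P pair: dE = -2, w = 1
  st2 <- buildSystem(latticeConfig(6), tinySpecies(), c(1L, 1L), seed = 1)
  co <- st2@coords
  co[1, ] <- c(0L, 0L, 0L); co[2, ] <- c(1L, 0L, 0L)
  st2@coords <- co
  set.seed(42)
  seen <- replicate(60, {
    pr <- proposeMove(st2, "binding_flip")
    pr@dE
  })
  expect_setequal(unique(seen), c(0, -2))
  ## both states admissible: Nc = Np = 2, w = 1
  pr <- proposeMove(st2, "binding_flip")
  expect_equal(unname(pr@counts["Nc"]), 2)
  expect_equal(pr@w, 1)

  ## end pivot and crankshaft report w = Np / Nc
  st3 <- buildSystem(latticeConfig(8), list(polySH3(3, 2, 0), polyPRM(3, 2, 0)),
                     c(2, 2), seed = 2)
  set.seed(7)
  for (k in 1:50) {
    pr <- proposeMove(st3, "end_pivot")
    if (pr@feasible)
      expect_equal(pr@w, unname(pr@counts["Np"] / pr@counts["Nc"]))
    pc <- proposeMove(st3, "crankshaft")
    if (pc@feasible)
      expect_equal(pc@w, unname(pc@counts["Np"] / pc@counts["Nc"]))
    pr <- proposeMove(st3, "reptation")
    if (pr@feasible)
      expect_equal(pr@w, unname((pr@counts["Np"] * pr@counts["Vp"]) /
                                  (pr@counts["Nc"] * pr@counts["Vc"])))
  }
})

test_that("runMC with zero steps returns the state unchanged", {
  st <- buildSystem(latticeConfig(6), tinySpecies(), c(2L, 2L), seed = 1)
  out <- runMC(st, 0)
  expect_identical(out$state@coords, st@coords)
  expect_equal(nrow(out$samples), 0)
})

test_that("energy cache equals from-scratch recomputation after long runs", {
  for (e in c(0L, 1L)) {
    st <- buildSystem(latticeConfig(10),
                      list(polySH3(3, 3, e), polyPRM(3, 3, e)), c(4, 4),
                      seed = 30 + e)
    run <- runMC(st, 1e5, sampleStride = 0, seed = 31 + e)
    expect_equal(run$state@energy, totalEnergy(run$state))
    expect_equal(nrow(validateState(run$state)), 0)
  }
})

test_that("runMC is bit-reproducible under seed and schedule", {
  st <- buildSystem(latticeConfig(9), list(polySH3(2, 2, 1), polyPRM(2, 2, 1)),
                    c(3, 3), seed = 8)
  r1 <- runMC(st, 2e4, sampleStride = 100, seed = 99)
  r2 <- runMC(st, 2e4, sampleStride = 100, seed = 99)
  expect_identical(r1$state@coords, r2$state@coords)
  expect_identical(r1$samples, r2$samples)
})

test_that("exact enumeration reproduces closed-form partition functions", {
  fx <- generateFixture("tiny-enumerable")
  en <- exactEnumeration(fx$config, fx$species, fx$counts, fx$interactions)
  ## 56 ordered placements of two monomers on 2^3 sites, 24 adjacent,
  ## each adjacent placement adding a bound state of weight e^2
  expect_equal(en$nStates, 80)
  expect_equal(en$Z, 56 + 24 * exp(2))
  expect_equal(en$pBound, 24 * exp(2) / (56 + 24 * exp(2)), tolerance = 1e-12)

  ## zero affinity: uniform measure over the same state count
  en0 <- exactEnumeration(fx$config, fx$species, fx$counts,
                          interactionModel(uSP = 0))
  expect_equal(en0$pBound, 24 / 80)

  ## single 2-domain chain with an implicit n = 1 linker on L = 3:
  ## 27 * 26 placements (Chebyshev shell has 26 distinct sites), of
  ## which 27 * 6 are face-adjacent and support one bond each
  chain <- list(moleculeTopology("SP", 2L, linkerN = 1L, linkerE = 0L,
                                 domainKind = c("S", "P")))
  enc <- exactEnumeration(latticeConfig(3), chain, 1L, interactionModel(-2))
  expect_equal(enc$nStates, 27 * 26 + 27 * 6)
  expect_error(
    exactEnumeration(latticeConfig(4), tinySpecies(), c(2L, 2L), cap = 100),
    "cap")
})

test_that("MC sampling matches exhaustive enumeration (detailed balance)", {
  ## two monomers on L = 2: per-state frequencies against Boltzmann
  fx <- generateFixture("tiny-enumerable")
  en <- exactEnumeration(fx$config, fx$species, fx$counts, fx$interactions)
  run <- runMC(fx$state, 6e5, sampleStride = 10, keepFrames = TRUE, seed = 42)
  keys <- vapply(run$frames, frameKey, character(1))
  keys <- keys[(length(keys) / 2 + 1):length(keys)]
  m <- length(keys)
  tab <- table(keys)
  obs <- as.numeric(tab[en$states$key]); obs[is.na(obs)] <- 0
  ## batch-means standard error per state (samples are autocorrelated)
  batch <- rep(seq_len(20), each = m / 20)
  zmax <- max(vapply(seq_len(nrow(en$states)), function(i) {
    ind <- as.numeric(keys == en$states$key[i])
    bm <- tapply(ind, batch, mean)
    se <- stats::sd(bm) / sqrt(20)
    if (se == 0) return(0)
    abs(mean(ind) - en$states$prob[i]) / se
  }, numeric(1)))
  expect_lt(zmax, 4)

  ## all five moves on a homotypic chain plus a ligand: aggregate bound
  ## probability against enumeration
  cfg <- latticeConfig(3)
  sp <- list(moleculeTopology("S2e", 2L, linkerN = 1L, linkerE = 1L,
                              domainKind = "S"),
             moleculeTopology("P1", 1L, domainKind = "P"))
  en2 <- exactEnumeration(cfg, sp, c(1L, 1L), interactionModel(-2),
                          keepStates = FALSE)
  st <- buildSystem(cfg, sp, c(1L, 1L), interactionModel(-2), seed = 5)
  run2 <- runMC(st, 2e6, sampleStride = 40, keepFrames = TRUE, seed = 13)
  half <- run2$frames[(length(run2$frames) / 2 + 1):length(run2$frames)]
  bnd <- vapply(half, function(f) any(f[, 4] >= 0), numeric(1))
  bm <- tapply(bnd, rep(seq_len(20), each = length(bnd) / 20), mean)
  se <- stats::sd(bm) / sqrt(20)
  expect_lt(abs(mean(bnd) - en2$pBound), 3 * se)
})

test_that("binding_flip alone samples the conditional Boltzmann law", {
  ## fixed adjacent S-P pair, only binding flips: P(bound) = e^2/(1+e^2)
  st <- buildSystem(latticeConfig(6), tinySpecies(), c(1L, 1L), seed = 1)
  co <- st@coords
  co[1, ] <- c(0L, 0L, 0L); co[2, ] <- c(1L, 0L, 0L)
  st@coords <- co
  run <- runMC(st, 2e5, schedule = c(binding_flip = 1), sampleStride = 10,
               keepFrames = TRUE, seed = 21)
  bnd <- vapply(run$frames, function(f) any(f[, 4] >= 0), numeric(1))
  bnd <- bnd[(length(bnd) / 2 + 1):length(bnd)]
  bm <- tapply(bnd, rep(seq_len(20), each = length(bnd) / 20), mean)
  pTheory <- exp(2) / (1 + exp(2))
  expect_lt(abs(mean(bnd) - pTheory), 3 * stats::sd(bm) / sqrt(20) + 1e-3)
})

test_that("lattice Kd from enumeration converges to the dilute limit", {
  kd <- vapply(c(4, 6, 8), function(L) latticeKd(-2, L), numeric(1))
  expect_true(all(diff(abs(kd - latticeKd(-2))) < 0))
  expect_lt(abs(latticeKd(-2, 8) - 1 / (6 * exp(2))) / latticeKd(-2), 0.35)
  expect_equal(latticeKd(-2), 1 / (6 * exp(2)))
})
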