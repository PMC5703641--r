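test_that("lattice configuration enforces its invariants", {
  cfg <- latticeConfig(10)
  expect_equal(cfg@L, 10L)
  expect_true(cfg@periodic)
  expect_error(latticeConfig(1), "L must be")
})

test_that("molecule topologies validate linker layouts", {
  top <- moleculeTopology("polySH3", 5, linkerN = 5, linkerE = 0,
                          domainKind = "S")
  expect_equal(top@valence, 5L)
  expect_length(top@linkerN, 4)
  expect_error(moleculeTopology("bad", 3, linkerN = 2, linkerE = 3),
               "0 <= e <= n")
  ## e = 0 implicit, e = n explicit, in-between hybrid
  lay0 <- latticegel:::.beadLayout(polySH3(2, 5, 0))
  expect_equal(lay0$kind, c(1L, 1L))
  expect_equal(lay0$linkType[1], 2L)       # Chebyshev well
  expect_equal(lay0$linkCap[1], 5L)
  lay5 <- latticegel:::.beadLayout(polySH3(2, 5, 5))
  expect_equal(sum(lay5$kind == 3L), 5)    # five explicit beads
  expect_true(all(lay5$linkType[1:6] == 1L))
  lay2 <- latticegel:::.beadLayout(polySH3(2, 5, 2))
  expect_equal(lay2$linkType[1:3], c(1L, 1L, 2L))
  expect_equal(lay2$linkCap[3], 3L)        # remaining implicit span
})

test_that("default interaction model matches the stickers-and-spacers setup", {
  im <- interactionModel()
  expect_equal(im@energies["S", "P"], -2)
  expect_equal(im@energies["S", "S"], 0)
  expect_equal(im@energies["L", "L"], 0)
  expect_identical(im@energies, t(im@energies))
})

test_that("buildSystem places molecules without overlap and unbound", {
  ## single monomer: no interactions possible
  st1 <- buildSystem(latticeConfig(2),
                     list(moleculeTopology("S1", 1, domainKind = "S")), 1L,
                     seed = 1)
  expect_equal(nBeads(st1), 1L)
  expect_equal(st1@energy, 0)

  ## production-scale geometry: 2.4e3 domains at valence 5 (480 chains)
  st <- buildSystem(latticeConfig(50), list(polySH3(5, 5, 0), polyPRM(5, 5, 0)),
                    c(240, 240), seed = 2)
  expect_equal(nBeads(st), 2400L)
  expect_equal(unname(concentrations(st)["domainsPerSite"]), 2400 / 50^3)
  expect_true(all(is.na(st@partner)))
  expect_equal(nrow(validateState(st)), 0)

  ## pigeonhole: 10 beads on 8 sites
  expect_error(buildSystem(latticeConfig(2), list(polySH3(5, 1, 0)), 2L),
               "capacity")
})

test_that("buildSystem is reproducible under a seed", {
  a <- buildSystem(latticeConfig(12), list(polySH3(3, 4, 1), polyPRM(3, 4, 1)),
                   c(4, 4), seed = 7)
  b <- buildSystem(latticeConfig(12), list(polySH3(3, 4, 1), polyPRM(3, 4, 1)),
                   c(4, 4), seed = 7)
  expect_identical(a@coords, b@coords)
})

test_that("totalEnergy counts only bound adjacent complementary pairs", {
  st <- buildSystem(latticeConfig(8), tinySpecies(), c(2L, 2L), seed = 3)
  co <- st@coords
  ## force two adjacent S-P pairs and bind them
  co[1, ] <- c(0L, 0L, 0L); co[3, ] <- c(1L, 0L, 0L)
  co[2, ] <- c(4L, 4L, 4L); co[4, ] <- c(4L, 5L, 4L)
  st@coords <- co
  st@partner <- c(3L, 4L, 1L, 2L)
  st@energy <- totalEnergy(st)
  expect_equal(st@energy, -4)

  ## adjacency without the bound flag contributes nothing
  st@partner <- rep(NA_integer_, 4)
  expect_equal(totalEnergy(st), 0)

  ## bound but not adjacent is an integrity error
  st@partner <- c(2L, 1L, NA, NA)
  expect_error(totalEnergy(st), "integrity")
})

test_that("totalEnergy equals the O(B^2) double-loop oracle", {
  for (seed in 1:5) {
    st <- randomBondedMonomers(12, 12, L = 7, seed = seed)
    expect_equal(totalEnergy(st), energyOracle(st))
  }
})

test_that("validateState reports each class of violation", {
  st <- buildSystem(latticeConfig(6), tinySpecies(), c(2L, 2L), seed = 4)
  expect_equal(nrow(validateState(st)), 0)

  bad <- st
  co <- bad@coords; co[2, ] <- co[1, ]; bad@coords <- co
  expect_true("double-occupancy" %in% validateState(bad)$check)

  drift <- st
  drift@energy <- drift@energy + 1
  expect_true("energy-drift" %in% validateState(drift)$check)

  tether <- buildSystem(latticeConfig(9), list(polySH3(2, 2, 0)), 1L, seed = 5)
  co <- tether@coords
  co[2, ] <- (co[1, ] + c(4L, 0L, 0L)) %% 9L   # beyond the n = 2 well
  tether@coords <- co
  expect_true("tether-break" %in% validateState(tether)$check)
})

test_that("tether contract holds along trajectories for all linker types", {
  for (e in c(0L, 2L, 5L)) {
    st <- buildSystem(latticeConfig(12),
                      list(polySH3(3, 5, e), polyPRM(3, 5, e)), c(3, 3),
                      seed = 10 + e)
    run <- runMC(st, 2e4, sampleStride = 0, seed = 20 + e)
    expect_equal(nrow(validateState(run$state)), 0)
  }
})

test_that("snapshot files round-trip states and support analysis", {
  st <- generateFixture("bound-chain")
  f <- tempfile(fileext = ".tsv")
  writeSnapshot(st, f, step = 123)
  sn <- readSnapshot(f)
  expect_equal(sn$L, 12L)
  expect_equal(sn$step, 123)
  expect_equal(nrow(sn$beads), nBeads(st))
  expect_equal(sn$beads$partner, st@partner)
  res <- analyzeSnapshots(f)
  expect_equal(res$phiC, 0.3)
  unlink(f)
})
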