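test_that("largest-cluster fraction matches known constructions", {
  ## 10 molecules with a bound chain of 3: phi_c = 0.3
  st <- generateFixture("bound-chain")
  cl <- largestClusterFraction(st)
  expect_equal(cl$phiC, 0.3)
  expect_equal(cl$NN, 3)

  ## no bonds anywhere: every molecule its own cluster
  st@partner <- rep(NA_integer_, nBeads(st))
  st@energy <- 0
  expect_equal(largestClusterFraction(st)$phiC, 1 / nMolecules(st))
})

test_that("cluster sizes agree with a BFS oracle on random states", {
  for (seed in 1:20) {
    st <- randomBondedMonomers(15, 15, L = 8, pBond = 0.7, seed = seed)
    cl <- largestClusterFraction(st)
    sizes <- bfsClusterOracle(st@beadMol, st@partner, nMolecules(st))
    expect_equal(cl$NN, max(sizes))
    expect_equal(cl$phiC, max(sizes) / nMolecules(st))
  }
})

test_that("intramolecular bonds never create network edges", {
  ## a single heterotypic chain bound to itself is still one node
  st <- buildSystem(latticeConfig(5),
                    list(moleculeTopology("SP", 2, linkerN = 1, linkerE = 0,
                                          domainKind = c("S", "P"))), 1L,
                    seed = 2)
  co <- st@coords
  co[1, ] <- c(0L, 0L, 0L); co[2, ] <- c(1L, 0L, 0L)
  st@coords <- co
  st@partner <- c(2L, 1L)
  st@energy <- totalEnergy(st)
  expect_equal(igraph::ecount(bindingNetwork(st)), 0)
  expect_equal(largestClusterFraction(st)$phiC, 1)
})

test_that("rho calibrates to 1 for uniform dispersion", {
  st <- generateFixture("uniform-gas", seed = 3)
  expect_lt(abs(densityParameter(st) - 1), 0.06)
})

test_that("rho matches the closed form for a uniformly filled ball", {
  ## beads uniformly filling a centered ball of radius r:
  ## Rg -> sqrt(3/5) r, so rho -> R_lattice / (sqrt(3/5) r)
  set.seed(4)
  L <- 60; r <- 6
  pts <- matrix(runif(9000, -r, r), ncol = 3)
  pts <- pts[rowSums(pts^2) <= r^2, , drop = FALSE] + L / 2
  rho <- latticeRadius(L) / rgPeriodic(pts, L)
  expect_lt(abs(rho / (latticeRadius(L) / (sqrt(3 / 5) * r)) - 1), 0.02)
  expect_gt(rho, 3)   # condensed configurations give rho >> 1
})

test_that("the periodic center of mass handles boundary-spanning droplets", {
  set.seed(5)
  L <- 40; r <- 5
  pts <- matrix(runif(6000, -r, r), ncol = 3)
  pts <- pts[rowSums(pts^2) <= r^2, , drop = FALSE]
  centered <- sweep(pts, 2, c(L / 2, L / 2, L / 2), "+")
  spanning <- centered %% L          # same ball moved onto the corner
  spanning[, 1] <- (pts[, 1]) %% L   # x wraps through 0
  expect_equal(rgPeriodic(spanning, L), rgPeriodic(centered, L),
               tolerance = 0.05)
})

test_that("single-bead systems have undefined rho", {
  st <- buildSystem(latticeConfig(4),
                    list(moleculeTopology("S1", 1, domainKind = "S")), 1L)
  expect_error(densityParameter(st), "undefined")
})

test_that("droplet radius is recovered from dense-ball constructions", {
  fx <- generateFixture("dense-ball", seed = 2)
  rn <- dropletRadius(fx$NT, fx$NN, fx$L, fx$Rg)
  expect_lt(abs(rn - fx$rTrue) / fx$rTrue, 0.05)

  ## the returned root satisfies the quintic after rescaling
  coef <- c((fx$NT - fx$NN) * fx$L^5 / 4 - fx$NT * fx$Rg^2 * fx$L^3, 0,
            3 / 5 * fx$NN * fx$L^3, 4 / 3 * pi * fx$NT * fx$Rg^2, 0,
            -4 / 5 * pi * fx$NT)
  expect_lt(abs(sum(coef * rn^(0:5))) / (abs(coef[6]) * (1 + rn)^5), 1e-8)
})

test_that("single-phase limit: NN = NT with a uniform ball recovers r0", {
  set.seed(6)
  L <- 100; r0 <- 10; NT <- 2000
  pts <- matrix(runif(3 * NT * 3, -r0, r0), ncol = 3)
  pts <- pts[rowSums(pts^2) <= r0^2, , drop = FALSE][seq_len(NT), ] + L / 2
  rg <- rgPeriodic(pts, L)
  rn <- dropletRadius(NT, NT, L, rg)
  expect_lt(abs(rn - r0) / r0, 0.01)
})

test_that("phase boundaries conserve molecules exactly", {
  ## worked numbers: NT=1000, NN=900, L=100, rN=10
  cb <- phaseBoundaries(1000, 900, 100, 10)
  expect_equal(unname(cb["csh"]), 2700 / (4 * pi * 1e3), tolerance = 1e-12)
  expect_equal(unname(cb["csl"]), 100 / (1e6 - 4 / 3 * pi * 1e3),
               tolerance = 1e-12)
  vd <- 4 / 3 * pi * 10^3
  expect_equal(cb[["csh"]] * vd + cb[["csl"]] * (1e6 - vd), 1000)

  ## one-phase limit
  cb0 <- phaseBoundaries(1000, 0, 100, 10)
  expect_true(is.na(cb0["csh"]))
  expect_equal(unname(cb0["csl"]), 1000 / 1e6)
  expect_error(phaseBoundaries(10, 5, 10, 10), "exceeds")
})

test_that("dense-ball pipeline recovers the construction densities", {
  fx <- generateFixture("dense-ball", seed = 7)
  rn <- dropletRadius(fx$NT, fx$NN, fx$L, fx$Rg)
  cb <- phaseBoundaries(fx$NT, fx$NN, fx$L, rn)
  cshTrue <- fx$NN / (4 / 3 * pi * fx$rTrue^3)
  cslTrue <- (fx$NT - fx$NN) / (fx$L^3 - 4 / 3 * pi * fx$rTrue^3)
  expect_lt(abs(cb["csh"] - cshTrue) / cshTrue, 0.2)
  expect_lt(abs(cb["csl"] - cslTrue) / cslTrue, 0.05)
})

test_that("regime classification applies the paper thresholds", {
  expect_equal(classifyRegime(0.5, 1.0)$regime, "gel, one-phase")
  expect_equal(classifyRegime(0.5, 2.0)$regime, "gel, two-phase")
  expect_equal(classifyRegime(0.05, 1.0)$regime, "sol, one-phase")
  ## thresholds are configuration values, echoed in the output
  out <- classifyRegime(0.2, 1.0, phiCC = 0.25)
  expect_false(out$gel)
  expect_equal(out$phiCC, 0.25)
})
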