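test_that("binding equilibrium takes the physical quadratic root", {
  ## infinite-affinity limit
  eq <- solveBinding(1e-3, 1e-3, 1e-12)
  expect_equal(eq$xa, 1, tolerance = 1e-4)
  ## weak-binding limit: [ab] -> [a][b]/Kd
  eq2 <- solveBinding(1e-3, 2e-3, 10)
  expect_equal(eq2$ab, 1e-3 * 2e-3 / 10, tolerance = 1e-3)
  ## mass-action residual over random triples
  set.seed(1)
  for (k in 1:1000) {
    a <- 10^runif(1, -6, 0); b <- 10^runif(1, -6, 0)
    Kd <- 10^runif(1, -6, 1)
    eq <- solveBinding(a, b, Kd)
    expect_true(eq$ab >= 0 && eq$ab <= min(a, b) + 1e-15)
    expect_lt(abs((a - eq$ab) * (b - eq$ab) / eq$ab - Kd) / Kd, 1e-10)
  }
  expect_error(solveBinding(-1, 1, 1), "non-negative")
})

test_that("branching parameter epsilon marks the percolation criterion", {
  expect_equal(fsEpsilon(5, 5, 0.25, 0.25), 1)
  expect_equal(fsEpsilon(3, 3, 0.5, 0.5), 1)
  expect_equal(fsEpsilon(1, 7, 0.9, 0.9), 0)  # monovalent never gels
})

test_that("gel points solve epsilon = 1 and match a root-finding oracle", {
  ## closed form at lambda = 16
  expect_equal(fsGelPoint(5, 5, 1), 4 / 9)
  ## epsilon at the returned gel point is 1 to 1e-8 (equal mode)
  for (Kd in c(1e-3, 0.02, 0.5)) {
    for (V in c(3, 5, 7)) {
      ac <- fsGelPoint(V, V, Kd)
      eq <- solveBinding(ac, ac, Kd)
      expect_lt(abs(fsEpsilon(V, V, eq$xa, eq$xb) - 1), 1e-8)
      ## independent numeric oracle: uniroot on epsilon([a]) = 1
      f <- function(a) {
        e <- solveBinding(a, a, Kd)
        fsEpsilon(V, V, e$xa, e$xb) - 1
      }
      oracle <- uniroot(f, c(1e-12, 1e3), tol = 1e-14)$root
      expect_equal(ac, oracle, tolerance = 1e-8)
    }
  }
  ## fixed-[b] mode agrees with equal mode at [b] = [a]_c, and with its
  ## own oracle elsewhere
  ac <- fsGelPoint(5, 5, 0.01)
  expect_equal(fsGelPoint(5, 5, 0.01, b = ac), ac, tolerance = 1e-8)
  b0 <- 0.05
  am <- fsGelPoint(5, 5, 0.01, b = b0)
  eqm <- solveBinding(am, b0, 0.01)
  expect_lt(abs(fsEpsilon(5, 5, eqm$xa, eqm$xb) - 1), 1e-8)
  ## gelation impossible below lambda = 1
  expect_warning(out <- fsGelPoint(2, 1, 0.01), "no gel point")
  expect_true(is.na(out))
  ## infinite-valence limit
  expect_lt(fsGelPoint(100, 100, 0.01), fsGelPoint(5, 5, 0.01))
})

test_that("random bipartite networks behave at the bound-fraction extremes", {
  ## x = 0: no edges, phi_c = 1/molecules
  p0 <- randomNetworkPhiC(5, 5, 2400, x = 0, replicates = 3, seed = 1)
  expect_equal(as.numeric(p0), 1 / 480)
  ## x = 1: near-regular random bipartite graph is essentially connected
  p1 <- randomNetworkPhiC(5, 5, 2400, x = 1, replicates = 5, seed = 2)
  expect_gt(as.numeric(p1), 0.95)
  expect_error(randomNetworkPhiC(5, 5, 4, x = 0.5), "stoichiometry")
})

test_that("phi_c(x) grows monotonically through the critical region", {
  set.seed(3)
  xg <- c(0.1, 0.2, 0.25, 0.3, 0.45)
  ph <- vapply(xg, function(x)
    as.numeric(randomNetworkPhiC(5, 5, 2400, x, replicates = 30)), numeric(1))
  expect_true(all(diff(ph) > -0.02))
  ## subcritical stays O(1/M); supercritical grows toward O(1)
  expect_lt(ph[1], 0.05)
  expect_gt(ph[5], 0.5)
})

test_that("phi_cc estimates are stable in system size and valence", {
  set.seed(4)
  a <- estimatePhiCc(5, nDomains = 2400, replicates = 120)
  b <- estimatePhiCc(5, nDomains = 4800, replicates = 120)
  expect_lt(abs(a$mean - b$mean), 0.04)
  ## grid interpolation agrees with direct evaluation at x_c
  set.seed(5)
  g <- estimatePhiCc(5, nDomains = 2400, replicates = 100,
                     xGrid = c(0.15, 0.25, 0.35))
  set.seed(5)
  d <- estimatePhiCc(5, nDomains = 2400, replicates = 100)
  expect_lt(abs(g$mean - d$mean), 0.05)
  expect_error(estimatePhiCc(5, xGrid = c(0.4, 0.6)), "bracket")
})

test_that("gel point extraction finds the lowest crossing", {
  expect_equal(gelPointFromSweep(c(1, 2, 3, 4) * 1e-3,
                                 c(0.01, 0.05, 0.30, 0.80)), 3e-3)
  expect_true(is.na(gelPointFromSweep(c(1, 2, 3), c(0.01, 0.05, 0.1))))
  ## synthetic sigmoid with known midpoint: crossing within one grid step
  conc <- seq(1e-3, 1e-2, length.out = 50)
  phi <- 1 / (1 + exp(-(conc - 5e-3) / 3e-4))
  cg <- gelPointFromSweep(conc, phi, phiCC = 0.5)
  expect_lt(abs(cg - 5e-3), diff(conc)[1] * 1.5)
  expect_error(gelPointFromSweep(c(2, 1), c(0.1, 0.2)), "sorted")
})

test_that("cooperativity ratio c* is labeled per the global-cooperativity rule", {
  expect_equal(cStar(0.01, 0.01)$cStar, 1)
  expect_equal(cStar(0.01, 0.01)$cooperativity, "zero")
  expect_equal(cStar(0.005, 0.01)$cooperativity, "positive")
  expect_equal(cStar(0.05, 0.01)$cooperativity, "negative")
  expect_true(is.na(cStar(NA_real_, 0.01)$cStar))
})
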