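## percolation_theory: Flory-Stockmayer analytics, the random bipartite
## network calibration of phi_cc, gel-point extraction and the
## cooperativity ratio c*.

#' Two-component binding equilibrium
#'
#' Solves `Kd = ([a]-[ab])([b]-[ab]) / [ab]` for the complex
#' concentration, taking the physical root of the quadratic (the one
#' with `[ab] <= min([a],[b])`):
#' `[ab] = (([a]+[b]+Kd) - sqrt(([a]+[b]+Kd)^2 - 4[a][b])) / 2`.
#'
#' @param a,b total domain concentrations (domains per site).
#' @param Kd dissociation constant (same units, > 0).
#' @return list: `a`, `b`, `Kd`, `ab`, and bound fractions `xa = ab/a`,
#'   `xb = ab/b`.
#' @export
solveBinding <- function(a, b, Kd) {
  if (any(a < 0) || any(b < 0)) stop("concentrations must be non-negative")
  if (any(Kd <= 0)) stop("Kd must be positive")
  s <- a + b + Kd
  ## numerically stable form of the smaller quadratic root (avoids
  ## cancellation when Kd >> [a][b])
  ab <- 2 * a * b / (s + sqrt(s^2 - 4 * a * b))
  list(a = a, b = b, Kd = Kd, ab = ab,
       xa = ifelse(a > 0, ab / a, 0), xb = ifelse(b > 0, ab / b, 0))
}

#' Flory-Stockmayer branching parameter
#'
#' `epsilon = (Va - 1) xa (Vb - 1) xb`: the mean number of additional
#' proteins a newly recruited protein brings into a pre-formed network.
#' `epsilon >= 1` cascades into a system-spanning cluster (gelation).
#'
#' @param Va,Vb valences of the two species.
#' @param xa,xb bound fractions.
#' @return epsilon (dimensionless).
#' @examples
#' fsEpsilon(5, 5, 0.25, 0.25)  # exactly 1: the 5:5 percolation point
#' @export
fsEpsilon <- function(Va, Vb, xa, xb) {
  (Va - 1) * xa * (Vb - 1) * xb
}

#' Flory-Stockmayer gel point
#'
#' The concentration of species-a domains at which `epsilon = 1`. In
#' equal-concentration mode (`b = NULL`), mass action gives the closed
#' form `[a]_c = Kd * sqrt(lambda) / (sqrt(lambda) - 1)^2` with
#' `lambda = (Va-1)(Vb-1)` and critical bound fraction
#' `x_c = 1/sqrt(lambda)`. With `[b]` fixed, `[a]_c` solves the
#' quadratic obtained from `[ab] = sqrt([a][b]/lambda)` inserted into
#' the mass-action law:
#' `[a]^2 + [a] (2(b+Kd) - b (lambda+1)^2 / lambda) + (b+Kd)^2 = 0`,
#' keeping the root at which the physical binding solution indeed gives
#' `epsilon = 1`.
#'
#' @param Va,Vb valences (`lambda > 1` required for a gel point).
#' @param Kd dissociation constant (domains per site).
#' @param b fixed concentration of species-b domains, or `NULL` for the
#'   equal-concentration mode.
#' @return `[a]_c` in domains per site, or `NA` (with a warning) when
#'   `lambda <= 1` so gelation is impossible. Note this is the
#'   *per-species* domain concentration: in the stoichiometric case the
#'   total domain concentration at the gel point is `2 [a]_c`.
#' @export
fsGelPoint <- function(Va, Vb, Kd, b = NULL) {
  lam <- (Va - 1) * (Vb - 1)
  if (lam <= 1) { warning("no gel point: (Va-1)(Vb-1) <= 1"); return(NA_real_) }
  if (is.null(b)) return(Kd * sqrt(lam) / (sqrt(lam) - 1)^2)
  B <- 2 * (b + Kd) - b * (lam + 1)^2 / lam
  C <- (b + Kd)^2
  disc <- B^2 - 4 * C
  if (disc < 0) { warning("no gel point at this [b]"); return(NA_real_) }
  roots <- (-B + c(-1, 1) * sqrt(disc)) / 2
  roots <- roots[roots > 0]
  if (!length(roots)) { warning("no positive gel point"); return(NA_real_) }
  eps <- vapply(roots, function(a) {
    eq <- solveBinding(a, b, Kd)
    fsEpsilon(Va, Vb, eq$xa, eq$xb)
  }, numeric(1))
  ok <- abs(eps - 1) < 1e-6
  if (!any(ok)) { warning("no root satisfies epsilon = 1"); return(NA_real_) }
  min(roots[ok])
}

#' Largest-cluster fraction of a random bipartite binding network
#'
#' The paper-style random network: `nDomains` interaction domains are
#' split stoichiometrically into A and B sides and grouped into
#' molecules of valence `Va`/`Vb` (consecutive blocks). Each A domain
#' binds, with probability `x`, a uniformly chosen B domain that does
#' not already have a partner. Clusters are computed on the molecule
#' graph and the mean largest-cluster molecule fraction over replicates
#' is returned.
#'
#' @param Va,Vb valences.
#' @param nDomains total interaction domains (default 2400, the
#'   simulation count); each side gets `round(nDomains/2/V)` whole
#'   molecules.
#' @param x bound fraction in `[0, 1]`.
#' @param replicates number of independent networks.
#' @param seed optional seed.
#' @return mean phi_c; attribute `"se"` carries the standard error.
#' @export
randomNetworkPhiC <- function(Va, Vb, nDomains = 2400, x, replicates = 50,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(x >= 0, x <= 1)
  mA <- round(nDomains / 2 / Va); mB <- round(nDomains / 2 / Vb)
  if (mA < 1 || mB < 1) stop("infeasible stoichiometry")
  nA <- mA * Va; nB <- mB * Vb
  nm <- mA + mB
  phis <- vapply(seq_len(replicates), function(r) {
    wants <- which(stats::runif(nA) < x)
    k <- min(length(wants), nB)
    if (k == 0) return(1 / nm)
    partners <- sample.int(nB, k)
    molA <- (wants[seq_len(k)] - 1L) %/% Va + 1L
    molB <- mA + (partners - 1L) %/% Vb + 1L
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = molA, to = molB), directed = FALSE,
      vertices = data.frame(name = seq_len(nm)))
    max(igraph::components(g)$csize) / nm
  }, numeric(1))
  out <- mean(phis)
  attr(out, "se") <- stats::sd(phis) / sqrt(replicates)
  out
}

#' Calibrate the critical largest-cluster fraction phi_cc
#'
#' Reads the random-network sigmoid `phi_c(x)` at the Flory-Stockmayer
#' critical bound fraction `x_c = 1/sqrt((Va-1)(Vb-1))` (the symmetric
#' case gives `1/(V-1)`) for each requested valence. With an explicit
#' `xGrid` the sigmoid is evaluated on the grid and interpolated at
#' `x_c`; otherwise it is evaluated at `x_c` directly. The resulting
#' `phi_cc ~ 0.17` is valence-independent and is the default gel
#' threshold downstream.
#'
#' @param valences symmetric valences to test.
#' @param nDomains,replicates,seed as in [randomNetworkPhiC()].
#' @param xGrid optional grid of bound fractions bracketing `x_c`.
#' @return list: `perValence` (named numeric), `mean`.
#' @export
estimatePhiCc <- function(valences = c(3, 5, 7), nDomains = 2400,
                          replicates = 50, xGrid = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pv <- vapply(valences, function(V) {
    xc <- 1 / (V - 1)
    if (is.null(xGrid)) {
      as.numeric(randomNetworkPhiC(V, V, nDomains, xc,
                                   replicates = replicates))
    } else {
      if (min(xGrid) > xc || max(xGrid) < xc)
        stop("xGrid does not bracket the critical bound fraction ", xc)
      ph <- vapply(xGrid, function(x)
        as.numeric(randomNetworkPhiC(V, V, nDomains, x,
                                     replicates = replicates)), numeric(1))
      stats::approx(xGrid, ph, xout = xc)$y
    }
  }, numeric(1))
  names(pv) <- paste0("V", valences)
  list(perValence = pv, mean = mean(pv))
}

#' Gel point from a concentration sweep
#'
#' The gel point `c_g` is the lowest concentration at which
#' `phi_c > phiCC`.
#'
#' @param conc concentrations, sorted increasing.
#' @param phiC corresponding largest-cluster fractions (replicate
#'   averages).
#' @param phiCC percolation threshold (default 0.17).
#' @return `c_g`, or `NA` if the sweep never crosses the threshold.
#' @examples
#' gelPointFromSweep(c(1, 2, 3, 4) * 1e-3, c(0.01, 0.05, 0.30, 0.80))
#' @export
gelPointFromSweep <- function(conc, phiC, phiCC = 0.17) {
  stopifnot(length(conc) == length(phiC))
  if (is.unsorted(conc)) stop("sweep must be sorted by concentration")
  idx <- which(phiC > phiCC)
  if (!length(idx)) return(NA_real_)
  conc[min(idx)]
}

#' Cooperativity ratio c*
#'
#' `c* = c_g,sim / c_g,FS`: the simulated gel point over the
#' Flory-Stockmayer prediction. `c* < 1` indicates positive global
#' cooperativity (gelation aided by phase separation), `c* = 1` zero,
#' `c* > 1` negative global cooperativity.
#'
#' @param cgSim simulated gel point.
#' @param cgFS Flory-Stockmayer gel point (same units).
#' @return list: `cStar`, `cgSim`, `cgFS`, `cooperativity` label.
#' @export
cStar <- function(cgSim, cgFS) {
  if (is.na(cgSim) || is.na(cgFS)) {
    return(list(cStar = NA_real_, cgSim = cgSim, cgFS = cgFS,
                cooperativity = NA_character_))
  }
  stopifnot(cgSim > 0, cgFS > 0)
  cs <- cgSim / cgFS
  label <- if (cs < 1) "positive" else if (cs > 1) "negative" else "zero"
  list(cStar = cs, cgSim = cgSim, cgFS = cgFS, cooperativity = label)
}
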