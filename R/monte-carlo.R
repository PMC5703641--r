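## monte_carlo: five-move Metropolis-Hastings kernel (C++ backed) plus an
## exhaustive-enumeration oracle for tiny systems.

.MOVE_TYPES <- c("binding_flip", "end_pivot", "crankshaft",
                 "cluster_translate", "reptation")

#' Modified Metropolis acceptance
#'
#' Accepts with probability `min(1, w * exp(-dE))`, with `dE` in kB*T and
#' `w` the Hastings weight of the proposal. Consumes exactly one uniform
#' variate when the probability is below one.
#'
#' @param dE energy change (kB*T).
#' @param w Hastings weight (> 0).
#' @return logical.
#' @examples
#' set.seed(1); mean(replicate(1e4, acceptMove(2, 1)))  # ~ exp(-2)
#' @export
acceptMove <- function(dE, w = 1) {
  if (!is.finite(dE)) stop("dE must be finite")
  if (!is.finite(w) || w <= 0) stop("w must be positive")
  p <- w * exp(-dE)
  if (p >= 1) TRUE else (stats::runif(1) < p)
}

#' Propose a single Monte Carlo move
#'
#' Draws one proposal of the requested type from the current state
#' without applying it. An immediate rejection (steric overlap, or no
#' admissible placement) is returned with `feasible = FALSE`.
#'
#' @param state a `SystemState`.
#' @param moveType one of `"binding_flip"`, `"end_pivot"`,
#'   `"crankshaft"`, `"cluster_translate"`, `"reptation"`.
#' @return a [MoveProposal-class].
#' @export
proposeMove <- function(state, moveType) {
  ti <- match(match.arg(moveType, .MOVE_TYPES), .MOVE_TYPES) - 1L
  cs <- .stateToC(state)
  if (ti == 1L && !any(cs$molEnd - cs$molStart >= 2L))
    stop("end_pivot requires a molecule with at least two beads")
  if (ti == 2L && !any(cs$molEnd - cs$molStart >= 3L))
    stop("crankshaft requires a molecule with at least three beads")
  if (ti == 4L && !any(cs$molLinkN >= 1L))
    stop("reptation requires valence >= 2 with a homogeneous linker")
  pr <- cpp_propose(cs, ti)
  toIdx <- function(i) if (i < 0L) NA_integer_ else i + 1L
  new("MoveProposal",
      moveType = .MOVE_TYPES[pr$type + 1L],
      feasible = pr$feasible, dE = pr$dE, w = pr$w,
      counts = c(Nc = pr$Nc, Np = pr$Np, Vc = pr$Vc, Vp = pr$Vp),
      bead = toIdx(pr$bead),
      oldPartner = toIdx(pr$oldPartner), newPartner = toIdx(pr$newPartner),
      oldPos = pr$oldPos, newPos = pr$newPos,
      details = list(clusterBeads = pr$clusterBeads + 1L,
                     delta = pr$delta, mol = toIdx(pr$mol),
                     fromHead = pr$fromHead, segLen = pr$segLen,
                     segPos = pr$segPos))
}

#' @export
setMethod("show", "MoveProposal", function(object) {
  cat("MoveProposal:", object@moveType,
      if (object@feasible) "" else "(immediate rejection)", "\n")
  if (object@feasible)
    cat(sprintf("  dE = %.4g kB*T, w = %.4g (Nc=%d Np=%d Vc=%g Vp=%g)\n",
                object@dE, object@w, object@counts["Nc"], object@counts["Np"],
                object@counts["Vc"], object@counts["Vp"]))
})

#' Apply a proposal to a state
#'
#' Deterministically applies an already-drawn feasible proposal,
#' returning the updated state. Used for auditing reversibility; the
#' production path applies moves inside [runMC()].
#'
#' @param state a `SystemState`.
#' @param proposal a [MoveProposal-class] from [proposeMove()].
#' @return the updated `SystemState`.
#' @export
applyProposal <- function(state, proposal) {
  if (!proposal@feasible) return(state)
  p <- state@partner
  co <- state@coords
  setBond <- function(bead, oldP, newP) {
    if (!is.na(oldP)) { p[oldP] <<- NA_integer_; p[bead] <<- NA_integer_ }
    if (!is.na(newP)) { p[bead] <<- newP; p[newP] <<- bead }
    else p[bead] <<- NA_integer_
  }
  switch(proposal@moveType,
    binding_flip = setBond(proposal@bead, proposal@oldPartner,
                           proposal@newPartner),
    end_pivot = ,
    crankshaft = {
      co[proposal@bead, ] <- proposal@newPos
      if (state@beadKind[proposal@bead] != 3L)
        setBond(proposal@bead, proposal@oldPartner, proposal@newPartner)
    },
    cluster_translate = {
      idx <- proposal@details$clusterBeads
      co[idx, ] <- sweep(co[idx, , drop = FALSE], 2,
                         -proposal@details$delta) %% state@config@L
    },
    reptation = {
      m <- proposal@details$mol
      idx <- which(state@beadMol == m)
      st <- min(idx); en <- max(idx)
      seg <- proposal@details$segLen
      fromHead <- proposal@details$fromHead
      dOld <- if (fromHead) st else en
      setBond(dOld, proposal@oldPartner, NA_integer_)
      block <- if (fromHead) (st + seg):en else st:(en - seg)
      shift <- if (fromHead) -seg else seg
      bco <- co[block, , drop = FALSE]; bp <- p[block]
      inBlock <- !is.na(bp) & bp >= min(block) & bp <= max(block)
      newIdx <- block + shift
      co[newIdx, ] <- bco
      p[newIdx] <- ifelse(inBlock, bp + shift, bp)
      ext <- which(!inBlock & !is.na(bp))
      p[bp[ext]] <- newIdx[ext]
      segPos <- proposal@details$segPos       # enumeration order, domain last
      if (fromHead) {
        memIdx <- (en - seg + 1L):en
        enuIdx <- seq_len(seg)
      } else {
        memIdx <- st:(st + seg - 1L)
        enuIdx <- c(seg, rev(seq_len(seg - 1L)))
      }
      co[memIdx, ] <- segPos[enuIdx, , drop = FALSE]
      p[memIdx] <- NA_integer_
      dNew <- if (fromHead) en else st
      if (!is.na(proposal@newPartner)) {
        p[dNew] <- proposal@newPartner
        p[proposal@newPartner] <- dNew
      }
    })
  state@partner <- p
  state@coords <- co
  state@energy <- state@energy + proposal@dE
  state
}

#' Run the Metropolis-Hastings chain
#'
#' Evolves the system for `nSteps` elementary move attempts (one attempt
#' per step) under the modified Metropolis criterion
#' `min(1, w * exp(-dE))`. Observables (energy, largest-cluster fraction
#' phi_c, density ratio rho, molecules in the largest network) are
#' recorded every `sampleStride` attempts. Runs are bit-reproducible
#' under (`seed`, `schedule`).
#'
#' @param state a `SystemState`.
#' @param nSteps number of attempted moves.
#' @param schedule named numeric weights over the five move types;
#'   default uniform over the types applicable to the topology. The
#'   schedule affects mixing, not the stationary distribution.
#' @param sampleStride record observables every this many attempts
#'   (0 = no sampling).
#' @param keepFrames if `TRUE`, also keep coordinate/binding frames at
#'   each sample (tiny systems only).
#' @param seed optional integer seed.
#' @return list with `state` (final), `samples` (data.frame: step,
#'   energy, phiC, NN, Rg, rho), `acceptance` (attempts/accepted per move
#'   type) and optionally `frames`.
#' @export
runMC <- function(state, nSteps, schedule = NULL,
                  sampleStride = max(1, floor(nSteps / 1000)),
                  keepFrames = FALSE, seed = NULL) {
  stopifnot(nSteps >= 0)
  if (!is.null(seed)) set.seed(seed)
  w <- rep(1, 5); names(w) <- .MOVE_TYPES
  if (!is.null(schedule)) {
    if (is.null(names(schedule)) || !all(names(schedule) %in% .MOVE_TYPES))
      stop("schedule must be named with move types")
    w[] <- 0; w[names(schedule)] <- schedule
  }
  if (nSteps == 0)
    return(list(state = state,
                samples = data.frame(step = numeric(), energy = numeric(),
                                     phiC = numeric(), NN = integer(),
                                     Rg = numeric(), rho = numeric()),
                acceptance = data.frame(move = .MOVE_TYPES, attempts = 0,
                                        accepted = 0)))
  cs <- .stateToC(state)
  res <- cpp_run_mc(cs, as.double(nSteps), as.numeric(w),
                    as.integer(sampleStride), isTRUE(keepFrames))
  if (abs(res$energy - res$energyCheck) > 1e-9)
    stop("invariant violation: cached energy ", res$energy,
         " != recomputed ", res$energyCheck)
  out <- list(
    state = .updateStateFromC(state, res$coords, res$partner, res$energy),
    samples = res$samples,
    acceptance = data.frame(move = .MOVE_TYPES,
                            attempts = res$acceptance[, 1],
                            accepted = res$acceptance[, 2],
                            rate = ifelse(res$acceptance[, 1] > 0,
                                          res$acceptance[, 2] / res$acceptance[, 1],
                                          NA_real_)))
  if (keepFrames) out$frames <- res$frames
  out
}

#' Average observables over the equilibrated window
#'
#' Ensemble averages are taken over the final half of a trajectory (the
#' default analysis window). A split-half drift check on phi_c flags
#' non-equilibrated runs: the window is halved again and the two
#' sub-window means compared against twice the standard error of the
#' difference.
#'
#' @param samples the `samples` data.frame from [runMC()].
#' @param fraction final fraction of the trajectory to average
#'   (default 0.5).
#' @return one-row data.frame: phiC, rho, NN, Rg, energy, equilibrated.
#' @export
trajectoryMeans <- function(samples, fraction = 0.5) {
  n <- nrow(samples)
  if (n == 0) stop("no samples recorded")
  win <- samples[seq.int(max(1L, floor(n * (1 - fraction)) + 1L), n), ]
  m <- nrow(win)
  h1 <- win$phiC[seq_len(floor(m / 2))]
  h2 <- win$phiC[seq.int(floor(m / 2) + 1L, m)]
  se <- sqrt(stats::var(h1) / max(length(h1), 1) +
             stats::var(h2) / max(length(h2), 1))
  eq <- if (!is.finite(se) || se == 0) abs(mean(h1) - mean(h2)) < 1e-12
        else abs(mean(h1) - mean(h2)) <= 2 * se
  data.frame(phiC = mean(win$phiC), rho = mean(win$rho), NN = mean(win$NN),
             Rg = mean(win$Rg), energy = mean(win$energy),
             equilibrated = eq, nSamples = m)
}
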