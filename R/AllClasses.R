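#' @import methods
NULL

.KIND_LEVELS <- c("S", "P", "L")

#' Cubic-lattice configuration
#'
#' Defines the simulation world: a 3-dimensional cubic lattice of side
#' `L` with periodic boundary conditions. Contacts (and explicit-linker
#' chain connectivity) use face (6-neighbor) adjacency; implicit tethers
#' use the Chebyshev (max-norm) metric, i.e. a cubic square well.
#'
#' @slot L integer, box side length in lattice units (>= 2).
#' @slot periodic logical, always `TRUE`.
#' @slot connectivity character, neighbor definition for contacts
#'   (currently only `"face"`).
#' @export
setClass("LatticeConfig",
  representation(L = "integer", periodic = "logical", connectivity = "character"),
  prototype(periodic = TRUE, connectivity = "face"))

setValidity("LatticeConfig", function(object) {
  msg <- character()
  if (length(object@L) != 1L || is.na(object@L) || object@L < 2L)
    msg <- c(msg, "L must be a single integer >= 2")
  if (!isTRUE(object@periodic))
    msg <- c(msg, "only periodic boundaries are supported")
  if (!identical(object@connectivity, "face"))
    msg <- c(msg, "connectivity must be 'face'")
  if (length(msg)) msg else TRUE
})

#' Species definition for a linear multivalent protein
#'
#' A bead-tether polymer with `valence` interaction domains joined by
#' `valence - 1` disordered linkers. Each linker spans `linkerN[i]`
#' lattice sites of which `linkerE[i]` are modeled as explicit
#' excluded-volume beads (`0` = fully implicit Flory-random-coil linker,
#' `linkerN[i]` = fully explicit self-avoiding linker, anything between
#' is a hybrid). The explicit beads of a hybrid linker sit contiguously
#' adjacent to the upstream domain; the remaining span is one implicit
#' square-well segment.
#'
#' @slot species character label (e.g. `"polySH3"`).
#' @slot valence integer, number of interaction domains (>= 1).
#' @slot domainKinds character vector of length `valence`, each `"S"` or
#'   `"P"`.
#' @slot linkerN integer vector of linker lengths in lattice sites.
#' @slot linkerE integer vector of explicit bead counts per linker.
#' @export
setClass("MoleculeTopology",
  representation(species = "character", valence = "integer",
                 domainKinds = "character",
                 linkerN = "integer", linkerE = "integer"))

setValidity("MoleculeTopology", function(object) {
  msg <- character()
  V <- object@valence
  if (length(V) != 1L || is.na(V) || V < 1L)
    msg <- c(msg, "valence must be a single integer >= 1")
  if (length(object@domainKinds) != V ||
      !all(object@domainKinds %in% c("S", "P")))
    msg <- c(msg, "domainKinds must have length valence, values 'S'/'P'")
  if (length(object@linkerN) != V - 1L || length(object@linkerE) != V - 1L)
    msg <- c(msg, "need valence - 1 linkers")
  if (V > 1L) {
    if (any(is.na(object@linkerN)) || any(object@linkerN < 1L))
      msg <- c(msg, "linker lengths must be >= 1")
    if (any(is.na(object@linkerE)) || any(object@linkerE < 0L) ||
        any(object@linkerE > object@linkerN))
      msg <- c(msg, "explicit bead counts must satisfy 0 <= e <= n")
  }
  if (length(msg)) msg else TRUE
})

#' Contact-energy model
#'
#' Symmetric pairwise energies `u_XY` (in units of kB*T) among the three
#' bead kinds S (SH3 domain), P (proline-rich motif) and L (linker bead).
#' The S-P energy accrues only between face-adjacent domains whose bound
#' flag is set; mere adjacency contributes nothing. Defaults: all zero
#' except `u_SP = -2`.
#'
#' @slot energies 3x3 symmetric numeric matrix with dimnames S, P, L.
#' @export
setClass("InteractionModel", representation(energies = "matrix"))

setValidity("InteractionModel", function(object) {
  en <- object@energies
  msg <- character()
  if (!is.numeric(en) || !identical(dim(en), c(3L, 3L)) ||
      !identical(rownames(en), .KIND_LEVELS) ||
      !identical(colnames(en), .KIND_LEVELS))
    msg <- c(msg, "energies must be a 3x3 numeric matrix with dimnames S,P,L")
  else if (!isTRUE(all.equal(en, t(en))))
    msg <- c(msg, "energies must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Full microstate of a lattice simulation
#'
#' Holds every bead's lattice coordinates (0-based, in `[0, L)`), its
#' kind, its molecule, the symmetric binding map (1-based bead index of
#' the bound partner, `NA` if unbound) and the cached total energy.
#' Beads of a molecule occupy a contiguous index block in chain order:
#' domain, explicit linker beads, domain, ...
#'
#' @slot config a [LatticeConfig-class].
#' @slot interactions an [InteractionModel-class].
#' @slot species list of [MoleculeTopology-class] objects.
#' @slot moleculeSpecies integer, per-molecule index into `species`.
#' @slot coords integer matrix (beads x 3).
#' @slot beadKind integer codes into `c("S","P","L")`.
#' @slot beadMol integer, 1-based molecule id per bead.
#' @slot partner integer, 1-based bound partner per bead or `NA`.
#' @slot energy numeric, cached total energy in kB*T.
#' @export
setClass("SystemState",
  representation(config = "LatticeConfig", interactions = "InteractionModel",
                 species = "list", moleculeSpecies = "integer",
                 coords = "matrix", beadKind = "integer",
                 beadMol = "integer", partner = "integer",
                 energy = "numeric"))

setValidity("SystemState", function(object) {
  msg <- character()
  nb <- nrow(object@coords)
  L <- object@config@L
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
  if (length(object@beadKind) != nb || length(object@beadMol) != nb ||
      length(object@partner) != nb)
    msg <- c(msg, "per-bead slots must match nrow(coords)")
  if (nb > 0) {
    if (any(object@coords < 0L) || any(object@coords >= L))
      msg <- c(msg, "coordinates outside [0, L)")
    key <- object@coords[, 1] + L * (object@coords[, 2] + L * object@coords[, 3])
    if (anyDuplicated(key)) msg <- c(msg, "two beads occupy one site")
    p <- object@partner
    bi <- which(!is.na(p))
    if (length(bi) && any(p[p[bi]] != bi, na.rm = TRUE))
      msg <- c(msg, "binding map is not symmetric")
  }
  if (!all(object@moleculeSpecies >= 1L) ||
      !all(object@moleculeSpecies <= length(object@species)))
    msg <- c(msg, "moleculeSpecies out of range")
  if (length(msg)) msg else TRUE
})

#' One attempted Monte Carlo move
#'
#' Records everything needed to apply, audit or invert a proposal: the
#' move type, affected beads with old/new coordinates, old/new binding
#' assignments, the energy change and the Hastings weight `w` together
#' with the interacting-state counts `Nc`/`Np` and (for reptation) the
#' placement counts `Vc`/`Vp` it was built from.
#'
#' @export
setClass("MoveProposal",
  representation(moveType = "character", feasible = "logical",
                 dE = "numeric", w = "numeric", counts = "numeric",
                 bead = "integer", oldPartner = "integer",
                 newPartner = "integer", oldPos = "integer",
                 newPos = "integer", details = "list"))

#' Two-parameter phase diagram
#'
#' Per-(affinity, concentration) order parameters with the derived
#' coexistence boundaries, gel line and critical-point estimate.
#'
#' @slot grid data.frame of per-point results.
#' @slot boundaries data.frame with one row per affinity (c_sl, c_sh, c_g).
#' @slot critical named numeric (affinity, concentration), `NA` if no
#'   two-phase point was found on the grid.
#' @slot thresholds named numeric (phiCC, rhoCutoff).
#' @export
setClass("PhaseDiagram",
  representation(grid = "data.frame", boundaries = "data.frame",
                 critical = "numeric", thresholds = "numeric"))
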