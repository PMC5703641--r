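## Plain-text snapshot format: a commented header carrying the box side
## and step number, then one row per bead.

#' Write a snapshot
#'
#' One row per bead: molecule id, bead index, bead kind (S|P|L), x, y,
#' z, bound-partner global bead index or -1; preceded by a header with
#' `L` and the step number.
#'
#' @param state a `SystemState`.
#' @param file output path.
#' @param step step number recorded in the header.
#' @export
writeSnapshot <- function(state, file, step = 0) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# latticegel snapshot",
               paste0("# L=", state@config@L),
               paste0("# step=", format(step, scientific = FALSE))), con)
  tb <- beadTable(state)
  tb$partner[is.na(tb$partner)] <- -1L
  utils::write.table(tb, con, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}

#' Read a snapshot
#'
#' @param file path written by [writeSnapshot()].
#' @return list: `L`, `step`, `beads` (data.frame with `partner` as
#'   1-based index or `NA`).
#' @export
readSnapshot <- function(file) {
  hdr <- readLines(file, n = 3)
  L <- as.integer(sub("# L=", "", hdr[2], fixed = TRUE))
  step <- as.numeric(sub("# step=", "", hdr[3], fixed = TRUE))
  beads <- utils::read.table(file, header = TRUE, skip = 3, sep = "\t")
  beads$partner[beads$partner < 0] <- NA_integer_
  list(L = L, step = step, beads = beads)
}

#' Per-frame order parameters from snapshot files
#'
#' @param files character vector of snapshot paths.
#' @return data.frame: file, step, phiC, NN, rho.
#' @export
analyzeSnapshots <- function(files) {
  do.call(rbind, lapply(files, function(f) {
    sn <- readSnapshot(f)
    cl <- largestClusterFraction(sn$beads)
    data.frame(file = f, step = sn$step, phiC = cl$phiC, NN = cl$NN,
               rho = densityParameter(sn$beads, L = sn$L))
  }))
}

#' Read a YAML simulation configuration
#'
#' Flat structured text with species blocks (valence, linker_n,
#' linker_explicit, count), box `L`, energy `uSP`, `steps` and `seed`.
#'
#' @param file YAML path.
#' @return the parsed list.
#' @export
readSimConfig <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  yaml::read_yaml(file)
}

#' Build a system from a parsed configuration
#'
#' @param cfg list from [readSimConfig()].
#' @return a `SystemState`.
#' @export
buildSystemFromConfig <- function(cfg) {
  species <- lapply(cfg$species, function(sp)
    moleculeTopology(sp$name, sp$valence,
                     linkerN = sp$linker_n %||% 5L,
                     linkerE = sp$linker_explicit %||% 0L,
                     domainKind = sp$domain_kind %||% "S"))
  counts <- vapply(cfg$species, function(sp) as.integer(sp$count), integer(1))
  buildSystem(latticeConfig(cfg$L), species, counts,
              interactionModel(uSP = cfg$uSP %||% -2),
              seed = cfg$seed %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
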