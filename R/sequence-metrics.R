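## sequence_metrics: charge composition of disordered linkers, the Delta
## deviation from a Flory-random-coil distance profile, regime
## classification and the residue <-> lattice-site mapping.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Charge metrics of disordered linker sequences
#'
#' `FCR = f+ + f-` (fraction of charged residues) and
#' `NCPR = f+ - f-` (net charge per residue), where `f+` counts Arg and
#' Lys and `f-` counts Asp and Glu, each normalized by sequence length.
#' Histidine is treated as neutral.
#'
#' @param x character vector of amino-acid sequences (optionally named),
#'   or a `Biostrings::AAStringSet`.
#' @param onUnknown what to do with letters outside the 20-residue
#'   alphabet: `"error"` (default) or `"skip"` (drop them from both the
#'   counts and the length, with a warning).
#' @return data.frame: name, length, fPlus, fMinus, FCR, NCPR.
#' @examples
#' chargeMetrics("EDEDSEKEEEEEDKEMEELQEEKECEKPQGDEEEEEEEEE")  # 0.80, -0.60
#' @export
chargeMetrics <- function(x, onUnknown = c("error", "skip")) {
  onUnknown <- match.arg(onUnknown)
  if (methods::is(x, "AAStringSet")) x <- as.character(x)
  nm <- names(x)
  if (is.null(nm)) nm <- paste0("seq", seq_along(x))
  rows <- lapply(seq_along(x), function(i) {
    aa <- strsplit(toupper(x[[i]]), "")[[1]]
    bad <- !(aa %in% .AA20)
    if (any(bad)) {
      if (onUnknown == "error")
        stop("unknown residue letter(s) in ", nm[i], ": ",
             paste(unique(aa[bad]), collapse = ", "))
      warning("skipping ", sum(bad), " unknown residue(s) in ", nm[i])
      aa <- aa[!bad]
    }
    n <- length(aa)
    fp <- sum(aa %in% c("R", "K")) / n
    fm <- sum(aa %in% c("D", "E")) / n
    data.frame(name = nm[i], length = n, fPlus = fp, fMinus = fm,
               FCR = fp + fm, NCPR = fp - fm)
  })
  do.call(rbind, rows)
}

#' Read sequences from a FASTA file
#'
#' @param file FASTA path.
#' @return named character vector of sequences.
#' @export
readLinkerSequences <- function(file) {
  as.character(Biostrings::readAAStringSet(file))
}

#' Inter-residue distance profile
#'
#' Ordered pairs (k, <R_k>): the mean spatial separation between residue
#' pairs `k` apart in sequence, for a chain of `N` residues.
#'
#' @param k sequence separations (subset of `1..N-1`, increasing).
#' @param r mean spatial separations (> 0).
#' @param N chain length in residues (default `max(k) + 1`).
#' @return data.frame of class `"DistanceProfile"` with attribute `N`.
#' @export
distanceProfile <- function(k, r, N = max(k) + 1L) {
  stopifnot(length(k) == length(r), all(r > 0), !is.unsorted(k),
            all(k >= 1), all(k <= N - 1))
  out <- data.frame(k = as.integer(k), r = as.numeric(r))
  attr(out, "N") <- as.integer(N)
  class(out) <- c("DistanceProfile", "data.frame")
  out
}

#' Read a two-column (k, <R_k>) profile from plain text
#'
#' @param file whitespace-delimited table, optionally with a header.
#' @param N chain length; default inferred as `max(k) + 1`.
#' @export
readDistanceProfile <- function(file, N = NULL) {
  tb <- utils::read.table(file, header = FALSE,
                          col.names = c("k", "r"),
                          comment.char = "#")
  if (!is.numeric(tb$k)) tb <- utils::read.table(file, header = TRUE)[, 1:2]
  names(tb) <- c("k", "r")
  distanceProfile(tb$k, tb$r, if (is.null(N)) max(tb$k) + 1L else N)
}

#' Ideal-chain reference profile generator (testing aid)
#'
#' A stand-in reference following the ideal-chain scaling
#' `<R_k> = b * k^0.5`. Real Flory-random-coil reference profiles come
#' from external ensemble calculations and should be supplied as input
#' files; this generator only provides a synthetic reference for tests
#' and examples.
#'
#' @param N chain length in residues.
#' @param b prefactor (length units per sqrt(residue)).
#' @export
idealChainProfile <- function(N, b = 5.5) {
  k <- seq_len(N - 1L)
  distanceProfile(k, b * sqrt(k), N)
}

#' Delta: mean signed relative deviation from the FRC reference
#'
#' \deqn{\Delta = \frac{1}{N}\sum_k \frac{\langle R_k\rangle -
#'       \langle R_k^{FRC}\rangle}{\langle R_k^{FRC}\rangle}}
#' over all shared sequence separations. Compact chains give
#' `Delta < 0`, expanded chains `Delta > 0`; the self-avoiding limit
#' sits near 0.5. The conventional normalizer is the residue count `N`
#' even though `N - 1` separations are summed; set
#' `normalization = "separations"` to divide by the number of summed
#' terms instead. The choice is recorded as an attribute.
#'
#' @param profile,reference [distanceProfile()] objects on the same
#'   k-grid; the reference must be strictly positive.
#' @param normalization `"N"` (default) or `"separations"`.
#' @return Delta (numeric) with attribute `"normalization"`.
#' @export
deltaParameter <- function(profile, reference,
                           normalization = c("N", "separations")) {
  normalization <- match.arg(normalization)
  if (!identical(profile$k, reference$k))
    stop("profile and reference must share the same k-grid")
  if (any(reference$r <= 0)) stop("reference entries must be positive")
  s <- sum((profile$r - reference$r) / reference$r)
  denom <- if (normalization == "N") attr(profile, "N") else length(profile$k)
  out <- s / denom
  attr(out, "normalization") <- normalization
  out
}

#' Classify a linker by its Delta value
#'
#' `Delta < -0.1`: negative effective solvation volume (compact,
#' self-attractive); `-0.1 <= Delta <= 0.1`: near-zero (FRC-like);
#' `Delta > 0.1`: positive (expanded, self-avoiding). The middle
#' interval is closed on both sides.
#'
#' @param delta finite numeric vector.
#' @return factor with levels `negative_ves`, `near_zero_ves`,
#'   `positive_ves`.
#' @export
classifyLinkerRegime <- function(delta) {
  stopifnot(all(is.finite(delta)))
  out <- ifelse(delta < -0.1, "negative_ves",
                ifelse(delta <= 0.1, "near_zero_ves", "positive_ves"))
  factor(out, levels = c("negative_ves", "near_zero_ves", "positive_ves"))
}

#' Map linker residues to lattice sites (N ~ 7 n)
#'
#' One lattice site spans about seven linker residues (the spatial
#' dimension of an SH3 domain), so `n = round(N / 7)` with a minimum of
#' one site; the inverse returns `7 n`.
#'
#' @param N linker length in residues (>= 1).
#' @return lattice sites `n`.
#' @examples
#' residuesToLattice(35)  # 5
#' latticeToResidues(5)   # 35
#' @export
residuesToLattice <- function(N) {
  stopifnot(all(N >= 1))
  pmax(1L, as.integer(round(N / 7)))
}

#' @rdname residuesToLattice
#' @param n linker length in lattice sites.
#' @export
latticeToResidues <- function(n) 7L * as.integer(n)

#' Full sequence-metric report
#'
#' Convenience wrapper producing the CSV-style report: FCR/NCPR per
#' sequence, plus Delta and its regime when a profile and reference are
#' supplied.
#'
#' @param sequences named character vector (or FASTA path).
#' @param profile,reference optional [distanceProfile()]s.
#' @param ... passed to [chargeMetrics()].
#' @export
sequenceReport <- function(sequences, profile = NULL, reference = NULL, ...) {
  if (length(sequences) == 1 && file.exists(sequences))
    sequences <- readLinkerSequences(sequences)
  out <- chargeMetrics(sequences, ...)
  if (!is.null(profile) && !is.null(reference)) {
    d <- deltaParameter(profile, reference)
    out$delta <- as.numeric(d)
    out$regime <- as.character(classifyLinkerRegime(as.numeric(d)))
  }
  out
}
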