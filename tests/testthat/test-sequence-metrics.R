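## the fourteen 40-residue linkers with printed charge metrics
TABLE2 <- data.frame(
  seq = c("EDEDSEKEEEEEDKEMEELQEEKECEKPQGDEEEEEEEEE",
          "DEEGNAYGSEREEEDEEEDEEDGKRELELEEEELGGEEED",
          "REKDREKYSQREQERDRQQNDQNRPSEKGEKEEKSKAKEE",
          "KSSSQTSGSLVSKSTSLASVSQLASKSSSQTSTSQLPSKS"),
  FCR = c(0.80, 0.70, 0.65, 0.10),
  NCPR = c(-0.60, -0.55, 0.00, 0.10))

test_that("FCR and NCPR reproduce the printed linker table exactly", {
  cm <- chargeMetrics(TABLE2$seq)
  expect_equal(cm$FCR, TABLE2$FCR)
  expect_equal(cm$NCPR, TABLE2$NCPR)
  expect_equal(chargeMetrics("GGGG")$FCR, 0)
  expect_equal(chargeMetrics("GGGG")$NCPR, 0)
})

test_that("charge metrics obey their bounds on arbitrary sequences", {
  set.seed(1)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (k in 1:50) {
    s <- paste(sample(alphabet, sample(5:60, 1), replace = TRUE),
               collapse = "")
    cm <- chargeMetrics(s)
    expect_gte(cm$FCR, abs(cm$NCPR))
    expect_true(cm$FCR >= 0 && cm$FCR <= 1)
  }
  ## histidine is neutral under the charge alphabet
  expect_equal(chargeMetrics("HHHH")$FCR, 0)
})

test_that("unknown residues error or are skipped per configuration", {
  expect_error(chargeMetrics("AXDE"), "unknown residue")
  expect_warning(cm <- chargeMetrics("AXDE", onUnknown = "skip"), "skipping")
  expect_equal(cm$length, 3L)
  expect_equal(cm$FCR, 2 / 3)
})

test_that("FASTA input round-trips through Biostrings", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">linker1", TABLE2$seq[1], ">linker2", TABLE2$seq[4]), f)
  seqs <- readLinkerSequences(f)
  expect_equal(unname(seqs), TABLE2$seq[c(1, 4)])
  rep <- sequenceReport(f)
  expect_equal(rep$FCR, TABLE2$FCR[c(1, 4)])
  unlink(f)
})

test_that("Delta follows its closed forms and an independent re-evaluation", {
  N <- 41
  ref <- idealChainProfile(N)
  ## identical profiles
  expect_equal(as.numeric(deltaParameter(ref, ref)), 0)
  ## profile = 1.5 x reference: Delta = 0.5 (N-1)/N under the caption
  ## normalization, exactly 0.5 when dividing by the summed separations
  prof <- distanceProfile(ref$k, 1.5 * ref$r, N)
  expect_equal(as.numeric(deltaParameter(prof, ref)), 0.5 * (N - 1) / N)
  expect_equal(as.numeric(deltaParameter(prof, ref,
                                         normalization = "separations")), 0.5)
  ## random profiles against a direct loop evaluation
  set.seed(2)
  for (k in 1:20) {
    r <- ref$r * exp(runif(N - 1, -0.5, 0.5))
    p <- distanceProfile(ref$k, r, N)
    acc <- 0
    for (i in seq_len(N - 1)) acc <- acc + (r[i] - ref$r[i]) / ref$r[i]
    expect_equal(as.numeric(deltaParameter(p, ref)), acc / N)
  }
})

test_that("Delta is linear in the profile on a shared grid", {
  N <- 30
  ref <- idealChainProfile(N)
  p <- distanceProfile(ref$k, 1.8 * ref$r, N)
  for (alpha in c(0.25, 0.5, 0.9)) {
    mix <- distanceProfile(ref$k, alpha * p$r + (1 - alpha) * ref$r, N)
    expect_equal(as.numeric(deltaParameter(mix, ref)),
                 alpha * as.numeric(deltaParameter(p, ref)),
                 tolerance = 1e-12)
  }
})

test_that("profile grids must match and references must be positive", {
  ref <- idealChainProfile(20)
  short <- distanceProfile(1:10, sqrt(1:10), 20)
  expect_error(deltaParameter(short, ref), "k-grid")
})

test_that("linker regimes split at +-0.1 with a closed middle interval", {
  expect_equal(as.character(classifyLinkerRegime(-0.2)), "negative_ves")
  expect_equal(as.character(classifyLinkerRegime(-0.1)), "near_zero_ves")
  expect_equal(as.character(classifyLinkerRegime(0.1)), "near_zero_ves")
  expect_equal(as.character(classifyLinkerRegime(0.3)), "positive_ves")
  expect_equal(as.character(classifyLinkerRegime(0.100001)), "positive_ves")
})

test_that("residue <-> lattice mapping follows N ~ 7n", {
  expect_equal(residuesToLattice(35), 5L)
  expect_equal(residuesToLattice(7), 1L)
  expect_equal(residuesToLattice(84), 12L)
  expect_equal(residuesToLattice(2), 1L)   # floor at one site
  expect_equal(latticeToResidues(5), 35L)
  expect_equal(residuesToLattice(latticeToResidues(3)), 3L)
})

test_that("plain-text profiles are read back faithfully", {
  f <- tempfile()
  prof <- idealChainProfile(15)
  write.table(prof, f, row.names = FALSE, col.names = FALSE)
  back <- readDistanceProfile(f)
  expect_equal(back$k, prof$k)
  expect_equal(back$r, prof$r, tolerance = 1e-6)
  unlink(f)
})
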