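smallConfig <- function(...) {
  args <- utils::modifyList(
    list(nMrna = 2L, nTrna = 4L, nNcrna = 1L,
         rrnaLengths = c(`16S` = 150), coverage = 30L),
    list(...))
  do.call(syntheticConfig, args)
}

test_that("reference generation is deterministic under the seed and varies across seeds", {
  cfg <- smallConfig(seed = 1)
  r1 <- generateReference(cfg)
  r2 <- generateReference(cfg)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeReferenceFasta(r1, f1); writeReferenceFasta(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  r3 <- generateReference(smallConfig(seed = 2))
  expect_false(identical(as.character(referenceSequences(r1)),
                         as.character(referenceSequences(r3))))
  bt <- table(biotypes(r1))
  expect_true(all(c("mRNA", "rRNA", "tRNA", "ncRNA") %in% names(bt)))
})

test_that("reference invariants are enforced", {
  cfg <- smallConfig(seed = 3)
  ref <- generateReference(cfg)
  u <- as.data.frame(ref@utr)
  expect_true(all(u$cds_len %% 3 == 0))
  lens <- setNames(Biostrings::width(referenceSequences(ref)),
                   transcripts(ref))
  expect_equal(u$utr5_len + u$cds_len + u$utr3_len,
               unname(lens[u$transcript]))
  # a CDS not divisible by 3 is rejected by the class validity
  broken <- ref
  expect_error({broken@utr$cds_len[1] <- broken@utr$cds_len[1] + 1L
                validObject(broken)},
               "divisible by 3")
  expect_error(syntheticConfig(eBase = 0.5, deltaMod = 0.6), "exceed 1")
  expect_error(syntheticConfig(replicates = 1), "replicates")
  expect_error(syntheticConfig(errorMix = c(0.5, 0.5, 0.5)), "errorMix")
})

test_that("truth sampling zeroes the IVT and shifts responsive wobble sites", {
  cfg <- smallConfig(seed = 4, stressShift = 0.3)
  ref <- generateReference(cfg)
  truth <- as.data.frame(sampleTruth(ref, cfg))
  ivt <- truth[truth$condition == "IVT", ]
  expect_true(all(ivt$stoichiometry == 0))
  lens <- setNames(Biostrings::width(referenceSequences(ref)),
                   transcripts(ref))
  expect_true(all(truth$pos >= 1 & truth$pos <= lens[truth$transcript]))
  # responsive (Q/Mnm) wobble sites move by +stressShift, clipped at 1
  tr <- as.data.frame(ref@trna)
  for (i in seq_len(nrow(tr))) {
    s0 <- truth$stoichiometry[truth$transcript == tr$transcript[i] &
                              truth$condition == "nostress"]
    s1 <- truth$stoichiometry[truth$transcript == tr$transcript[i] &
                              truth$condition == "acid"]
    if (tr$pathway[i] %in% c("Q", "Mnm"))
      expect_equal(s1, pmin(1, s0 + 0.3))
    else expect_equal(s1, s0)
  }
})

test_that("requesting a 36-site rRNA layout yields 36 truth rows per condition", {
  cfg <- syntheticConfig(seed = 5, nMrna = 1L, nTrna = 1L, nNcrna = 1L,
                         coverage = 10L)
  ref <- generateReference(cfg)
  truth <- as.data.frame(sampleTruth(ref, cfg))
  rrna <- truth[truth$transcript %in% c("16S", "23S") &
                truth$condition == "nostress", ]
  expect_identical(nrow(rrna), 36L)
  km <- knownModTable()
  expect_setequal(paste(rrna$transcript, rrna$pos),
                  paste(km$molecule, km$position))
})

test_that("simulated per-position error rates match the molecule-level model", {
  # one transcript, no modification: empirical rate ~ eBase; fully
  # modified site: ~ eBase + deltaMod; binomial tolerance at 4 SD
  cfg <- syntheticConfig(seed = 6, nMrna = 1L, nTrna = 1L, nNcrna = 1L,
                         rrnaLengths = c(`16S` = 120), coverage = 800L,
                         eBase = 0.03, deltaMod = 0.25, meanQ = 20, qSd = 0)
  ref <- generateReference(cfg)
  truth <- S4Vectors::DataFrame(transcript = "16S", pos = 60L, mod = "m5C",
                                condition = "nostress", stoichiometry = 1)
  d <- withr::local_tempdir()
  sams <- simulateAlignments(ref, truth, cfg, d, conditions = "nostress",
                             replicates = 1L, transcripts = "16S")
  prof <- computeBCError(readAlignments(sams$path[1]),
                         referenceSequences(ref)["16S"])
  pd <- as.data.frame(profileData(prof))
  expect_true(all(pd$coverage == 800L))    # read-count conservation
  sd0 <- sqrt(0.03 * 0.97 / 800)
  base <- pd$bcerror[pd$pos != 60]
  expect_true(all(abs(base - 0.03) < 4 * sd0))
  expect_lt(abs(mean(base) - 0.03), 3 * sd0 / sqrt(length(base)))
  sd1 <- sqrt(0.28 * 0.72 / 800)
  expect_lt(abs(pd$bcerror[pd$pos == 60] - 0.28), 4 * sd1)
})

test_that("alignment simulation is byte-deterministic and IVT stays at baseline", {
  cfg <- smallConfig(seed = 7, coverage = 200L)
  ref <- generateReference(cfg)
  truth <- sampleTruth(ref, cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateAlignments(ref, truth, cfg, d1, conditions = "IVT",
                     replicates = 1L, transcripts = "16S")
  simulateAlignments(ref, truth, cfg, d2, conditions = "IVT",
                     replicates = 1L, transcripts = "16S")
  s1 <- readLines(file.path(d1, "IVT_rep1.sam"))
  s2 <- readLines(file.path(d2, "IVT_rep1.sam"))
  expect_identical(s1, s2)
  prof <- computeBCError(readAlignments(file.path(d1, "IVT_rep1.bam")),
                         referenceSequences(ref)["16S"])
  pd <- as.data.frame(profileData(prof))
  # no position should sit far above eBase in the unmodified control
  expect_true(all(pd$bcerror < 0.03 + 4 * sqrt(0.03 * 0.97 / 200)))
})

test_that("pre-tRNA length simulation couples modification to maturity as configured", {
  base <- list(seed = 8, nMrna = 1L, nTrna = 20L, nNcrna = 1L,
               rrnaLengths = c(`16S` = 100), coverage = 80L)
  mk <- function(f) do.call(syntheticConfig, c(base, immaturityFactor = f))
  cfg0 <- mk(0)
  ref <- generateReference(cfg0)
  truth <- sampleTruth(ref, cfg0)
  tab0 <- simulatePretrnaLengths(ref, truth, cfg0, conditions = "nostress")
  immature <- tab0$length > 100
  expect_false(any(tab0$modified[immature]))  # factor 0: no immature mods

  tab <- simulatePretrnaLengths(ref, truth, mk(0.3),
                                conditions = "nostress")
  agg <- aggregate(cbind(length, modified) ~ transcript, tab, mean)
  expect_lt(cor(agg$length, agg$modified), 0)
})

test_that("synthetic TE classes track codon scores only when the effect is on", {
  cfg <- syntheticConfig(seed = 9, nMrna = 60L, nTrna = 1L, nNcrna = 1L,
                         rrnaLengths = c(`16S` = 100), coverage = 10L,
                         teEffect = 3)
  ref <- generateReference(cfg)
  te <- generateTeTable(ref, cfg)
  expect_setequal(te$transcript, names(which(biotypes(ref) == "mRNA")))
  inc <- te$codon_abundance[te$class == "increased"]
  dec <- te$codon_abundance[te$class == "decreased"]
  expect_gt(median(inc), median(dec))
})
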