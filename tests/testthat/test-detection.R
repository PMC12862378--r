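profFromBC <- function(bc, transcript = "tx", coverage = 100L,
                       sample = "s") {
  n <- length(bc)
  new("PileupProfile", sample = sample, sampleClass = "mRNAe", minDepth = 5,
      data = S4Vectors::DataFrame(
        transcript = transcript, pos = seq_len(n),
        coverage = coverage,
        error_count = as.integer(round(bc * coverage)),
        bcerror = bc, masked = FALSE))
}

test_that("delta profiles subtract positionwise and mask the normalized form", {
  a <- profFromBC(c(0.30, 0.10, 0.05))
  b <- profFromBC(c(0.20, 0.10, 0.00))
  d <- deltaProfile(a, b)
  dd <- as.data.frame(profileData(d))
  expect_equal(dd$delta, c(0.10, 0.00, 0.05))
  expect_equal(dd$norm_delta[1], 0.50)
  # zero control: delta reported, normalized masked
  expect_true(dd$norm_masked[3])
  expect_false(dd$masked[3])
  expect_true(is.na(dd$norm_delta[3]))
  # identical profiles give an all-zero delta
  expect_true(all(profileData(deltaProfile(a, a))$delta == 0))
  # antisymmetry
  d2 <- deltaProfile(b, a)
  expect_equal(profileData(d2)$delta, -dd$delta)
  # masked input positions stay masked
  am <- a; am@data$masked[2] <- TRUE
  expect_true(profileData(deltaProfile(am, b))$masked[2])
  # length mismatch is a hard error
  expect_error(deltaProfile(a, profFromBC(c(0.1, 0.2))), "identical")
})

test_that("threshold calibration reproduces hand-enumerated precision/recall", {
  # 6 positions: known sites at 1-4 with delta .05/.03/.01/.04,
  # non-sites at 5-6 with delta .025/0
  d <- deltaProfile(profFromBC(c(0.05, 0.03, 0.01, 0.04, 0.025, 0)),
                    profFromBC(rep(0, 6)))
  known <- data.frame(molecule = "tx", position = 1:4, mod = "m")
  cal <- calibrateThreshold(d, known, grid = c(0.02))
  g <- calibrationGrid(cal)
  expect_equal(g$tp, 3)
  expect_equal(g$precision, 0.75)
  expect_equal(g$recall, 0.75)

  # perfect separation: precision = recall = 1 throughout (0, 0.5]
  dp <- deltaProfile(profFromBC(c(0.5, 0, 0.5, 0, 0)),
                     profFromBC(rep(0, 5)))
  kp <- data.frame(molecule = "tx", position = c(1, 3), mod = "m")
  calp <- calibrateThreshold(dp, kp, grid = c(0.01, 0.1, 0.3, 0.5))
  expect_true(all(calibrationGrid(calp)$precision == 1))
  expect_true(all(calibrationGrid(calp)$recall == 1))

  # recall is non-increasing along the ascending grid
  cal2 <- calibrateThreshold(d, known, grid = seq(0, 0.06, by = 0.005))
  expect_true(all(diff(calibrationGrid(cal2)$recall) <= 0))

  # tau override wins over the F1 optimum
  cal3 <- calibrateThreshold(d, known, grid = seq(0, 0.06, by = 0.005),
                             tau = 0.02)
  expect_equal(chosenThreshold(cal3), 0.02)

  expect_error(calibrateThreshold(d, known[0, ]), "empty")
  dmask <- d; dmask@data$masked <- TRUE
  expect_error(calibrateThreshold(dmask, known), "masked")
})

test_that("site classification respects the threshold boundary and nests", {
  d <- deltaProfile(profFromBC(c(0.021, 0.019, 0.020, 0.30)),
                    profFromBC(rep(0, 4)))
  calls <- classifySites(d, tau = 0.02)
  expect_setequal(calls$pos, c(1, 3, 4))  # 0.021 and 0.020 in, 0.019 out
  # tau = 0 calls every unmasked non-negative position
  expect_identical(nrow(classifySites(d, tau = 0)), 4L)
  # nesting: higher tau yields a subset
  c1 <- classifySites(d, 0.01); c2 <- classifySites(d, 0.025)
  expect_true(all(paste(c2$transcript, c2$pos) %in%
                  paste(c1$transcript, c1$pos)))
})

test_that("consensus requires every replicate and honors external regions", {
  r1 <- data.frame(transcript = "tx", pos = c(10, 20, 30),
                   delta = c(0.05, 0.04, 0.03))
  r2 <- data.frame(transcript = "tx", pos = c(10, 30),
                   delta = c(0.06, 0.02))
  cons <- consensusSites(list(rep1 = r1, rep2 = r2))
  expect_setequal(cons$pos, c(10, 30))      # pos 20 only in rep1: dropped
  expect_true(all(grepl("rep1", cons$supported_by) &
                  grepl("rep2", cons$supported_by)))
  # a region mask keeps only covered calls
  regions <- GenomicRanges::GRanges("tx", IRanges::IRanges(8, 12))
  consR <- consensusSites(list(rep1 = r1, rep2 = r2), regions = regions)
  expect_equal(consR$pos, 10)
  expect_match(consR$supported_by, "region")
  # regions given but nothing overlaps: everything dropped
  far <- GenomicRanges::GRanges("tx", IRanges::IRanges(100, 200))
  expect_identical(nrow(consensusSites(list(rep1 = r1, rep2 = r2),
                                       regions = far)), 0L)
  expect_error(consensusSites(list()), "no replicate")
})

test_that("BED region input round-trips through the 0-based convention", {
  bed <- tempfile(fileext = ".bed")
  writeLines("tx\t7\t12", bed)  # 0-based half-open [7,12) = 1-based 8..12
  r1 <- data.frame(transcript = "tx", pos = c(7, 8, 12, 13),
                   delta = rep(0.05, 4))
  cons <- consensusSites(list(a = r1, b = r1), regions = bed)
  expect_setequal(cons$pos, c(8, 12))
})

test_that("motif proximity fractions come from sense-strand IUPAC search", {
  # plant the motif GTTCA at position 11 of transcript m1
  s <- paste0(strrep("A", 10), "GTTCA", strrep("A", 15))
  seqs <- Biostrings::DNAStringSet(c(m1 = s, m2 = strrep("C", 30)))
  calls <- data.frame(
    transcript = c("m1", "m1", "m1", rep("m2", 5)),
    pos = c(7, 12, 26, 1:5))  # starts within 4 nt of 11: pos 7 and 12
  expect_equal(motifProximityFraction(calls, seqs, "GUUCA", window = 4),
               2 / 8)
  # IUPAC code in the motif
  expect_equal(motifProximityFraction(calls, seqs, "GUUCN", window = 4),
               2 / 8)
  # motif matching at every call / no occurrence at all
  expect_equal(motifProximityFraction(calls[1, , drop = FALSE], seqs,
                                      "GUUCA"), 1.0)
  expect_equal(motifProximityFraction(calls, seqs, "GGGGG"), 0.0)
  expect_error(motifProximityFraction(calls, seqs, character(0)), "empty")
})

test_that("the shipped known-site table loads and validates", {
  km <- knownModTable()
  expect_identical(anyDuplicated(km[, c("molecule", "position")]), 0L)
  expect_true(all(c("16S", "23S") %in% km$molecule))
})
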