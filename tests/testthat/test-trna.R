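trnaProfile <- function(bcByTx, sample = "s", coverage = 50L,
                        minDepth = 5) {
  rows <- lapply(names(bcByTx), function(tx) {
    bc <- bcByTx[[tx]]
    cov <- rep_len(coverage, length(bc))
    S4Vectors::DataFrame(transcript = tx, pos = seq_along(bc),
                         coverage = as.integer(cov),
                         error_count = as.integer(round(bc * cov)),
                         bcerror = bc, masked = cov < minDepth)
  })
  new("PileupProfile", sample = sample, sampleClass = "tRNAseq",
      minDepth = minDepth, data = do.call(rbind, rows))
}

flatTrna <- function(n = 76, bc = 0.05) rep(bc, n)

test_that("anticodon delta matrices average replicates and apply the depth rule", {
  meta <- data.frame(transcript = c("t1", "t2"),
                     anticodon_start = c(34L, 34L))
  ctrl <- trnaProfile(list(t1 = flatTrna(), t2 = flatTrna()))
  # identical stress and control profiles give an all-zero matrix
  acd0 <- anticodonDeltaMatrix(list(ctrl, ctrl), list(ctrl, ctrl), meta)
  expect_true(all(acd0$mean == 0))
  expect_identical(dim(acd0$mean), c(2L, 7L))
  expect_identical(colnames(acd0$mean), as.character(32:38))

  # t1 raised to 0.4 at position 34 in stress (control 0.1)
  s1 <- list(t1 = replace(flatTrna(bc = 0.1), 34, 0.4),
             t2 = flatTrna(bc = 0.1))
  c1 <- list(t1 = flatTrna(bc = 0.1), t2 = flatTrna(bc = 0.1))
  acd <- anticodonDeltaMatrix(list(trnaProfile(s1)), list(trnaProfile(c1)),
                              meta)
  expect_equal(acd$mean["t1", "34"], 0.3)
  expect_equal(acd$mean["t1", "35"], 0)

  # replicate averaging: deltas 0.3 and 0.1 -> mean 0.2
  s2 <- list(t1 = replace(flatTrna(bc = 0.1), 34, 0.2),
             t2 = flatTrna(bc = 0.1))
  acd2 <- anticodonDeltaMatrix(
    list(trnaProfile(s1), trnaProfile(s2)),
    list(trnaProfile(c1), trnaProfile(c1)), meta)
  expect_equal(acd2$mean["t1", "34"], 0.2)

  # a tRNA with 4 reads fails the >= 5 read depth rule and is excluded
  low <- trnaProfile(list(t1 = flatTrna(), t2 = flatTrna()),
                     coverage = c(rep(50L, 76)))
  low@data$coverage[low@data$transcript == "t2"] <- 4L
  low@data$masked <- low@data$coverage < 5L
  acd3 <- anticodonDeltaMatrix(list(low), list(low), meta)
  expect_identical(acd3$excluded, "t2")
  expect_identical(rownames(acd3$mean), "t1")

  expect_error(
    anticodonDeltaMatrix(list(ctrl), list(ctrl),
                         meta[meta$transcript == "t1", , drop = FALSE]),
    "metadata missing")
})

test_that("cumulative anticodon delta is additive over its positions", {
  meta <- data.frame(transcript = "t1", anticodon_start = 34L)
  bc <- flatTrna(bc = 0.1)
  bc[34:36] <- c(0.3, 0.25, 0.15)
  acd <- anticodonDeltaMatrix(list(trnaProfile(list(t1 = bc))),
                              list(trnaProfile(list(t1 = flatTrna(bc = 0.1)))),
                              meta)
  tot <- anticodonTotalDelta(acd)
  expect_equal(unname(tot["t1"]),
               sum(acd$mean["t1", c("34", "35", "36")]))
  expect_equal(unname(tot["t1"]), 0.2 + 0.15 + 0.05)
  totLoop <- anticodonTotalDelta(acd, span = "loop")
  expect_equal(unname(totLoop["t1"]), sum(acd$mean["t1", ]))
})

test_that("stress-responsiveness needs magnitude and replicate sign agreement", {
  meta <- data.frame(transcript = "t1", anticodon_start = 34L)
  mk <- function(d34) {
    bc <- flatTrna(bc = 0.3); bc[34] <- 0.3 + d34
    trnaProfile(list(t1 = bc))
  }
  ctrl <- trnaProfile(list(t1 = flatTrna(bc = 0.3)))
  # all-zero deltas: non-responsive
  r0 <- classifyStressResponsive(
    anticodonDeltaMatrix(list(ctrl, ctrl), list(ctrl, ctrl), meta))
  expect_false(r0$responsive)
  # +0.3 in both replicates at cutoff 0.1: responsive increase
  r1 <- classifyStressResponsive(
    anticodonDeltaMatrix(list(mk(0.3), mk(0.3)), list(ctrl, ctrl), meta))
  expect_true(r1$responsive)
  expect_equal(r1$direction, "increase")
  expect_equal(r1$position, 34L)
  # sign conflict between replicates: non-responsive
  r2 <- classifyStressResponsive(
    anticodonDeltaMatrix(list(mk(0.3), mk(-0.2)), list(ctrl, ctrl), meta))
  expect_false(r2$responsive)
  # below cutoff: non-responsive
  r3 <- classifyStressResponsive(
    anticodonDeltaMatrix(list(mk(0.05), mk(0.05)), list(ctrl, ctrl), meta))
  expect_false(r3$responsive)
})

test_that("length distributions weight each tRNA and replicate equally", {
  # one tRNA with 10 reads at 80 nt, another with 1000 reads at 300 nt:
  # each contributes half the group density
  lengths <- rbind(
    data.frame(transcript = "t1", condition = "ns", replicate = 1,
               length = rep(80, 10)),
    data.frame(transcript = "t2", condition = "ns", replicate = 1,
               length = rep(300, 1000)))
  d <- lengthDistributions(lengths, binwidth = 10)
  expect_equal(sum(d$density * 10), 1)
  d80 <- d$density[d$bin_mid == 75]
  d300 <- d$density[d$bin_mid == 295]
  expect_equal(d80, d300)      # equal weights despite 100x read counts
  expect_equal(d80, 0.05)      # half the mass in one 10-nt bin

  # point mass: all reads in one bin
  one <- data.frame(transcript = "t1", condition = "ns", replicate = 1,
                    length = rep(80, 50))
  d1 <- lengthDistributions(one, binwidth = 10)
  expect_identical(sum(d1$density > 0), 1L)

  # reads beyond the range clip into the last bin
  long <- data.frame(transcript = "t1", condition = "ns", replicate = 1,
                     length = c(80, 700))
  d2 <- lengthDistributions(long, binwidth = 10)
  expect_equal(d2$density[d2$bin_mid == 495], 0.05)

  # a (group, condition) combination without reads warns and is omitted
  mixed <- rbind(lengths,
                 data.frame(transcript = "t2", condition = "acid",
                            replicate = 1, length = rep(120, 5)))
  expect_warning(
    dmix <- lengthDistributions(mixed, groups = c(t1 = "a", t2 = "b")),
    "empty group")
  expect_false(any(dmix$group == "a" & dmix$condition == "acid"))
})

test_that("maturity metric is the log2 ratio of condition mean lengths", {
  lengths <- rbind(
    data.frame(transcript = "t1", condition = "acid", replicate = 1,
               length = rep(200, 10)),
    data.frame(transcript = "t1", condition = "ns", replicate = 1,
               length = rep(100, 10)),
    data.frame(transcript = "t2", condition = "acid", replicate = 1,
               length = rep(90, 4)),       # below minReads
    data.frame(transcript = "t2", condition = "ns", replicate = 1,
               length = rep(90, 10)),
    data.frame(transcript = "t3", condition = "acid", replicate = 1,
               length = rep(120, 8)),
    data.frame(transcript = "t3", condition = "ns", replicate = 1,
               length = rep(120, 8)))
  m <- maturityMetric(lengths, stress = "acid", control = "ns")
  expect_equal(m$maturity[m$transcript == "t1"], 1.0)
  expect_equal(m$maturity[m$transcript == "t3"], 0.0)
  expect_false("t2" %in% m$transcript)
})

test_that("the correlation test gates Pearson by Shapiro-Wilk normality", {
  # perfectly monotone decreasing, heavily non-normal pairs -> Spearman -1
  x <- c(1, 2, 3, 4, 5, 6, 7, 200)
  y <- -exp(x / 3)
  r <- correlationTest(x, y)
  expect_equal(r$method, "spearman")
  expect_equal(r$estimate, -1)

  # Spearman is invariant under strictly monotone transforms
  r2 <- correlationTest(exp(x), y)
  expect_equal(r2$estimate, r$estimate)
  expect_equal(r2$p.value, r$p.value)

  # near-normal data -> Pearson, equal to the closed-form ratio
  set.seed(21)
  xn <- c(-1.2, -0.5, 0.1, 0.4, 0.9, 1.5)
  yn <- c(-0.9, -0.6, -0.1, 0.5, 0.8, 1.2)
  rp <- correlationTest(xn, yn)
  expect_equal(rp$method, "pearson")
  closed <- sum((xn - mean(xn)) * (yn - mean(yn))) /
    sqrt(sum((xn - mean(xn))^2) * sum((yn - mean(yn))^2))
  expect_equal(rp$estimate, closed)

  expect_error(correlationTest(1:3, 1:3), "at least 4")
})

test_that("maturity-modification correlation recovers the synthetic coupling", {
  cfg <- syntheticConfig(seed = 23, nMrna = 1L, nTrna = 30L, nNcrna = 1L,
                         rrnaLengths = c(`16S` = 100), coverage = 60L,
                         immaturityFactor = 0.3)
  ref <- generateReference(cfg)
  truth <- sampleTruth(ref, cfg)
  tab <- simulatePretrnaLengths(ref, truth, cfg, conditions = "nostress")
  agg <- aggregate(cbind(length, modified) ~ transcript, tab, mean)
  r <- correlationTest(agg$length, agg$modified)
  expect_lt(r$estimate, 0)
  expect_lt(r$p.value, 0.05)
})
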