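#' @include AllClasses.R utils.R
NULL

BASES <- c("A", "C", "G", "T")

#' Build a synthetic-data configuration
#'
#' Collects the parameters of the synthetic epitranscriptome in one
#' validated object. Defaults describe the emulated study design: two
#' biological replicates per condition plus an unmodified IVT control, a
#' 3\% baseline basecalling error, a 25\% error boost on modified
#' molecules, 500x coverage, and a pre-tRNA population mixing mature
#' (70-100 nt) and immature (100-500 nt, leader/trailer-bearing) reads
#' whose anticodon modification level drops on immature molecules.
#'
#' @param seed master RNG seed (integer). All outputs are byte-identical
#'   under the same configuration.
#' @param nMrna,nTrna,nNcrna transcript counts per biotype (each >= 1).
#' @param rrnaLengths named numeric: one rRNA transcript per entry.
#' @param eBase,deltaMod,errorMix basecalling-error model (see
#'   [SyntheticConfig]).
#' @param coverage reads per transcript per replicate.
#' @param conditions,ivtLabel,replicates sample layout.
#' @param meanQ,qSd per-read quality model (Phred).
#' @param matureRange,immatureRange,matureWeightRange pre-tRNA read-length
#'   mixture.
#' @param immaturityFactor multiplier on the anticodon modification
#'   probability of immature reads (1 decouples length from modification).
#' @param stressShift stoichiometry increase at responsive wobble sites
#'   under stress.
#' @param teEffect strength of the link between codon scores and the
#'   synthetic translational-efficiency classes.
#' @return a validated [SyntheticConfig].
#' @examples
#' cfg <- syntheticConfig(seed = 1, coverage = 50)
#' cfg
#' @export
syntheticConfig <- function(seed = 1L,
                            nMrna = 6L, nTrna = 20L, nNcrna = 2L,
                            rrnaLengths = c(`16S` = 1542, `23S` = 2904),
                            eBase = 0.03, deltaMod = 0.25,
                            coverage = 500L,
                            conditions = c("nostress", "acid", "IVT"),
                            ivtLabel = "IVT",
                            replicates = 2L,
                            errorMix = c(mismatch = 0.6, deletion = 0.3,
                                         insertion = 0.1),
                            meanQ = 12, qSd = 2,
                            matureRange = c(70, 100),
                            immatureRange = c(100, 500),
                            matureWeightRange = c(0.3, 0.9),
                            immaturityFactor = 0.3,
                            stressShift = 0.3,
                            teEffect = 1) {
  if (any(c(nMrna, nTrna, nNcrna) < 1L) || length(rrnaLengths) < 1L)
    stop("the reference needs at least one transcript of each biotype")
  if (is.null(names(rrnaLengths)))
    stop("rrnaLengths must be named (e.g. c(`16S` = 1542, `23S` = 2904))")
  new("SyntheticConfig",
      seed = as.integer(seed),
      nMrna = as.integer(nMrna), nTrna = as.integer(nTrna),
      nNcrna = as.integer(nNcrna),
      rrnaLengths = rrnaLengths,
      eBase = eBase, deltaMod = deltaMod,
      coverage = as.integer(coverage),
      conditions = conditions, ivtLabel = ivtLabel,
      replicates = as.integer(replicates),
      errorMix = errorMix, meanQ = meanQ, qSd = qSd,
      matureRange = matureRange, immatureRange = immatureRange,
      matureWeightRange = matureWeightRange,
      immaturityFactor = immaturityFactor,
      stressShift = stressShift, teEffect = teEffect)
}

#' Generate a synthetic transcriptome reference
#'
#' Random transcript sequences with realistic structural metadata: mRNAs
#' carry 5'UTR/CDS/3'UTR partitions (CDS length divisible by 3), tRNAs
#' carry an anticodon position plus leader/trailer lengths describing the
#' unprocessed precursor, and rRNAs take the configured lengths so that
#' curated rRNA site positions remain addressable.
#'
#' @param config a [SyntheticConfig].
#' @return a [SyntheticReference].
#' @examples
#' ref <- generateReference(syntheticConfig(seed = 1))
#' ref
#' @export
generateReference <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  withSeed(deriveSeed(config@seed, "reference"), {
    seqs <- character(); biotype <- character()
    utr <- list(); trna <- list()

    for (i in seq_along(config@rrnaLengths)) {
      id <- names(config@rrnaLengths)[i]
      seqs[[id]] <- randomDna(config@rrnaLengths[i])
      biotype[[id]] <- "rRNA"
    }
    for (i in seq_len(config@nMrna)) {
      id <- sprintf("mRNA_%02d", i)
      u5 <- sample(20:60, 1); cds <- 3L * sample(50:150, 1)
      u3 <- sample(20:60, 1)
      seqs[[id]] <- randomDna(u5 + cds + u3)
      biotype[[id]] <- "mRNA"
      utr[[id]] <- data.frame(transcript = id, utr5_len = u5,
                              cds_len = cds, utr3_len = u3)
    }
    pathways <- c("Q", "Mnm", "cmo5U", "other")
    for (i in seq_len(config@nTrna)) {
      id <- sprintf("tRNA_%02d", i)
      len <- sample(72:90, 1)
      seqs[[id]] <- randomDna(len)
      biotype[[id]] <- "tRNA"
      trna[[id]] <- data.frame(
        transcript = id,
        anticodon_start = 34L,
        leader_len = sample(20:150, 1),
        trailer_len = sample(20:250, 1),
        pathway = pathways[(i - 1L) %% 4L + 1L])
    }
    for (i in seq_len(config@nNcrna)) {
      id <- sprintf("ncRNA_%02d", i)
      seqs[[id]] <- randomDna(sample(80:200, 1))
      biotype[[id]] <- "ncRNA"
    }

    new("SyntheticReference",
        sequences = Biostrings::DNAStringSet(unlist(seqs)),
        biotype = unlist(biotype),
        utr = DataFrame(do.call(rbind, unname(utr))),
        trna = DataFrame(do.call(rbind, unname(trna))))
  })
}

#' Sample a ground-truth modification table
#'
#' Places modified sites on the reference and assigns each a per-condition
#' stoichiometry (fraction of molecules modified). rRNA sites default to
#' the shipped curated positions when the reference rRNAs are long enough
#' to host them; each tRNA gets a wobble-position site whose stoichiometry
#' increases by `stressShift` under non-control conditions when the tRNA is
#' on the Q or Mnm pathway (the stress-responsive set). The IVT condition
#' is modification-free: its stoichiometry is exactly 0 everywhere.
#'
#' @param reference a [SyntheticReference].
#' @param config a [SyntheticConfig].
#' @param rrnaSites optional data.frame (molecule, position, mod)
#'   overriding the rRNA site layout; defaults to [knownModTable()] where
#'   positions fit, otherwise random positions.
#' @param rrnaStoichiometries stoichiometries assigned (in table order) to
#'   the rRNA sites; recycled/interpolated to the site count.
#' @param sitesPerMrna modified sites sampled per mRNA/ncRNA transcript.
#' @return a [S4Vectors::DataFrame] with columns transcript, pos (1-based),
#'   mod, condition, stoichiometry; one row per site and condition.
#' @export
sampleTruth <- function(reference, config, rrnaSites = NULL,
                        rrnaStoichiometries = seq(0.2, 0.9, length.out = 36),
                        sitesPerMrna = 3L) {
  stopifnot(is(reference, "SyntheticReference"), is(config, "SyntheticConfig"))
  lens <- BiocGenerics::width(reference@sequences)
  names(lens) <- names(reference@sequences)
  rrna <- names(which(reference@biotype == "rRNA"))

  withSeed(deriveSeed(config@seed, "truth"), {
    sites <- list()

    if (is.null(rrnaSites)) {
      km <- knownModTable()
      if (all(km$molecule %in% rrna) &&
          all(km$position <= lens[km$molecule])) {
        rrnaSites <- data.frame(molecule = km$molecule,
                                position = km$position, mod = km$mod)
      } else {
        rrnaSites <- do.call(rbind, lapply(rrna, function(tx) {
          p <- sort(sample(seq_len(lens[tx]), min(18L, lens[tx])))
          data.frame(molecule = tx, position = p, mod = "mod")
        }))
      }
    }
    s_r <- rep_len(rrnaStoichiometries, nrow(rrnaSites))
    sites$rrna <- data.frame(transcript = rrnaSites$molecule,
                             pos = rrnaSites$position,
                             mod = rrnaSites$mod, s_control = s_r,
                             s_stress = s_r)

    mr <- names(reference@biotype)[reference@biotype %in% c("mRNA", "ncRNA")]
    for (tx in mr) {
      n <- min(sitesPerMrna, lens[tx])
      p <- sort(sample(seq_len(lens[tx]), n))
      s <- stats::runif(n, 0.2, 0.9)
      sites[[tx]] <- data.frame(transcript = tx, pos = p, mod = "mod",
                                s_control = s, s_stress = s)
    }

    modname <- c(Q = "Q", Mnm = "mnm5s2U", cmo5U = "cmo5U", other = "mod")
    tr <- reference@trna
    for (i in seq_len(nrow(tr))) {
      s0 <- stats::runif(1, 0.3, 0.6)
      responsive <- tr$pathway[i] %in% c("Q", "Mnm")
      s1 <- if (responsive) min(1, s0 + config@stressShift) else s0
      sites[[tr$transcript[i]]] <- data.frame(
        transcript = tr$transcript[i], pos = tr$anticodon_start[i],
        mod = modname[[tr$pathway[i]]], s_control = s0, s_stress = s1)
    }

    tab <- do.call(rbind, unname(sites))
    control <- setdiff(config@conditions, config@ivtLabel)[1]
    out <- do.call(rbind, lapply(config@conditions, function(cond) {
      s <- if (cond == config@ivtLabel) 0 else
        if (cond == control) tab$s_control else tab$s_stress
      data.frame(transcript = tab$transcript, pos = tab$pos, mod = tab$mod,
                 condition = cond, stoichiometry = s)
    }))
    rownames(out) <- NULL
    DataFrame(out)
  })
}

# -- read simulation ---------------------------------------------------------

# One simulated sample: per read, per position, an error event occurs with
# probability eBase (+ deltaMod on molecules drawn as modified); the event
# is a mismatch, single-base deletion, or single-base insertion-after, in
# the configured proportions. Boundary positions (first/last) only take
# mismatches so the CIGAR never starts or ends in D/I.
simulateSampleReads <- function(refChars, L, sitePos, siteStoich, n, config) {
  p <- matrix(config@eBase, n, L)
  for (j in seq_along(sitePos)) {
    modified <- stats::runif(n) < siteStoich[j]
    p[modified, sitePos[j]] <- config@eBase + config@deltaMod
  }
  err <- matrix(stats::runif(n * L), n, L) < p
  type <- matrix(0L, n, L)
  ne <- sum(err)
  if (ne)
    type[err] <- sample(1:3, ne, replace = TRUE, prob = config@errorMix)
  if (L >= 1) type[type[, 1] > 1L, 1] <- 1L
  if (L >= 2) type[type[, L] > 1L, L] <- 1L

  qs <- pmin(41L, pmax(2L, round(stats::rnorm(n, config@meanQ, config@qSd))))
  seqs <- character(n); cigars <- character(n); quals <- character(n)
  for (i in seq_len(n)) {
    ti <- type[i, ]
    sub <- which(ti == 1L); del <- which(ti == 2L); ins <- which(ti == 3L)
    x <- refChars
    if (length(sub))
      x[sub] <- vapply(refChars[sub],
                       function(b) sample(BASES[BASES != b], 1L), "")
    if (length(ins))
      x[ins] <- paste0(x[ins], sample(BASES, length(ins), replace = TRUE))
    if (length(del)) x <- x[-del]
    seqs[i] <- paste(x, collapse = "")
    cigars[i] <- buildCigar(L, del, ins)
    quals[i] <- strrep(intToUtf8(qs[i] + 33L), nchar(seqs[i]))
  }
  list(seq = seqs, cigar = cigars, qual = quals)
}

# CIGAR for a read spanning reference 1..L with 1-nt deletions at `del`
# and 1-nt insertions opening after `ins`.
buildCigar <- function(L, del, ins) {
  if (!length(del) && !length(ins)) return(paste0(L, "M"))
  ev <- c(del, ins + 0.25)           # order D-at-p before I-after-p
  o <- order(ev); ev <- ev[o]
  isIns <- ev %% 1 != 0
  lens <- integer(0); ops <- character(0)
  prev <- 0
  for (k in seq_along(ev)) {
    pp <- floor(ev[k])
    mlen <- if (isIns[k]) pp - prev else pp - prev - 1L
    if (mlen > 0) { lens <- c(lens, mlen); ops <- c(ops, "M") }
    lens <- c(lens, 1L); ops <- c(ops, if (isIns[k]) "I" else "D")
    prev <- pp
  }
  if (prev < L) { lens <- c(lens, L - prev); ops <- c(ops, "M") }
  # merge adjacent identical ops (e.g. consecutive 1-nt deletions)
  keep <- c(TRUE, ops[-1] != ops[-length(ops)])
  grp <- cumsum(keep)
  paste0(tapply(lens, grp, sum), ops[keep], collapse = "")
}

#' Simulate aligned reads with modification-dependent basecalling error
#'
#' Writes one coordinate-sorted, indexed BAM per (condition, replicate),
#' containing full-length reads over each selected transcript. The
#' expected error proportion at a site with stoichiometry \eqn{s} is
#' \eqn{e_{base} + s\,\delta_{mod}}; every other position errs at
#' \eqn{e_{base}}. Per-read qualities are constant strings drawn from the
#' configured read-quality model so quality filters can be exercised.
#'
#' @param reference a [SyntheticReference].
#' @param truth the site table from [sampleTruth()].
#' @param config a [SyntheticConfig].
#' @param dir output directory (created if missing).
#' @param conditions,replicates subset of the layout to simulate
#'   (defaults: all configured conditions and replicates).
#' @param transcripts transcripts to cover (default: all in the reference).
#' @return data.frame with condition, replicate and the BAM path per sample.
#' @export
simulateAlignments <- function(reference, truth, config, dir,
                               conditions = config@conditions,
                               replicates = seq_len(config@replicates),
                               transcripts = names(reference@sequences)) {
  stopifnot(is(reference, "SyntheticReference"))
  if (config@coverage <= 0L) stop("coverage must be positive")
  bad <- setdiff(unique(truth$transcript), names(reference@sequences))
  if (length(bad))
    stop("truth names transcripts absent from the reference: ",
         paste(bad, collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  lens <- BiocGenerics::width(reference@sequences)
  names(lens) <- names(reference@sequences)
  chars <- lapply(transcripts,
                  function(tx) strsplit(as.character(
                    reference@sequences[[tx]]), "")[[1]])
  names(chars) <- transcripts

  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", transcripts,
                   as.integer(lens[transcripts])))

  out <- list()
  for (cond in conditions) {
    for (rep_i in replicates) {
      lines <- hdr
      withSeed(deriveSeed(config@seed, paste("align", cond, rep_i)), {
        for (tx in transcripts) {
          st <- truth[truth$transcript == tx & truth$condition == cond, ,
                      drop = FALSE]
          sim <- simulateSampleReads(chars[[tx]], lens[[tx]], st$pos,
                                     st$stoichiometry, config@coverage,
                                     config)
          lines <- c(lines, sprintf(
            "%s\t0\t%s\t1\t60\t%s\t*\t0\t0\t%s\t%s",
            sprintf("r_%s_%d_%s_%04d", cond, rep_i, tx,
                    seq_len(config@coverage)),
            tx, sim$cigar, sim$seq, sim$qual))
        }
      })
      sam <- file.path(dir, sprintf("%s_rep%d.sam", cond, rep_i))
      writeLines(lines, sam)
      bam <- Rsamtools::asBam(sam, file.path(dir,
                                             sprintf("%s_rep%d", cond, rep_i)),
                              overwrite = TRUE, indexDestination = TRUE)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, replicate = rep_i, path = bam,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate pre-tRNA read lengths with maturation-coupled modification
#'
#' Draws, per tRNA, a two-component read population: mature reads
#' (70-100 nt by default) and immature, leader/trailer-bearing reads
#' (100-500 nt). Each tRNA has a fixed mature-read mixture weight drawn
#' from `matureWeightRange`. A read carries the anticodon modification
#' with probability equal to the site stoichiometry, multiplied by
#' `immaturityFactor` on immature reads — a factor below 1 creates the
#' negative dependence between read length and anticodon modification
#' level that the maturity analysis is designed to recover; a factor of 1
#' makes length and modification state independent.
#'
#' @inheritParams simulateAlignments
#' @return data.frame with transcript, condition, replicate, length (nt),
#'   mature and modified flags, one row per read.
#' @export
simulatePretrnaLengths <- function(reference, truth, config,
                                   conditions = setdiff(config@conditions,
                                                        config@ivtLabel),
                                   replicates = seq_len(config@replicates)) {
  tr <- reference@trna
  if (!nrow(tr)) stop("reference contains no tRNAs")
  w <- vapply(tr$transcript, function(tx)
    withSeed(deriveSeed(config@seed, paste0("maturity_", tx)),
             stats::runif(1, config@matureWeightRange[1],
                          config@matureWeightRange[2])), numeric(1))

  out <- list()
  for (cond in conditions) {
    for (rep_i in replicates) {
      withSeed(deriveSeed(config@seed, paste("lengths", cond, rep_i)), {
        for (i in seq_len(nrow(tr))) {
          tx <- tr$transcript[i]
          s <- truth$stoichiometry[truth$transcript == tx &
                                   truth$pos == tr$anticodon_start[i] &
                                   truth$condition == cond]
          s <- if (length(s)) s[1] else 0
          n <- config@coverage
          mature <- stats::runif(n) < w[[tx]]
          len <- integer(n)
          len[mature] <- round(stats::runif(sum(mature),
                                            config@matureRange[1],
                                            config@matureRange[2]))
          len[!mature] <- round(stats::runif(sum(!mature),
                                             config@immatureRange[1],
                                             config@immatureRange[2]))
          pmod <- ifelse(mature, s, s * config@immaturityFactor)
          modified <- stats::runif(n) < pmod
          out[[length(out) + 1L]] <- data.frame(
            transcript = tx, condition = cond, replicate = rep_i,
            length = len, mature = mature, modified = modified,
            stringsAsFactors = FALSE)
        }
      })
    }
  }
  do.call(rbind, out)
}

#' Generate a synthetic translational-efficiency table
#'
#' Assigns every mRNA a TE log-fold-change and class (increased /
#' decreased / unchanged). With `teEffect > 0`, transcripts rich in
#' modification-dependent codons are preferentially assigned to the
#' "increased" class (class odds scale with `exp(teEffect * z)` where z is
#' the standardized codon score), giving the downstream rank-sum
#' comparison a known effect size; with `teEffect = 0` classes are drawn
#' independently of codon content.
#'
#' @inheritParams simulateAlignments
#' @param sets codon-set table used for scoring (default [codonSetTable()]).
#' @return data.frame with transcript, te_lfc, class, codon_abundance.
#' @export
generateTeTable <- function(reference, config, sets = codonSetTable()) {
  mr <- names(which(reference@biotype == "mRNA"))
  if (!length(mr))
    return(data.frame(transcript = character(), te_lfc = numeric(),
                      class = character(), codon_abundance = numeric()))
  cds <- extractCds(reference)
  sc <- countCodons(cds, sets)
  ab <- sc$abundance[match(mr, sc$transcript)]
  z <- if (all(is.na(ab)) || stats::sd(ab, na.rm = TRUE) == 0)
    rep(0, length(ab)) else as.numeric(scale(ab))
  z[is.na(z)] <- 0

  withSeed(deriveSeed(config@seed, "te"), {
    cls <- vapply(z, function(zi) {
      wts <- c(increased = exp(config@teEffect * zi),
               decreased = exp(-config@teEffect * zi),
               unchanged = 1)
      sample(names(wts), 1, prob = wts / sum(wts))
    }, "")
    mu <- c(increased = 1, decreased = -1, unchanged = 0)
    lfc <- stats::rnorm(length(mr), mu[cls], 0.3)
    data.frame(transcript = mr, te_lfc = lfc, class = unname(cls),
               codon_abundance = ab, stringsAsFactors = FALSE)
  })
}

#' Extract CDS sequences from a synthetic reference
#'
#' @param reference a [SyntheticReference].
#' @return [Biostrings::DNAStringSet] of in-frame CDS sequences, one per
#'   mRNA.
#' @export
extractCds <- function(reference) {
  u <- reference@utr
  if (!nrow(u)) return(Biostrings::DNAStringSet())
  cds <- Biostrings::subseq(reference@sequences[u$transcript],
                            start = u$utr5_len + 1L,
                            width = u$cds_len)
  names(cds) <- u$transcript
  cds
}

#' Write reference / truth artifacts
#'
#' @param reference a [SyntheticReference]; `truth` a table from
#'   [sampleTruth()].
#' @param path output path (FASTA or TSV).
#' @return the path, invisibly.
#' @export
writeReferenceFasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference@sequences, path)
  invisible(path)
}

#' @rdname writeReferenceFasta
#' @param truth truth table.
#' @export
writeTruthTable <- function(truth, path) {
  utils::write.table(as.data.frame(truth), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
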