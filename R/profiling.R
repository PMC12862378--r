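#' @include AllClasses.R utils.R
NULL

#' Read direct-RNA alignment records
#'
#' Loads every record (including unmapped and secondary ones, so the
#' filter report can account for them) from a BAM or SAM file into a
#' [DrsAlignments] object. SAM input is converted on the fly with
#' [Rsamtools::asBam()].
#'
#' @param file path to a BAM or SAM file.
#' @return a [DrsAlignments].
#' @export
readAlignments <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile()
    file <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "seq", "qual"),
    flag = Rsamtools::scanBamFlag())
  b <- Rsamtools::scanBam(file, param = p)[[1]]
  reads <- DataFrame(
    qname = b$qname,
    flag = b$flag,
    rname = as.character(b$rname),
    strand = as.character(b$strand),
    pos = b$pos,
    mapq = b$mapq,
    cigar = b$cigar,
    seq = as.character(b$seq),
    qual = as.character(b$qual))
  new("DrsAlignments", reads = reads, source = file,
      filterReport = DataFrame(reason = character(), n = integer()))
}

#' Filter reads by mapping state and mean read quality
#'
#' Applies the read-level filters used before error profiling: drop
#' unmapped reads, secondary and supplementary (chimeric) alignments,
#' reads without quality strings, reverse-strand alignments (direct RNA
#' reads are sense-strand in transcript space; their presence is reported
#' with a warning), and reads whose mean quality is not strictly greater
#' than the class threshold — Q > 9 for mRNA-enriched ("mRNAe") samples,
#' Q > 5 for tRNA-seq samples.
#'
#' @param aln a [DrsAlignments].
#' @param sampleClass "mRNAe" or "tRNAseq"; sets the default `minMeanQ`.
#' @param minMeanQ exclusive mean-quality threshold; overrides the class
#'   default.
#' @param keepPrimaryOnly drop secondary/supplementary alignments
#'   (default TRUE).
#' @return the filtered [DrsAlignments]; `filterReport(x)` tabulates kept
#'   and dropped reads by reason.
#' @export
filterReads <- function(aln, sampleClass = c("mRNAe", "tRNAseq"),
                        minMeanQ = NULL, keepPrimaryOnly = TRUE) {
  stopifnot(is(aln, "DrsAlignments"))
  sampleClass <- match.arg(sampleClass)
  if (is.null(minMeanQ))
    minMeanQ <- if (sampleClass == "mRNAe") 9 else 5
  r <- aln@reads
  n <- nrow(r)
  reason <- rep(NA_character_, n)

  unmapped <- bitwAnd(r$flag, 4L) != 0L
  reason[is.na(reason) & unmapped] <- "unmapped"
  if (keepPrimaryOnly) {
    sec <- bitwAnd(r$flag, 256L) != 0L | bitwAnd(r$flag, 2048L) != 0L
    reason[is.na(reason) & sec] <- "secondary_or_chimeric"
  }
  rev <- !is.na(r$strand) & r$strand == "-"
  if (any(is.na(reason) & rev)) {
    warning(sum(is.na(reason) & rev),
            " reverse-strand alignment(s) dropped")
    reason[is.na(reason) & rev] <- "reverse_strand"
  }
  noq <- is.na(r$qual) | r$qual == "*" | !nzchar(r$qual)
  if (any(is.na(reason) & noq)) {
    warning(sum(is.na(reason) & noq), " read(s) without quality strings")
    reason[is.na(reason) & noq] <- "no_quality"
  }
  mq <- meanReadQuality(r$qual)
  lowq <- !is.na(mq) & mq <= minMeanQ
  reason[is.na(reason) & lowq] <- "low_quality"

  keep <- is.na(reason)
  reason[keep] <- "kept"
  tab <- table(factor(reason, levels = c("kept", "unmapped",
                                         "secondary_or_chimeric",
                                         "reverse_strand", "no_quality",
                                         "low_quality")))
  new("DrsAlignments", reads = r[keep, , drop = FALSE], source = aln@source,
      filterReport = DataFrame(reason = names(tab), n = as.integer(tab)))
}

#' Per-position basecalling-error profile from alignments
#'
#' For every reference position, counts the reads whose alignment spans it
#' (by match, mismatch or deletion; soft-clipped bases are ignored) and
#' the reads exhibiting a basecalling discrepancy there. A read
#' contributes at most one error per position: a substitution, a deletion
#' spanning the position, or an insertion opening immediately 3' of it
#' (charged to the 5'-adjacent aligned position). BCError is the ratio of
#' the two counts; positions covered by fewer than `minDepth` reads are
#' masked.
#'
#' @param aln a (filtered) [DrsAlignments].
#' @param reference a named [Biostrings::DNAStringSet] or FASTA path.
#' @param minDepth minimum coverage for an unmasked position (default 5).
#' @param sample,sampleClass labels stored on the profile.
#' @return a [PileupProfile] covering every reference transcript.
#' @export
computeBCError <- function(aln, reference, minDepth = 5,
                           sample = "sample",
                           sampleClass = c("mRNAe", "tRNAseq")) {
  stopifnot(is(aln, "DrsAlignments"))
  sampleClass <- match.arg(sampleClass)
  if (is.character(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  names(reference) <- sub("\\s.*$", "", names(reference))
  r <- aln@reads
  mapped <- r[!is.na(r$pos) & bitwAnd(r$flag, 4L) == 0L, , drop = FALSE]
  bad <- setdiff(unique(mapped$rname), names(reference))
  if (length(bad))
    stop("alignment references transcript(s) absent from the FASTA: ",
         paste(bad, collapse = ", "))

  pieces <- lapply(names(reference), function(tx) {
    L <- BiocGenerics::width(reference[tx])
    idx <- which(mapped$rname == tx)
    if (!length(idx)) {
      return(DataFrame(transcript = tx, pos = seq_len(L),
                       coverage = 0L, error_count = 0L,
                       bcerror = NA_real_, masked = TRUE))
    }
    cig <- mapped$cigar[idx]
    pos <- mapped$pos[idx]
    laid <- GenomicAlignments::sequenceLayer(
      Biostrings::DNAStringSet(mapped$seq[idx]), cig)
    wid <- BiocGenerics::width(laid)
    left <- Biostrings::DNAStringSet(strrep("+", pos - 1L))
    right <- Biostrings::DNAStringSet(strrep("+", L - (pos - 1L) - wid))
    mat <- as.matrix(Biostrings::xscat(left, laid, right))
    refv <- strsplit(as.character(reference[[tx]]), "")[[1]]
    covm <- mat != "+"
    errm <- covm & (mat != matrix(refv, nrow(mat), L, byrow = TRUE))

    insr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cig, pos = pos, ops = "I")
    nin <- lengths(insr)
    if (any(nin > 0)) {
      row <- rep(seq_along(idx), nin)
      at <- unlist(IRanges::start(insr)) - 1L  # 5'-adjacent ref position
      ok <- at >= 1L & at <= L
      ok[ok] <- covm[cbind(row[ok], at[ok])]
      if (any(ok)) errm[cbind(row[ok], at[ok])] <- TRUE
    }

    cov <- colSums(covm)
    err <- colSums(errm)
    DataFrame(transcript = tx, pos = seq_len(L),
              coverage = as.integer(cov), error_count = as.integer(err),
              bcerror = ifelse(cov > 0, err / cov, NA_real_),
              masked = cov < minDepth)
  })
  new("PileupProfile", sample = sample, sampleClass = sampleClass,
      minDepth = as.numeric(minDepth), data = do.call(rbind, pieces))
}

#' Pool replicate profiles by count
#'
#' Sums coverage and error counts positionwise across profiles of the same
#' transcripts and recomputes BCError from the pooled counts (count
#' pooling, not averaging of proportions), as when biological replicates
#' are combined into one sample. Masking is re-evaluated on the pooled
#' coverage.
#'
#' @param profiles a list of [PileupProfile] objects over identical
#'   transcripts and lengths.
#' @param sample label for the pooled profile.
#' @return a [PileupProfile].
#' @export
poolProfiles <- function(profiles, sample = "pooled") {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, TRUE, "PileupProfile")))
  key <- function(p) paste(p@data$transcript, p@data$pos)
  d0 <- profiles[[1]]@data
  cov <- d0$coverage; err <- d0$error_count
  for (p in profiles[-1]) {
    if (!identical(key(p), key(profiles[[1]])))
      stop("profiles must cover identical transcripts and lengths")
    cov <- cov + p@data$coverage
    err <- err + p@data$error_count
  }
  minDepth <- profiles[[1]]@minDepth
  new("PileupProfile", sample = sample,
      sampleClass = profiles[[1]]@sampleClass, minDepth = minDepth,
      data = DataFrame(transcript = d0$transcript, pos = d0$pos,
                       coverage = cov, error_count = err,
                       bcerror = ifelse(cov > 0, err / cov, NA_real_),
                       masked = cov < minDepth))
}

#' Read-length table from alignments
#'
#' One record per retained read with its query length (sequence length as
#' stored, including soft-clipped bases). Optionally trims an adapter
#' sequence found at either read end before measuring.
#'
#' @param aln a (filtered) [DrsAlignments].
#' @param condition,replicate labels attached to every record.
#' @param adapter optional adapter sequence (character); when present at a
#'   read end it is removed before the length is taken.
#' @return data.frame with transcript, condition, replicate, length.
#' @export
readLengthTable <- function(aln, condition = "sample", replicate = 1L,
                            adapter = NULL) {
  stopifnot(is(aln, "DrsAlignments"))
  r <- aln@reads
  if (!nrow(r))
    return(data.frame(transcript = character(), condition = character(),
                      replicate = integer(), length = integer()))
  s <- r$seq
  if (!is.null(adapter) && nzchar(adapter)) {
    al <- nchar(adapter)
    pre <- startsWith(s, adapter)
    s[pre] <- substring(s[pre], al + 1L)
    post <- endsWith(s, adapter)
    s[post] <- substring(s[post], 1L, nchar(s[post]) - al)
  }
  len <- nchar(s)
  if (any(len <= 0L)) {
    warning("dropping ", sum(len <= 0L), " read(s) with no sequence left")
  }
  keep <- len > 0L
  data.frame(transcript = r$rname[keep], condition = condition,
             replicate = replicate, length = len[keep],
             stringsAsFactors = FALSE)
}
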