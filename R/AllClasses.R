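#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- isSingleNumber isSingleString
NULL

#' Configuration for the synthetic epitranscriptome generator
#'
#' Holds every tunable of the synthetic-data module: reference composition,
#' the basecalling-error model (baseline error rate and the error boost a
#' modified nucleotide adds), sequencing depth, the condition/replicate
#' layout, per-read quality model, and the pre-tRNA read-length mixture.
#'
#' The error model is molecule-level: a read drawn from a site with
#' stoichiometry \eqn{s} is modified with probability \eqn{s}; modified
#' molecules basecall erroneously at that site with probability
#' \eqn{e_{base} + \delta_{mod}}, unmodified ones with \eqn{e_{base}}.
#' The expected per-position error proportion is therefore
#' \eqn{e_{base} + s\,\delta_{mod}}, which is what makes the differential
#' error an unbiased stoichiometry estimator.
#'
#' @slot seed integer master seed; per-(condition, replicate) substreams are
#'   derived from it so adding a replicate does not perturb the others.
#' @slot nMrna,nTrna,nNcrna counts of mRNA, tRNA and ncRNA transcripts.
#' @slot rrnaLengths named numeric, one rRNA transcript per entry
#'   (defaults: 16S 1542 nt, 23S 2904 nt).
#' @slot eBase baseline per-position basecalling error proportion.
#' @slot deltaMod additional error proportion on a modified molecule.
#' @slot coverage reads per transcript per replicate.
#' @slot conditions character vector of condition labels.
#' @slot ivtLabel which condition is the unmodified IVT control.
#' @slot replicates biological replicates per condition (>= 2).
#' @slot errorMix proportions of mismatch/deletion/insertion among error
#'   events (sums to 1).
#' @slot meanQ,qSd per-read mean quality model (Phred scale).
#' @slot matureRange,immatureRange read-length ranges (nt) for mature and
#'   immature pre-tRNA molecules.
#' @slot matureWeightRange range from which each tRNA's mature-read mixture
#'   weight is drawn (a fixed property of the tRNA).
#' @slot immaturityFactor multiplier (< 1 couples) on the anticodon
#'   modification probability of immature reads.
#' @slot stressShift additive stoichiometry shift at stress-responsive
#'   wobble sites under the stress condition.
#' @slot teEffect enrichment effect linking codon scores to the synthetic
#'   translational-efficiency classes.
#' @export
setClass("SyntheticConfig",
  representation(
    seed = "integer",
    nMrna = "integer", nTrna = "integer", nNcrna = "integer",
    rrnaLengths = "numeric",
    eBase = "numeric", deltaMod = "numeric",
    coverage = "integer",
    conditions = "character", ivtLabel = "character", replicates = "integer",
    errorMix = "numeric",
    meanQ = "numeric", qSd = "numeric",
    matureRange = "numeric", immatureRange = "numeric",
    matureWeightRange = "numeric",
    immaturityFactor = "numeric",
    stressShift = "numeric",
    teEffect = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@eBase < 0 || object@eBase >= 1)
    msg <- c(msg, "eBase must lie in [0, 1)")
  if (object@deltaMod <= 0 || object@deltaMod > 1)
    msg <- c(msg, "deltaMod must lie in (0, 1]")
  if (object@eBase + object@deltaMod > 1)
    msg <- c(msg, "eBase + deltaMod must not exceed 1")
  if (object@coverage < 1L)
    msg <- c(msg, "coverage must be a positive integer")
  if (object@replicates < 2L)
    msg <- c(msg, "every non-IVT condition needs >= 2 replicates")
  if (!(object@ivtLabel %in% object@conditions))
    msg <- c(msg, "conditions must include the IVT label")
  if (length(object@errorMix) != 3L ||
      abs(sum(object@errorMix) - 1) > 1e-8 || any(object@errorMix < 0))
    msg <- c(msg, "errorMix must be 3 non-negative proportions summing to 1")
  if (length(object@matureWeightRange) != 2L ||
      any(object@matureWeightRange < 0) || any(object@matureWeightRange > 1) ||
      diff(object@matureWeightRange) < 0)
    msg <- c(msg, "matureWeightRange must be an increasing range within [0, 1]")
  if (object@immaturityFactor < 0 || object@immaturityFactor > 1)
    msg <- c(msg, "immaturityFactor must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Synthetic transcriptome reference
#'
#' Transcript sequences plus the structural metadata downstream stages
#' need: a biotype per transcript, 5'UTR/CDS/3'UTR bounds for mRNAs, and
#' anticodon/leader/trailer geometry for tRNAs (the stored tRNA sequence is
#' the mature molecule; leader and trailer lengths describe the unprocessed
#' precursor).
#'
#' @slot sequences [Biostrings::DNAStringSet] of transcript sequences
#'   (RNA stored in the DNA alphabet, U as T).
#' @slot biotype named character: mRNA, rRNA, tRNA or ncRNA per transcript.
#' @slot utr [S4Vectors::DataFrame] with transcript, utr5_len, cds_len,
#'   utr3_len for mRNAs.
#' @slot trna [S4Vectors::DataFrame] with transcript, anticodon_start
#'   (1-based in mature coordinates), leader_len, trailer_len, pathway.
#' @export
setClass("SyntheticReference",
  representation(
    sequences = "DNAStringSet",
    biotype = "character",
    utr = "DataFrame",
    trna = "DataFrame"
  )
)

setValidity("SyntheticReference", function(object) {
  msg <- character()
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "sequences must carry unique names")
  if (!identical(sort(nm), sort(names(object@biotype))))
    msg <- c(msg, "biotype must be named for every transcript")
  if (nrow(object@utr)) {
    len <- BiocGenerics::width(object@sequences)[
      match(object@utr$transcript, nm)]
    if (any(object@utr$cds_len %% 3 != 0))
      msg <- c(msg, "CDS lengths must be divisible by 3")
    if (any(object@utr$utr5_len + object@utr$cds_len +
            object@utr$utr3_len != len))
      msg <- c(msg, "UTR5 + CDS + UTR3 lengths must equal transcript length")
  }
  if (nrow(object@trna)) {
    len <- BiocGenerics::width(object@sequences)[
      match(object@trna$transcript, nm)]
    if (any(object@trna$anticodon_start + 2L > len))
      msg <- c(msg, "anticodon must fit inside the mature tRNA")
  }
  if (length(msg)) msg else TRUE
})

#' Parsed direct-RNA alignments
#'
#' A light container over one sample's alignment records (from BAM or SAM),
#' keeping exactly the fields the error-profiling stage consumes. After
#' [filterReads()] the `filterReport` slot records how many reads each
#' filter removed.
#'
#' @slot reads [S4Vectors::DataFrame] with columns qname, flag, rname,
#'   strand, pos, mapq, cigar, seq, qual.
#' @slot source path the records were read from.
#' @slot filterReport [S4Vectors::DataFrame] (reason, n) filled by
#'   [filterReads()].
#' @export
setClass("DrsAlignments",
  representation(
    reads = "DataFrame",
    source = "character",
    filterReport = "DataFrame"
  )
)

#' Per-position basecalling-error profile
#'
#' For every transcript position: the number of spanning reads (coverage),
#' the number of reads showing a basecalling discrepancy there
#' (substitution, spanning deletion, or insertion opening immediately
#' 3' of the position), and their ratio BCError. Positions with coverage
#' below `minDepth` are masked.
#'
#' @slot sample sample label.
#' @slot sampleClass "mRNAe" or "tRNAseq" (controls the default read
#'   quality filter upstream).
#' @slot minDepth minimum coverage for an unmasked position.
#' @slot data [S4Vectors::DataFrame] with transcript, pos (1-based),
#'   coverage, error_count, bcerror, masked.
#' @export
setClass("PileupProfile",
  representation(
    sample = "character",
    sampleClass = "character",
    minDepth = "numeric",
    data = "DataFrame"
  )
)

setValidity("PileupProfile", function(object) {
  d <- object@data
  msg <- character()
  need <- c("transcript", "pos", "coverage", "error_count", "bcerror", "masked")
  if (!all(need %in% colnames(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  if (any(d$error_count > d$coverage))
    msg <- c(msg, "error_count must not exceed coverage")
  ok <- !d$masked
  if (any(ok & (d$bcerror < 0 | d$bcerror > 1)))
    msg <- c(msg, "BCError must lie in [0, 1] at unmasked positions")
  if (length(msg)) msg else TRUE
})

#' Differential basecalling-error profile
#'
#' Positionwise difference of BCError between two profiles
#' (delta = BCError_a - BCError_b) and its normalized form
#' delta / BCError_b. A position is masked wherever either input is
#' masked; the normalized value is additionally masked where the
#' denominator BCError_b is zero.
#'
#' @slot sampleA,sampleB the labels of the two inputs (a minus b).
#' @slot data [S4Vectors::DataFrame] with transcript, pos, delta,
#'   norm_delta, masked, norm_masked.
#' @export
setClass("DeltaProfile",
  representation(
    sampleA = "character",
    sampleB = "character",
    data = "DataFrame"
  )
)

setValidity("DeltaProfile", function(object) {
  d <- object@data
  need <- c("transcript", "pos", "delta", "norm_delta", "masked", "norm_masked")
  if (!all(need %in% colnames(d)))
    return(paste("data must have columns:", paste(need, collapse = ", ")))
  ok <- !d$masked
  if (any(abs(d$delta[ok]) > 1 + 1e-12))
    return("delta must lie in [-1, 1] at unmasked positions")
  TRUE
})

#' Threshold calibration against known modification sites
#'
#' Precision/recall/F1 of putative-site classification over a grid of
#' differential-error thresholds, evaluated against a curated table of
#' known modification positions, plus the chosen operating threshold.
#'
#' @slot grid data.frame with tau, tp, fp, fn, precision, recall, f1.
#' @slot tau the chosen threshold (F1-maximizing unless overridden).
#' @slot restriction "all" or "regions" (whether candidate positions were
#'   restricted to externally called regions).
#' @export
setClass("ThresholdCalibration",
  representation(
    grid = "data.frame",
    tau = "numeric",
    restriction = "character"
  )
)

setValidity("ThresholdCalibration", function(object) {
  g <- object@grid
  msg <- character()
  ok <- !is.na(g$precision)
  if (any(g$precision[ok] < 0 | g$precision[ok] > 1) ||
      any(g$recall < 0 | g$recall > 1))
    msg <- c(msg, "precision and recall must lie in [0, 1]")
  if (is.unsorted(g$tau))
    msg <- c(msg, "grid must be ascending in tau")
  if (any(diff(g$recall) > 1e-12))
    msg <- c(msg, "recall must be non-increasing along an ascending grid")
  if (length(msg)) msg else TRUE
})
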