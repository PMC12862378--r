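#' @include AllClasses.R
NULL

#' Accessors for epiDRS objects
#'
#' `profileData()` returns the per-position table of a [PileupProfile] or
#' [DeltaProfile]; `bcerror()` the BCError vector; `sampleName()` the sample
#' label; `transcripts()` the transcript names of a profile or reference;
#' `referenceSequences()` the [Biostrings::DNAStringSet] of a
#' [SyntheticReference]; `biotypes()` its biotype assignment;
#' `readRecords()` the alignment table of a [DrsAlignments];
#' `filterReport()` the per-reason drop counts filled by [filterReads()];
#' `calibrationGrid()` and `chosenThreshold()` the grid and operating
#' threshold of a [ThresholdCalibration].
#'
#' @param x an epiDRS object.
#' @name accessors
#' @aliases profileData bcerror sampleName transcripts referenceSequences
#'   biotypes readRecords filterReport calibrationGrid chosenThreshold
NULL

#' @rdname accessors
#' @export
setGeneric("profileData", function(x) standardGeneric("profileData"))

#' @rdname accessors
#' @export
setGeneric("bcerror", function(x) standardGeneric("bcerror"))

#' @rdname accessors
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @rdname accessors
#' @export
setGeneric("transcripts", function(x) standardGeneric("transcripts"))

#' @rdname accessors
#' @export
setGeneric("referenceSequences",
           function(x) standardGeneric("referenceSequences"))

#' @rdname accessors
#' @export
setGeneric("biotypes", function(x) standardGeneric("biotypes"))

#' @rdname accessors
#' @export
setGeneric("readRecords", function(x) standardGeneric("readRecords"))

#' @rdname accessors
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname accessors
#' @export
setGeneric("calibrationGrid", function(x) standardGeneric("calibrationGrid"))

#' @rdname accessors
#' @export
setGeneric("chosenThreshold", function(x) standardGeneric("chosenThreshold"))

setMethod("profileData", "PileupProfile", function(x) x@data)
setMethod("profileData", "DeltaProfile", function(x) x@data)
setMethod("bcerror", "PileupProfile", function(x) x@data$bcerror)
setMethod("sampleName", "PileupProfile", function(x) x@sample)
setMethod("transcripts", "PileupProfile",
          function(x) unique(as.character(x@data$transcript)))
setMethod("transcripts", "SyntheticReference",
          function(x) names(x@sequences))
setMethod("referenceSequences", "SyntheticReference", function(x) x@sequences)
setMethod("biotypes", "SyntheticReference", function(x) x@biotype)
setMethod("readRecords", "DrsAlignments", function(x) x@reads)
setMethod("filterReport", "DrsAlignments", function(x) x@filterReport)
setMethod("calibrationGrid", "ThresholdCalibration", function(x) x@grid)
setMethod("chosenThreshold", "ThresholdCalibration", function(x) x@tau)

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat("  seed:", object@seed, "\n")
  cat("  transcripts: ", object@nMrna, " mRNA, ", length(object@rrnaLengths),
      " rRNA, ", object@nTrna, " tRNA, ", object@nNcrna, " ncRNA\n", sep = "")
  cat("  error model: eBase=", object@eBase, ", deltaMod=", object@deltaMod,
      ", mix(M/D/I)=", paste(object@errorMix, collapse = "/"), "\n", sep = "")
  cat("  coverage:", object@coverage, "reads/transcript/replicate\n")
  cat("  conditions:", paste(object@conditions, collapse = ", "),
      sprintf("(IVT = %s, %d replicates)\n", object@ivtLabel,
              object@replicates))
})

setMethod("show", "SyntheticReference", function(object) {
  tab <- table(object@biotype)
  cat("SyntheticReference with", length(object@sequences), "transcripts (",
      paste(sprintf("%s: %d", names(tab), as.integer(tab)), collapse = ", "),
      ")\n")
})

setMethod("show", "DrsAlignments", function(object) {
  cat("DrsAlignments:", nrow(object@reads), "records from",
      object@source, "\n")
  if (nrow(object@filterReport)) {
    cat("  filter report:\n")
    for (i in seq_len(nrow(object@filterReport)))
      cat(sprintf("    %-14s %d\n", object@filterReport$reason[i],
                  object@filterReport$n[i]))
  }
})

setMethod("show", "PileupProfile", function(object) {
  d <- object@data
  cat("PileupProfile '", object@sample, "' (", object@sampleClass, "): ",
      length(unique(d$transcript)), " transcripts, ", nrow(d),
      " positions (", sum(d$masked), " masked at depth < ",
      object@minDepth, ")\n", sep = "")
})

setMethod("show", "DeltaProfile", function(object) {
  d <- object@data
  cat("DeltaProfile ", object@sampleA, " - ", object@sampleB, ": ",
      nrow(d), " positions (", sum(d$masked), " masked)\n", sep = "")
})

setMethod("show", "ThresholdCalibration", function(object) {
  i <- which.min(abs(object@grid$tau - object@tau))
  cat("ThresholdCalibration over", nrow(object@grid), "thresholds",
      sprintf("(restriction: %s)\n", object@restriction))
  cat(sprintf("  chosen tau = %g: precision %.3f, recall %.3f, F1 %.3f\n",
              object@tau, object@grid$precision[i], object@grid$recall[i],
              object@grid$f1[i]))
})
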