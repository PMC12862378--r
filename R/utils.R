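#' @include AllClasses.R
NULL

# Deterministic 32-bit sub-seed from a master seed and a stream label, so
# each (condition, replicate) gets an independent stream and adding one
# stream never perturbs another.
deriveSeed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(paste0(label))) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Mean read quality on the Phred scale
#'
#' Converts a vector of per-base Phred qualities to the read-level quality
#' used for filtering: the Phred transform of the mean per-base error
#' probability, \eqn{-10 \log_{10}(\overline{10^{-Q/10}})}. This is the
#' convention of read-QV filters on nanopore data; it equals the plain mean
#' when all bases share one quality.
#'
#' @param qual a character vector of Phred+33 quality strings.
#' @return numeric vector of read-level mean qualities; `NA` for empty or
#'   missing ("*") quality strings.
#' @export
meanReadQuality <- function(qual) {
  vapply(qual, function(q) {
    if (is.na(q) || q == "*" || !nzchar(q)) return(NA_real_)
    p <- 10^(-(utf8ToInt(q) - 33L) / 10)
    -10 * log10(mean(p))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write / read per-position profile tables
#'
#' Profiles are exchanged as plain TSV with 1-based positions, matching the
#' coordinate convention of rRNA site nomenclature (e.g. C1402).
#'
#' @param profile a [PileupProfile].
#' @param path output TSV path.
#' @return `writeProfile` returns `path` invisibly; `readProfile` returns a
#'   [PileupProfile].
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "PileupProfile"))
  d <- as.data.frame(profileData(profile))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfile
#' @param sample,sampleClass,minDepth metadata to attach on read-back.
#' @export
readProfile <- function(path, sample = basename(path),
                        sampleClass = "mRNAe", minDepth = 5) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  new("PileupProfile", sample = sample, sampleClass = sampleClass,
      minDepth = as.numeric(minDepth), data = DataFrame(d))
}

# Restriction regions: accept a BED path, a GRanges, or NULL.
asRegionRanges <- function(regions) {
  if (is.null(regions)) return(NULL)
  if (is.character(regions)) regions <- rtracklayer::import(regions)
  if (!is(regions, "GRanges"))
    stop("regions must be a BED file path or a GRanges object")
  regions
}

# TRUE for each (transcript, pos) that falls inside at least one region.
inRegions <- function(transcript, pos, regions) {
  gr <- GenomicRanges::GRanges(transcript, IRanges::IRanges(pos, pos))
  IRanges::overlapsAny(gr, regions)
}
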