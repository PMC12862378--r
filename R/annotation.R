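#' @include AllClasses.R utils.R
NULL

#' Transcript annotation table
#'
#' Builds the per-transcript annotation used to place putative sites into
#' transcript regions. Each mRNA is partitioned into 5'UTR / CDS / 3'UTR
#' (1-based closed intervals); rRNA, tRNA and other non-coding transcripts
#' are labelled ncRNA territory.
#'
#' @param reference a [SyntheticReference], or NULL when building from
#'   files.
#' @param gff optional GFF3 path (1-based closed, as written by
#'   [writeAnnotationGFF3()]).
#' @param utr optional UTR TSV path with columns transcript, utr5_len,
#'   cds_len, utr3_len.
#' @return data.frame with transcript, biotype, length, utr5_start,
#'   utr5_end, cds_start, cds_end, utr3_start, utr3_end (NA where absent).
#' @export
transcriptAnnotation <- function(reference = NULL, gff = NULL, utr = NULL) {
  if (!is.null(reference)) {
    stopifnot(is(reference, "SyntheticReference"))
    len <- BiocGenerics::width(reference@sequences)
    tx <- names(reference@sequences)
    out <- data.frame(transcript = tx,
                      biotype = unname(reference@biotype[tx]),
                      length = len,
                      utr5_start = NA_integer_, utr5_end = NA_integer_,
                      cds_start = NA_integer_, cds_end = NA_integer_,
                      utr3_start = NA_integer_, utr3_end = NA_integer_,
                      stringsAsFactors = FALSE)
    u <- as.data.frame(reference@utr)
    i <- match(u$transcript, out$transcript)
    out$utr5_start[i] <- ifelse(u$utr5_len > 0, 1L, NA_integer_)
    out$utr5_end[i] <- ifelse(u$utr5_len > 0, u$utr5_len, NA_integer_)
    out$cds_start[i] <- u$utr5_len + 1L
    out$cds_end[i] <- u$utr5_len + u$cds_len
    out$utr3_start[i] <- ifelse(u$utr3_len > 0, u$utr5_len + u$cds_len + 1L,
                                NA_integer_)
    out$utr3_end[i] <- ifelse(u$utr3_len > 0,
                              u$utr5_len + u$cds_len + u$utr3_len,
                              NA_integer_)
    return(out)
  }
  if (is.null(gff) || is.null(utr))
    stop("provide either a reference object or both gff and utr paths")
  gr <- rtracklayer::import(gff)
  genes <- gr[gr$type == "gene"]
  ut <- utils::read.delim(utr, stringsAsFactors = FALSE)
  tx <- as.character(GenomicRanges::seqnames(genes))
  out <- data.frame(transcript = tx,
                    biotype = genes$biotype,
                    length = BiocGenerics::end(genes),
                    utr5_start = NA_integer_, utr5_end = NA_integer_,
                    cds_start = NA_integer_, cds_end = NA_integer_,
                    utr3_start = NA_integer_, utr3_end = NA_integer_,
                    stringsAsFactors = FALSE)
  i <- match(ut$transcript, out$transcript)
  out$utr5_start[i] <- ifelse(ut$utr5_len > 0, 1L, NA_integer_)
  out$utr5_end[i] <- ifelse(ut$utr5_len > 0, ut$utr5_len, NA_integer_)
  out$cds_start[i] <- ut$utr5_len + 1L
  out$cds_end[i] <- ut$utr5_len + ut$cds_len
  out$utr3_start[i] <- ifelse(ut$utr3_len > 0,
                              ut$utr5_len + ut$cds_len + 1L, NA_integer_)
  out$utr3_end[i] <- ifelse(ut$utr3_len > 0,
                            ut$utr5_len + ut$cds_len + ut$utr3_len,
                            NA_integer_)
  out
}

#' Write / read the transcript annotation as GFF3 + UTR TSV
#'
#' The GFF3 is written in transcript space with 1-based closed intervals
#' (gene, five_prime_UTR, CDS, three_prime_UTR features); the UTR TSV
#' carries the segment lengths. Round-tripping through
#' [transcriptAnnotation()] is bit-exact on the coordinates.
#'
#' @param reference a [SyntheticReference].
#' @param gff,utr output paths.
#' @return the GFF path, invisibly.
#' @export
writeAnnotationGFF3 <- function(reference, gff, utr) {
  ann <- transcriptAnnotation(reference)
  feats <- list(GenomicRanges::GRanges(
    ann$transcript, IRanges::IRanges(1L, ann$length), type = "gene",
    biotype = ann$biotype, phase = NA_integer_))
  cod <- ann[!is.na(ann$cds_start), , drop = FALSE]
  addFeat <- function(s, e, type) {
    k <- !is.na(s)
    if (any(k)) {
      gr <- GenomicRanges::GRanges(
        cod$transcript[k], IRanges::IRanges(s[k], e[k]), type = type,
        biotype = cod$biotype[k],
        phase = if (type == "CDS") 0L else NA_integer_)
      feats[[length(feats) + 1L]] <<- gr
    }
  }
  addFeat(cod$utr5_start, cod$utr5_end, "five_prime_UTR")
  addFeat(cod$cds_start, cod$cds_end, "CDS")
  addFeat(cod$utr3_start, cod$utr3_end, "three_prime_UTR")
  all <- suppressWarnings(do.call(c, feats))
  rtracklayer::export(all, gff, format = "gff3")
  u <- as.data.frame(reference@utr)
  utils::write.table(u, utr, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gff)
}

#' Assign transcript-region labels to site calls
#'
#' Labels each call as CDS, 5'UTR, 3'UTR, ncRNA or intergenic based on the
#' transcript annotation, with precedence CDS > 5'UTR > 3'UTR > ncRNA >
#' intergenic when intervals overlap. When reference sequences are
#' supplied the called base identity (RNA alphabet) is attached.
#'
#' @param calls data.frame with transcript and pos columns.
#' @param annotation a [transcriptAnnotation()] table.
#' @param sequences optional named [Biostrings::DNAStringSet] (or
#'   [SyntheticReference]) for base identities.
#' @return the calls with added `region` (and `base`) columns.
#' @export
assignBiotype <- function(calls, annotation, sequences = NULL) {
  if (is(sequences, "SyntheticReference"))
    sequences <- referenceSequences(sequences)
  i <- match(calls$transcript, annotation$transcript)
  if (anyNA(i))
    stop("call(s) on transcripts absent from the annotation: ",
         paste(unique(calls$transcript[is.na(i)]), collapse = ", "))
  beyond <- calls$pos < 1L | calls$pos > annotation$length[i]
  if (any(beyond))
    stop("call beyond transcript bounds: ",
         paste(sprintf("%s:%d", calls$transcript[beyond],
                       calls$pos[beyond]), collapse = ", "))
  inSeg <- function(s, e) !is.na(s) & calls$pos >= s & calls$pos <= e
  a <- annotation[i, , drop = FALSE]
  region <- rep("intergenic", nrow(calls))
  region[a$biotype %in% c("ncRNA", "rRNA", "tRNA")] <- "ncRNA"
  region[inSeg(a$utr3_start, a$utr3_end)] <- "3UTR"
  region[inSeg(a$utr5_start, a$utr5_end)] <- "5UTR"
  region[inSeg(a$cds_start, a$cds_end)] <- "CDS"
  calls$region <- region
  if (!is.null(sequences)) {
    calls$base <- vapply(seq_len(nrow(calls)), function(k)
      chartr("T", "U", as.character(Biostrings::subseq(
        sequences[[calls$transcript[k]]], calls$pos[k], calls$pos[k]))),
      "")
  }
  calls
}

#' Relative position of a site within its transcript segment
#'
#' For sites labelled 5'UTR, CDS or 3'UTR, computes
#' (pos - segment start + 1) / segment length, a proportion in (0, 1]
#' enabling metagene comparisons across transcripts of different lengths.
#' Other labels (and zero-length segments, with a warning) yield NA.
#'
#' @param sites output of [assignBiotype()].
#' @param annotation a [transcriptAnnotation()] table.
#' @return the sites with an added `rel_pos` column.
#' @export
relativePosition <- function(sites, annotation) {
  i <- match(sites$transcript, annotation$transcript)
  a <- annotation[i, , drop = FALSE]
  seg <- cbind(
    start = ifelse(sites$region == "CDS", a$cds_start,
            ifelse(sites$region == "5UTR", a$utr5_start,
            ifelse(sites$region == "3UTR", a$utr3_start, NA_integer_))),
    end = ifelse(sites$region == "CDS", a$cds_end,
          ifelse(sites$region == "5UTR", a$utr5_end,
          ifelse(sites$region == "3UTR", a$utr3_end, NA_integer_))))
  len <- seg[, "end"] - seg[, "start"] + 1L
  zero <- !is.na(len) & len <= 0L
  if (any(zero)) warning(sum(zero), " site(s) in zero-length segments")
  rel <- (sites$pos - seg[, "start"] + 1L) / len
  rel[zero] <- NA_real_
  sites$rel_pos <- rel
  sites
}

#' Metagene density of site relative positions
#'
#' Histograms the relative positions of annotated sites per segment (and
#' optionally per condition and base identity), normalizing each
#' (condition, segment) group to unit area so densities are comparable
#' across groups.
#'
#' @param sites output of [relativePosition()]; may carry a `condition`
#'   column.
#' @param bins number of equal-width bins over (0, 1] (default 50).
#' @param base optional nucleotide filter ("A", "C", "G" or "U").
#' @return data.frame with (condition,) region, bin_mid, count, density.
#' @export
metageneDensity <- function(sites, bins = 50, base = NULL) {
  if (!nrow(sites)) stop("no annotated sites supplied")
  keep <- !is.na(sites$rel_pos)
  if (!is.null(base)) keep <- keep & sites$base == base
  s <- sites[keep, , drop = FALSE]
  if (!"condition" %in% colnames(s)) s$condition <- "all"
  brk <- seq(0, 1, length.out = bins + 1L)
  groups <- split(s, paste(s$condition, s$region, sep = "\r"))
  out <- lapply(groups, function(g) {
    h <- graphics::hist(g$rel_pos, breaks = brk, plot = FALSE,
                        include.lowest = TRUE)
    data.frame(condition = g$condition[1], region = g$region[1],
               bin_mid = h$mids, count = h$counts,
               density = h$counts / sum(h$counts) / diff(brk)[1],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}

#' Roll up modified sites into functional categories
#'
#' Counts modified sites and distinct genes per user-supplied functional
#' category (e.g. a KEGG top-level hierarchy). Genes missing from the
#' category table are tallied under "Function unknown".
#'
#' @param sites annotated site calls (transcript column identifies the
#'   gene).
#' @param categories data.frame with columns gene and category.
#' @return data.frame with category, n_sites, n_genes.
#' @export
functionalRollup <- function(sites, categories) {
  if (!all(c("gene", "category") %in% colnames(categories)))
    stop("categories must have columns gene and category")
  cat_of <- categories$category[match(sites$transcript, categories$gene)]
  missing <- is.na(cat_of)
  if (any(missing))
    message(length(unique(sites$transcript[missing])),
            " gene(s) missing from the category table; ",
            "counted as 'Function unknown'")
  cat_of[missing] <- "Function unknown"
  agg <- split(sites$transcript, cat_of)
  data.frame(category = names(agg),
             n_sites = lengths(agg),
             n_genes = vapply(agg, function(g) length(unique(g)), 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}
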