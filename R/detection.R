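#' @include AllClasses.R utils.R
NULL

#' Differential basecalling-error profile
#'
#' Positionwise difference delta = BCError_sample - BCError_control and
#' its normalized form delta / BCError_control. Positions masked in either
#' input stay masked; the normalized value is additionally masked where
#' the control BCError is zero (the plain delta is still reported there).
#'
#' @param sample,control [PileupProfile] objects over identical
#'   transcripts and lengths.
#' @return a [DeltaProfile].
#' @examples
#' # delta at a position with sample BCError 0.30 and control 0.20 is
#' # 0.10, normalized 0.50
#' @export
deltaProfile <- function(sample, control) {
  stopifnot(is(sample, "PileupProfile"), is(control, "PileupProfile"))
  a <- sample@data; b <- control@data
  if (!identical(paste(a$transcript, a$pos), paste(b$transcript, b$pos)))
    stop("profiles must cover identical transcripts and lengths")
  masked <- a$masked | b$masked
  delta <- a$bcerror - b$bcerror
  zero <- !masked & b$bcerror == 0
  norm <- ifelse(masked | zero, NA_real_, delta / b$bcerror)
  new("DeltaProfile", sampleA = sample@sample, sampleB = control@sample,
      data = DataFrame(transcript = a$transcript, pos = a$pos,
                       delta = ifelse(masked, NA_real_, delta),
                       norm_delta = norm,
                       masked = masked,
                       norm_masked = masked | zero))
}

#' Calibrate the classification threshold against known sites
#'
#' Sweeps a grid of differential-error thresholds; at each threshold the
#' predicted positives are the unmasked positions with delta at or above
#' it (optionally restricted to externally called regions), and precision
#' and recall are evaluated against a curated known-modification table.
#' The operating threshold is the F1-maximizing grid value (ties resolved
#' to the smallest, i.e. most sensitive, threshold) unless overridden via
#' `tau`.
#'
#' @param delta a [DeltaProfile] (e.g. combined no-stress minus combined
#'   IVT).
#' @param known a known-modification table with columns molecule,
#'   position ([knownModTable()] format).
#' @param grid ascending thresholds to sweep (default 0 to 0.2 by 0.005).
#' @param regions optional BED path or [GenomicRanges::GRanges] restricting
#'   candidate positions to externally called modified regions.
#' @param tolerance matching window in nt: a predicted position matches a
#'   known site within this distance (default 0 = exact position).
#' @param tau optional override of the operating threshold.
#' @return a [ThresholdCalibration].
#' @export
calibrateThreshold <- function(delta, known,
                               grid = seq(0, 0.2, by = 0.005),
                               regions = NULL, tolerance = 0,
                               tau = NULL) {
  stopifnot(is(delta, "DeltaProfile"))
  if (is.null(known) || !nrow(known)) stop("known-site table is empty")
  d <- delta@data
  ok <- !d$masked
  if (!any(ok)) stop("delta profile is masked everywhere")
  regions <- asRegionRanges(regions)
  restriction <- "all"
  if (!is.null(regions)) {
    ok <- ok & inRegions(as.character(d$transcript), d$pos, regions)
    restriction <- "regions"
  }
  cand <- data.frame(transcript = as.character(d$transcript[ok]),
                     pos = d$pos[ok], delta = d$delta[ok])

  covered <- unique(as.character(d$transcript[!d$masked]))
  kn <- known[known$molecule %in% covered, , drop = FALSE]
  nKnown <- nrow(kn)
  if (!nKnown) stop("no known site lies on a covered transcript")

  # for each candidate position, whether it matches a known site, and for
  # each known site, the largest delta of a candidate within tolerance
  matchesKnown <- logical(nrow(cand))
  bestDelta <- rep(-Inf, nKnown)
  for (i in seq_len(nKnown)) {
    hit <- cand$transcript == kn$molecule[i] &
      abs(cand$pos - kn$position[i]) <= tolerance
    matchesKnown <- matchesKnown | hit
    if (any(hit)) bestDelta[i] <- max(cand$delta[hit])
  }

  res <- lapply(grid, function(t) {
    pred <- cand$delta >= t
    nPred <- sum(pred)
    tp <- sum(bestDelta >= t)          # known sites recovered
    fp <- nPred - sum(pred & matchesKnown)
    fn <- nKnown - tp
    precision <- if (nPred > 0) sum(pred & matchesKnown) / nPred else NA_real_
    recall <- tp / nKnown
    f1 <- if (!is.na(precision) && precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    data.frame(tau = t, tp = tp, fp = fp, fn = fn,
               precision = precision, recall = recall, f1 = f1)
  })
  g <- do.call(rbind, res)
  chosen <- if (!is.null(tau)) tau else g$tau[which.max(g$f1)]
  new("ThresholdCalibration", grid = g, tau = chosen,
      restriction = restriction)
}

#' Classify putative modification sites
#'
#' Every unmasked position whose differential error reaches the threshold
#' becomes a putative site call. The call set shrinks (never grows) as the
#' threshold increases.
#'
#' @param delta a [DeltaProfile].
#' @param tau classification threshold (the study convention is 0.02).
#' @return data.frame with transcript, pos, delta — one row per call.
#' @export
classifySites <- function(delta, tau = 0.02) {
  stopifnot(is(delta, "DeltaProfile"), tau >= 0)
  d <- delta@data
  keep <- !d$masked & d$delta >= tau
  out <- data.frame(transcript = as.character(d$transcript[keep]),
                    pos = d$pos[keep], delta = d$delta[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Consensus site calls across replicates (and an external detector)
#'
#' Retains calls present at the same transcript and position in every
#' replicate call set; when external region calls are supplied (e.g. from
#' a signal-level detector), a retained call must additionally fall inside
#' at least one region. The `supported_by` column records the supporting
#' evidence.
#'
#' @param calls named list of per-replicate call data.frames
#'   (from [classifySites()]).
#' @param regions optional BED path or [GenomicRanges::GRanges].
#' @return data.frame with transcript, pos, delta (mean across replicates)
#'   and supported_by (comma-separated evidence labels).
#' @export
consensusSites <- function(calls, regions = NULL) {
  if (length(calls) == 0L) stop("no replicate call sets supplied")
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    names(calls) <- paste0("rep", seq_along(calls))
  keys <- lapply(calls, function(x) paste(x$transcript, x$pos))
  shared <- Reduce(intersect, keys)
  first <- calls[[1]]
  sel <- match(shared, keys[[1]])
  out <- data.frame(transcript = first$transcript[sel],
                    pos = first$pos[sel],
                    stringsAsFactors = FALSE)
  out$delta <- rowMeans(do.call(cbind, lapply(seq_along(calls), function(i)
    calls[[i]]$delta[match(shared, keys[[i]])])))
  support <- rep(paste(names(calls), collapse = ","), nrow(out))

  regions <- asRegionRanges(regions)
  if (!is.null(regions) && nrow(out)) {
    inr <- inRegions(out$transcript, out$pos, regions)
    out <- out[inr, , drop = FALSE]
    support <- paste0(support[inr], ",region")
  }
  out$supported_by <- if (nrow(out)) support else character(0)
  rownames(out) <- NULL
  out
}

#' Fraction of calls near a sequence motif
#'
#' For each call, searches the reference for motif matches starting within
#' a +/- `window` nt neighborhood of the called position (sense strand;
#' IUPAC ambiguity codes in the motifs are honored) and returns the
#' fraction of calls with at least one nearby match. Used e.g. to ask how
#' many putative sites sit near known pseudouridylation motifs.
#'
#' @param calls data.frame with transcript and pos columns.
#' @param sequences named [Biostrings::DNAStringSet] (or
#'   [SyntheticReference]).
#' @param motifs character vector of motifs (RNA or DNA alphabet, IUPAC
#'   codes allowed). Must be non-empty; no default is assumed.
#' @param window neighborhood half-width in nt (default 4).
#' @return proportion of calls with a nearby motif match.
#' @export
motifProximityFraction <- function(calls, sequences, motifs, window = 4) {
  if (length(motifs) == 0L) stop("motif list is empty")
  if (is(sequences, "SyntheticReference"))
    sequences <- referenceSequences(sequences)
  if (!nrow(calls)) return(NA_real_)
  motifs <- chartr("Uu", "Tt", motifs)
  hit <- logical(nrow(calls))
  for (tx in unique(calls$transcript)) {
    if (!tx %in% names(sequences))
      stop("call on transcript absent from the reference: ", tx)
    starts <- sort(unique(unlist(lapply(motifs, function(m)
      BiocGenerics::start(Biostrings::matchPattern(
        m, sequences[[tx]], fixed = "subject"))))))
    idx <- which(calls$transcript == tx)
    for (i in idx)
      hit[i] <- any(abs(starts - calls$pos[i]) <= window)
  }
  mean(hit)
}

#' Load the curated rRNA known-modification table
#'
#' The package ships a curated table of the 36 characterized modification
#' positions on the E. coli small (16S) and large (23S) ribosomal subunit
#' RNAs, used to calibrate the error-based classifier.
#'
#' @param path optional path to a user table (TSV with columns molecule,
#'   position, mod); defaults to the shipped fixture.
#' @return data.frame with molecule, position (1-based), mod.
#' @export
knownModTable <- function(path = system.file("extdata",
                                             "ecoli_rrna_known_mods.tsv",
                                             package = "epiDRS")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("molecule", "position", "mod")
  if (!all(need %in% colnames(tab)))
    stop("known-modification table needs columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(tab[, c("molecule", "position")]))
    stop("duplicate (molecule, position) keys in known-modification table")
  tab
}
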