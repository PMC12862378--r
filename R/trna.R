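#' @include AllClasses.R utils.R
NULL

loopOffsets <- function(span = c("loop", "anticodon")) {
  span <- match.arg(span)
  # canonical numbering: anticodon = 34-36, anticodon loop = 32-38
  if (span == "loop") -2:4 else 0:2
}

#' Anticodon-loop differential error matrix
#'
#' For each tRNA, computes the stress-minus-control BCError difference at
#' every anticodon-loop position (canonical numbering 32-38; the wobble
#' position 34 is the anticodon start given in the metadata), averaged
#' across replicate pairs. tRNAs failing the read-depth requirement
#' (masked, i.e. < minDepth reads, at any loop position in any replicate)
#' are excluded and listed.
#'
#' @param stress,control lists of per-replicate [PileupProfile] objects
#'   (equal length, paired by index).
#' @param meta data.frame with transcript, anticodon_start (1-based,
#'   mature coordinates) and optionally pathway.
#' @return list with `mean` (tRNA x loop-position matrix of mean deltas),
#'   `replicates` (per-replicate matrices) and `excluded` (tRNA ids that
#'   failed depth).
#' @export
anticodonDeltaMatrix <- function(stress, control, meta) {
  stopifnot(length(stress) == length(control), length(stress) >= 1L)
  off <- loopOffsets("loop")
  posLabels <- as.character(34L + off)

  txAll <- unique(unlist(lapply(stress, transcripts)))
  bad <- setdiff(txAll, meta$transcript)
  if (length(bad))
    stop("metadata missing for profiled tRNA(s): ",
         paste(bad, collapse = ", "))
  use <- meta[meta$transcript %in% txAll, , drop = FALSE]
  if (!nrow(use)) stop("no profiled tRNA matches the metadata")

  getDelta <- function(sp, cp, tx, positions) {
    ds <- sp@data[sp@data$transcript == tx, , drop = FALSE]
    dc <- cp@data[cp@data$transcript == tx, , drop = FALSE]
    is_ <- match(positions, ds$pos); ic <- match(positions, dc$pos)
    if (anyNA(is_) || anyNA(ic)) return(NULL)
    if (any(ds$masked[is_]) || any(dc$masked[ic])) return(NULL)
    ds$bcerror[is_] - dc$bcerror[ic]
  }

  repMats <- vector("list", length(stress))
  excluded <- character(0)
  for (r in seq_along(stress)) {
    m <- matrix(NA_real_, nrow(use), length(off),
                dimnames = list(use$transcript, posLabels))
    for (i in seq_len(nrow(use))) {
      positions <- use$anticodon_start[i] + off
      d <- getDelta(stress[[r]], control[[r]], use$transcript[i], positions)
      if (is.null(d)) excluded <- union(excluded, use$transcript[i])
      else m[i, ] <- d
    }
    repMats[[r]] <- m
  }
  keep <- setdiff(use$transcript, excluded)
  repMats <- lapply(repMats, function(m) m[keep, , drop = FALSE])
  meanMat <- Reduce(`+`, repMats) / length(repMats)
  list(mean = meanMat, replicates = repMats, excluded = excluded)
}

#' Total anticodon differential error
#'
#' Sums the per-position differential error over the anticodon (positions
#' 34-36 by default) or the whole anticodon loop (32-38), giving one
#' comprehensive modification-change measure per tRNA. The total is, by
#' construction, additive over its positionwise components.
#'
#' @param acd output of [anticodonDeltaMatrix()].
#' @param span "anticodon" (34-36, default) or "loop" (32-38).
#' @return named numeric vector, one total per tRNA.
#' @export
anticodonTotalDelta <- function(acd, span = c("anticodon", "loop")) {
  span <- match.arg(span)
  cols <- as.character(34L + loopOffsets(span))
  rowSums(acd$mean[, cols, drop = FALSE])
}

#' Flag stress-responsive tRNAs
#'
#' A tRNA is stress-responsive when the magnitude of its mean
#' anticodon-loop differential error reaches the cutoff at some loop
#' position and the sign of the change at that position agrees across all
#' replicates.
#'
#' @param acd output of [anticodonDeltaMatrix()].
#' @param cutoff minimum |delta| (default 0.1).
#' @return data.frame with transcript, responsive, direction ("increase",
#'   "decrease" or "none"), max_abs_delta and position (canonical loop
#'   numbering).
#' @export
classifyStressResponsive <- function(acd, cutoff = 0.1) {
  m <- acd$mean
  out <- lapply(rownames(m), function(tx) {
    v <- m[tx, ]
    j <- which.max(abs(v))
    ok <- abs(v[j]) >= cutoff
    if (ok) {
      signs <- vapply(acd$replicates, function(r) sign(r[tx, j]), 0)
      ok <- all(signs == sign(v[j])) && all(signs != 0)
    }
    data.frame(transcript = tx,
               responsive = ok,
               direction = if (!ok) "none" else
                 if (v[j] > 0) "increase" else "decrease",
               max_abs_delta = abs(v[j]),
               position = as.integer(colnames(m)[j]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Equal-weighted read-length distributions
#'
#' Computes, for each group of tRNAs (e.g. stress-responsive vs
#' non-responsive) and condition, the read-length density over 0-500 nt.
#' The density of every (tRNA, replicate) is computed first with unit
#' area, then averaged with equal weights within the group, so each
#' pre-tRNA, biological replicate and sample condition contributes equally
#' regardless of read counts. Reads longer than the range are clipped
#' into the last bin.
#'
#' @param lengths read-length table (transcript, condition, replicate,
#'   length).
#' @param groups named character vector mapping transcript -> group label
#'   (default: one group "all").
#' @param binwidth bin width in nt (default 10).
#' @param range length range covered (default c(0, 500)).
#' @return data.frame with group, condition, bin_mid, density; each
#'   (group, condition) density integrates to 1.
#' @export
lengthDistributions <- function(lengths, groups = NULL, binwidth = 10,
                                range = c(0, 500)) {
  if (is.null(groups)) {
    groups <- rep("all", length(unique(lengths$transcript)))
    names(groups) <- unique(lengths$transcript)
  }
  brk <- seq(range[1], range[2], by = binwidth)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  lengths$group <- groups[lengths$transcript]
  lengths <- lengths[!is.na(lengths$group), , drop = FALSE]

  out <- list()
  for (g in unique(lengths$group)) {
    for (cond in unique(lengths$condition)) {
      sub <- lengths[lengths$group == g & lengths$condition == cond, ,
                     drop = FALSE]
      if (!nrow(sub)) {
        warning("empty group: ", g, " / ", cond)
        next
      }
      units <- split(pmin(sub$length, range[2]),
                     paste(sub$transcript, sub$replicate))
      dens <- vapply(units, function(x) {
        h <- graphics::hist(x, breaks = brk, plot = FALSE,
                            include.lowest = TRUE)
        h$counts / sum(h$counts) / binwidth
      }, numeric(length(mids)))
      avg <- rowMeans(as.matrix(dens))
      out[[length(out) + 1L]] <- data.frame(
        group = g, condition = cond, bin_mid = mids, density = avg,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(group = character(), condition = character(),
                      bin_mid = numeric(), density = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pre-tRNA maturity metric from read lengths
#'
#' Uses the average read length of a pre-tRNA as a maturity proxy (longer
#' reads retain leader/trailer sequence, i.e. earlier processing stages)
#' and summarizes the stress-vs-control contrast as the log2 ratio of
#' condition mean lengths (replicates pooled). tRNAs with fewer than
#' `minReads` reads in either condition are excluded.
#'
#' @param lengths read-length table (transcript, condition, replicate,
#'   length).
#' @param stress,control condition labels to contrast.
#' @param minReads minimum reads per condition (default 5).
#' @return data.frame with transcript, mean_stress, mean_control and
#'   maturity = log2(mean_stress / mean_control).
#' @export
maturityMetric <- function(lengths, stress, control, minReads = 5) {
  txs <- unique(lengths$transcript)
  out <- lapply(txs, function(tx) {
    ls <- lengths$length[lengths$transcript == tx &
                         lengths$condition == stress]
    lc <- lengths$length[lengths$transcript == tx &
                         lengths$condition == control]
    if (length(ls) < minReads || length(lc) < minReads) return(NULL)
    data.frame(transcript = tx, mean_stress = mean(ls),
               mean_control = mean(lc),
               maturity = log2(mean(ls) / mean(lc)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(transcript = character(), mean_stress = numeric(),
                      mean_control = numeric(), maturity = numeric())
  rownames(res) <- NULL
  res
}

#' Normality-gated correlation test
#'
#' Tests the association between two paired variables with Pearson
#' correlation when both pass a Shapiro-Wilk normality test at the given
#' alpha, and with Spearman rank correlation otherwise; p-values are
#' two-sided. This is the gating convention for relating pre-tRNA
#' maturity to anticodon modification change.
#'
#' @param x,y paired numeric vectors (>= 4 complete pairs).
#' @param alpha normality test level (default 0.05).
#' @return data.frame with method, estimate, p.value, n and the per-
#'   variable Shapiro-Wilk statistics.
#' @export
correlationTest <- function(x, y, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stop("need at least 4 complete pairs")
  swx <- stats::shapiro.test(x)
  swy <- stats::shapiro.test(y)
  normal <- swx$p.value > alpha && swy$p.value > alpha
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided"))
  data.frame(method = method,
             estimate = unname(ct$estimate),
             p.value = ct$p.value,
             n = length(x),
             shapiro_w_x = unname(swx$statistic),
             shapiro_p_x = swx$p.value,
             shapiro_w_y = unname(swy$statistic),
             shapiro_p_y = swy$p.value,
             stringsAsFactors = FALSE)
}

#' Maturity-modification correlation
#'
#' Joins the maturity metrics with the total anticodon differential
#' errors and runs the normality-gated correlation test, optionally on
#' the stress-responsive subset only.
#'
#' @param maturity output of [maturityMetric()].
#' @param totals named numeric from [anticodonTotalDelta()].
#' @param subset optional character vector of transcripts to restrict to
#'   (e.g. the stress-responsive set).
#' @param alpha normality gate level.
#' @return as [correlationTest()].
#' @export
maturityModificationCorrelation <- function(maturity, totals,
                                            subset = NULL, alpha = 0.05) {
  m <- maturity
  if (!is.null(subset)) m <- m[m$transcript %in% subset, , drop = FALSE]
  shared <- intersect(m$transcript, names(totals))
  if (length(shared) < 4L) stop("need at least 4 paired observations")
  correlationTest(m$maturity[match(shared, m$transcript)],
                  unname(totals[shared]), alpha = alpha)
}
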