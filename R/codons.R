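#' @include AllClasses.R utils.R
NULL

#' The wobble-modification codon-set table
#'
#' Nine synonymous codon pairs, each pairing a codon whose decoding
#' requires a wobble-position (nucleotide 34) anticodon modification from
#' the queuosine (Q) or Mnm (mnm5s2U) pathway with its
#' modification-independent synonym. The two codons of a set encode the
#' same amino acid and differ only at the third position. The shipped
#' default assigns the U-ending codon as modification-dependent for the
#' Q-decoded amino acids (Asn, Asp, His, Tyr) and the G-ending codon for
#' the Mnm-decoded ones (Arg, Gln, Glu, Gly, Leu) — the standard
#' wobble-decoding assignments; a user table in the same format replaces
#' it wherever a `sets` argument is accepted.
#'
#' @param path optional TSV with columns amino_acid, pathway, dependent,
#'   independent (codons in the RNA alphabet); defaults to the shipped
#'   table.
#' @return validated data.frame with columns amino_acid, pathway,
#'   dependent, independent.
#' @export
codonSetTable <- function(path = system.file("extdata", "codon_sets.tsv",
                                             package = "epiDRS")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validateCodonSets(tab)
  tab
}

validateCodonSets <- function(tab) {
  need <- c("amino_acid", "pathway", "dependent", "independent")
  if (!all(need %in% colnames(tab)))
    stop("codon-set table needs columns: ", paste(need, collapse = ", "))
  dep <- chartr("U", "T", toupper(tab$dependent))
  ind <- chartr("U", "T", toupper(tab$independent))
  all18 <- c(dep, ind)
  if (any(nchar(all18) != 3L))
    stop("codons must be 3 nt long")
  if (anyDuplicated(all18))
    stop("no codon may appear in two sets")
  gc <- Biostrings::GENETIC_CODE
  aaD <- gc[dep]; aaI <- gc[ind]
  if (any(is.na(aaD)) || any(is.na(aaI)) || any(aaD != aaI))
    stop("the two codons of a set must encode the same amino acid")
  if (any(substr(dep, 1, 2) != substr(ind, 1, 2)))
    stop("set codons must differ only at the third position")
  invisible(TRUE)
}

#' Modification-dependent codon abundance per CDS
#'
#' Counts, in an in-frame non-overlapping scan of each coding sequence,
#' the occurrences of the 18 set codons and scores each transcript as
#'
#' \deqn{abundance = \frac{n_{dep}}{n_{dep} + n_{ind}}}
#'
#' the fraction of set-codon occurrences that are modification-dependent.
#' Transcripts containing none of the 18 codons are masked (NA), not
#' scored zero. Codons containing ambiguity characters are simply not
#' counted; premature stops are ordinary codons (no set codon is a stop).
#'
#' @param cds a [Biostrings::DNAStringSet] (or single character/DNAString)
#'   of CDSs; lengths must be divisible by 3.
#' @param sets a codon-set table (default [codonSetTable()]).
#' @return data.frame with transcript, count_dependent, count_independent,
#'   abundance.
#' @export
countCodons <- function(cds, sets = codonSetTable()) {
  validateCodonSets(sets)
  if (is.character(cds)) cds <- Biostrings::DNAStringSet(cds)
  if (is(cds, "DNAString")) cds <- Biostrings::DNAStringSet(cds)
  if (is.null(names(cds))) names(cds) <- paste0("cds", seq_along(cds))
  if (any(BiocGenerics::width(cds) %% 3L != 0L))
    stop("CDS length(s) not divisible by 3: ",
         paste(names(cds)[BiocGenerics::width(cds) %% 3L != 0L],
               collapse = ", "))
  dep <- chartr("U", "T", toupper(sets$dependent))
  ind <- chartr("U", "T", toupper(sets$independent))
  freq <- Biostrings::trinucleotideFrequency(cds, step = 3)
  nDep <- as.integer(rowSums(freq[, dep, drop = FALSE]))
  nInd <- as.integer(rowSums(freq[, ind, drop = FALSE]))
  tot <- nDep + nInd
  data.frame(transcript = names(cds),
             count_dependent = nDep, count_independent = nInd,
             abundance = ifelse(tot > 0, nDep / tot, NA_real_),
             stringsAsFactors = FALSE)
}

#' Tie-aware top/bottom selection by codon abundance
#'
#' Orders scored transcripts by abundance and returns the `n` highest (or
#' lowest), together with every transcript tied with the score at the
#' boundary rank — so a tie spanning the cut returns more than `n` ids,
#' as when a tie across ranks 399-403 turns a bottom-400 selection into
#' 403 transcripts. Masked (NA) scores are never selected.
#'
#' @param scores output of [countCodons()].
#' @param n nominal selection size.
#' @param direction "highest" or "lowest".
#' @return character vector of selected transcript ids (length >= n when
#'   the boundary is tied).
#' @export
rankSelect <- function(scores, n, direction = c("highest", "lowest")) {
  direction <- match.arg(direction)
  s <- scores[!is.na(scores$abundance), , drop = FALSE]
  if (n > nrow(s))
    stop("n exceeds the number of scored transcripts")
  decreasing <- direction == "highest"
  o <- order(s$abundance, decreasing = decreasing)
  boundary <- s$abundance[o[n]]
  keep <- if (decreasing) s$abundance >= boundary else
    s$abundance <= boundary
  s$transcript[o][sort(which(keep[o]))]
}

#' Compare codon abundance between translational-efficiency classes
#'
#' Two-sided Mann-Whitney U test (midrank tie handling) of
#' modification-dependent codon abundance between transcripts whose
#' translational efficiency increased versus decreased under stress.
#'
#' @param scores output of [countCodons()].
#' @param te TE table with columns transcript and class.
#' @param classes the two class labels to compare (first vs second).
#' @return data.frame with the group labels and sizes, medians, the U
#'   statistic (of the first group) and the two-sided p-value.
#' @export
compareTeGroups <- function(scores, te,
                            classes = c("increased", "decreased")) {
  stopifnot(length(classes) == 2L)
  ab <- scores$abundance[match(te$transcript, scores$transcript)]
  g1 <- ab[te$class == classes[1] & !is.na(ab)]
  g2 <- ab[te$class == classes[2] & !is.na(ab)]
  if (!length(g1) || !length(g2))
    stop("a class is empty after removing masked scores")
  wt <- suppressWarnings(stats::wilcox.test(g1, g2, exact = FALSE,
                                            correct = FALSE,
                                            alternative = "two.sided"))
  # prefer the exact p-value when there are no ties and groups are small
  if (length(g1) < 50 && length(g2) < 50 &&
      !anyDuplicated(c(g1, g2))) {
    wt <- stats::wilcox.test(g1, g2, exact = TRUE,
                             alternative = "two.sided")
  }
  data.frame(group1 = classes[1], group2 = classes[2],
             n1 = length(g1), n2 = length(g2),
             median1 = stats::median(g1), median2 = stats::median(g2),
             U = unname(wt$statistic), p.value = wt$p.value,
             stringsAsFactors = FALSE)
}
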