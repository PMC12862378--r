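# In-memory alignment fixtures, built directly as DrsAlignments objects.

makeAln <- function(rname, pos, cigar, seq, qual = NULL, flag = 0L,
                    strand = "+", mapq = 60L,
                    qname = sprintf("r%03d", seq_along(seq))) {
  if (is.null(qual)) qual <- strrep("I", nchar(seq))  # Q40 everywhere
  n <- length(seq)
  new("DrsAlignments",
      reads = S4Vectors::DataFrame(
        qname = rep_len(qname, n), flag = rep_len(as.integer(flag), n),
        rname = rep_len(rname, n), strand = rep_len(strand, n),
        pos = rep_len(as.integer(pos), n), mapq = rep_len(mapq, n),
        cigar = rep_len(cigar, n), seq = seq, qual = rep_len(qual, n)),
      source = "in-memory",
      filterReport = S4Vectors::DataFrame(reason = character(),
                                          n = integer()))
}

# Random toy alignment set against a random reference, with substitutions,
# 1-nt deletions, 1-nt insertions and terminal soft clips. The first and
# last aligned positions of every read are kept indel-free so the CIGAR
# stays canonical.
randomToyAlignments <- function(seed, maxReads = 50) {
  set.seed(seed)
  L <- sample(30:60, 1)
  refc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  n <- sample(5:maxReads, 1)
  pos <- integer(n); cigar <- character(n); seqs <- character(n)
  for (i in seq_len(n)) {
    s <- sample(seq_len(L - 8L), 1)
    e <- sample(seq(min(s + 5L, L), L), 1)
    span <- s:e
    state <- sample(c("m", "x", "d", "ins"), length(span), replace = TRUE,
                    prob = c(0.85, 0.06, 0.05, 0.04))
    state[c(1, length(span))] <- sample(c("m", "x"), 2, replace = TRUE)
    qchars <- character(0); ops <- character(0)
    for (k in seq_along(span)) {
      p <- span[k]
      if (state[k] == "d") { ops <- c(ops, "D"); next }
      base <- refc[p]
      if (state[k] == "x")
        base <- sample(setdiff(c("A", "C", "G", "T"), base), 1)
      qchars <- c(qchars, base); ops <- c(ops, "M")
      if (state[k] == "ins") {
        qchars <- c(qchars, sample(c("A", "C", "G", "T"), 1))
        ops <- c(ops, "I")
      }
    }
    scl <- sample(0:4, 1); scr <- sample(0:4, 1)
    qchars <- c(sample(c("A", "C", "G", "T"), scl, replace = TRUE), qchars,
                sample(c("A", "C", "G", "T"), scr, replace = TRUE))
    ops <- c(rep("S", scl), ops, rep("S", scr))
    r <- rle(ops)
    cigar[i] <- paste0(r$lengths, r$values, collapse = "")
    pos[i] <- s
    seqs[i] <- paste(qchars, collapse = "")
  }
  ref <- Biostrings::DNAStringSet(paste(refc, collapse = ""))
  names(ref) <- "toy"
  list(reference = ref,
       aln = makeAln("toy", pos, cigar, seqs))
}
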