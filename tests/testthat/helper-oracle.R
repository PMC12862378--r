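# Exact Mann-Whitney oracle: enumerate every assignment of the pooled
# values into groups of sizes n1/n2 and compute U (pair-count definition)
# and the two-sided permutation p-value.
exactMannWhitney <- function(x, y) {
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  pooled <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  combos <- utils::combn(n1 + n2, n1)
  us <- apply(combos, 2, function(idx) {
    xx <- pooled[idx]; yy <- pooled[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  mid <- n1 * n2 / 2
  p <- mean(abs(us - mid) >= abs(U - mid) - 1e-9)
  list(U = U, p = p)
}

# Naive per-read, per-position pileup enumeration: an independent oracle
# for BCError that walks every CIGAR operation one base at a time.
naiveBCError <- function(aln, reference, minDepth = 5) {
  ref <- as.character(reference[[1]])
  L <- nchar(ref)
  refc <- strsplit(ref, "")[[1]]
  cov <- integer(L); err <- integer(L)
  r <- epiDRS::readRecords(aln)
  for (i in seq_len(nrow(r))) {
    toks <- regmatches(r$cigar[i],
                       gregexpr("\\d+[MIDNSHP=X]", r$cigar[i]))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", toks))
    ops <- sub("^\\d+", "", toks)
    qc <- strsplit(r$seq[i], "")[[1]]
    rp <- r$pos[i]; qp <- 1L
    covered <- logical(L); erred <- logical(L)
    for (k in seq_along(ops)) {
      op <- ops[k]; nn <- lens[k]
      if (op %in% c("M", "=", "X")) {
        for (j in 0:(nn - 1L)) {
          covered[rp + j] <- TRUE
          if (qc[qp + j] != refc[rp + j]) erred[rp + j] <- TRUE
        }
        rp <- rp + nn; qp <- qp + nn
      } else if (op == "D" || op == "N") {
        for (j in 0:(nn - 1L)) {
          covered[rp + j] <- TRUE
          erred[rp + j] <- TRUE
        }
        rp <- rp + nn
      } else if (op == "I") {
        at <- rp - 1L
        if (at >= 1L && at <= L && covered[at]) erred[at] <- TRUE
        qp <- qp + nn
      } else if (op %in% c("S", "H")) {
        if (op == "S") qp <- qp + nn
      }
    }
    cov <- cov + covered
    err <- err + (covered & erred)
  }
  data.frame(pos = seq_len(L), coverage = cov, error_count = err,
             bcerror = ifelse(cov > 0, err / cov, NA_real_),
             masked = cov < minDepth)
}
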