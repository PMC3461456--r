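# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: plain character arithmetic, explicit
# summation and exhaustive enumeration only.

# Direct Poisson pmf summation: P(X >= x) = sum_{k >= x} e^-u u^k / k!,
# summed upward in log space until terms vanish.
poisTailOracle <- function(x, u) {
  if (x == 0) return(1)
  total <- 0
  k <- x
  repeat {
    term <- exp(-u + k * log(u) - lgamma(k + 1))
    total <- total + term
    if (term < total * 1e-18 && k > u + 10) break
    k <- k + 1
    if (k > x + 10000) break
  }
  min(1, total)
}

# Full hypergeometric enumeration for a 2x2 table with fixed margins;
# two-sided rule: sum outcomes no more probable than the observed one.
fisherEnumOracle <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b
  c1 <- a + c
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  pk <- exp(lchoose(r1, support) + lchoose(n - r1, c1 - support) -
              lchoose(n, c1))
  pObs <- pk[match(a, support)]
  min(1, sum(pk[pk <= pObs * (1 + 1e-7)]))
}

# Brute-force Hamming scan over every genome offset and both strands;
# reverse-strand hits reported at the 0-based coordinate of the fragment's
# first base (= 3' end of the reverse-complement match).
bruteAlignOracle <- function(seq, genome, len = nchar(seq), maxMM = 0L) {
  pat <- substr(seq, 1L, len)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1L]]),
                                      collapse = ""))
  out <- list()
  for (chrom in names(chromSizes(genome))) {
    schars <- strsplit(as.character(genomeSeqs(genome)[[chrom]]), "")[[1L]]
    npos <- length(schars) - len + 1L
    if (npos < 1L) next
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else revcomp(pat)
      pchars <- strsplit(p, "")[[1L]]
      mm <- integer(npos)
      for (j in seq_len(len))
        mm <- mm + (schars[j:(j + npos - 1L)] != pchars[j])
      hit <- which(mm <= maxMM)
      if (length(hit))
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom,
          pos = if (strand == "+") hit - 1L else hit + len - 2L,
          strand = strand, mismatches = mm[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

sortHits <- function(h) {
  h <- h[order(h$chrom, h$pos, h$strand), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# Exhaustive analogue of the one-window-size peak scan: enumerate every
# anchored window, count by direct subsetting, then apply the same greedy
# rule (highest count, ties by lowest coordinate) by repeated full scans.
exhaustivePeaksOracle <- function(events, windowSize, kmin) {
  ef <- data.frame(chrom = as.character(GenomicRanges::seqnames(events)),
                   pos = GenomicRanges::start(events) - 1L,
                   stringsAsFactors = FALSE)
  wins <- unique(ef[, c("chrom", "pos")])
  wins$count <- vapply(seq_len(nrow(wins)), function(i)
    sum(ef$chrom == wins$chrom[i] & ef$pos >= wins$pos[i] &
          ef$pos < wins$pos[i] + windowSize), integer(1L))
  wins <- wins[wins$count >= kmin, , drop = FALSE]
  chosen <- list()
  while (nrow(wins)) {
    o <- order(-wins$count, wins$chrom, wins$pos)
    best <- wins[o[1L], ]
    chosen[[length(chosen) + 1L]] <- best
    keep <- !(wins$chrom == best$chrom &
                wins$pos < best$pos + windowSize &
                wins$pos + windowSize > best$pos)
    wins <- wins[keep, , drop = FALSE]
  }
  if (!length(chosen))
    return(data.frame(chrom = character(), start = numeric(),
                      count = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, chosen)
  out <- data.frame(chrom = out$chrom, start = out$pos, count = out$count,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Brute-force window-size plan: for every (window, integer count) pair on
# the grid decide significance directly, then keep the largest window per
# achievable count.
windowPlanOracle <- function(totalEvents, config) {
  ws <- seq(config@wMin, config@wMax, by = config@wStep)
  alpha <- config@alpha
  kmin <- vapply(ws, function(w) {
    u <- totalEvents * w / config@genomeSize
    k <- 2L    # a lone insertion is never a common insertion site
    while (min(1, poisTailOracle(k, u) * totalEvents) >= alpha) k <- k + 1L
    k
  }, integer(1L))
  sizes <- vapply(sort(unique(kmin)), function(k) max(ws[kmin <= k]),
                  numeric(1L))
  sort(unique(sizes), decreasing = TRUE)
}

# Events GRanges built directly from coordinate triplets.
makeEvents <- function(chrom, binStart, library,
                       orientation = "+", readCount = 1) {
  n <- length(binStart)
  if (n == 0L)
    return(GenomicRanges::GRanges(library = character(),
                                  readCount = numeric(),
                                  nRawPositions = integer()))
  GenomicRanges::GRanges(
    seqnames = rep_len(chrom, n),
    ranges = IRanges::IRanges(start = rep_len(binStart, n) + 1L, width = 100L),
    strand = rep_len(orientation, n),
    library = rep_len(library, n),
    readCount = rep_len(readCount, n),
    nRawPositions = rep_len(1L, n))
}

# A read laid out as barcode + tag + genomic (+ tail).
makeRead <- function(barcode, tag, genomic, tail = "") {
  paste0(barcode, tag, genomic, tail)
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")
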