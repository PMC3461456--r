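#' Load a reference genome
#'
#' @param fasta path to a genome FASTA (optional when `sizes` is given).
#' @param sizes path to a two-column chrom.sizes file (name, length), or a
#'   named numeric vector. Derived from the FASTA when omitted.
#' @return a [GenomeIndex-class].
#' @export
readGenome <- function(fasta = NULL, sizes = NULL) {
  seqs <- DNAStringSet()
  if (!is.null(fasta)) {
    seqs <- readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  }
  if (is.null(sizes)) {
    if (!length(seqs)) stop("supply a FASTA and/or a chrom.sizes table")
    sz <- stats::setNames(as.numeric(Biostrings::width(seqs)), names(seqs))
  } else if (is.character(sizes)) {
    tab <- utils::read.delim(sizes, header = FALSE, stringsAsFactors = FALSE)
    sz <- stats::setNames(as.numeric(tab[[2L]]), as.character(tab[[1L]]))
  } else {
    sz <- sizes
  }
  if (length(seqs)) seqs <- seqs[names(sz)]
  new("GenomeIndex", seqs = seqs, sizes = sz)
}

#' Build a genome index from sequences in memory
#'
#' @param seqs named character vector or `DNAStringSet` of chromosomes.
#' @return a [GenomeIndex-class].
#' @export
genomeFromSeqs <- function(seqs) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- paste0("chr", seq_along(seqs))
  new("GenomeIndex", seqs = seqs,
      sizes = stats::setNames(as.numeric(Biostrings::width(seqs)), names(seqs)))
}

#' Default iterative mapping schedule
#'
#' Five rounds of end-to-end prefix mapping with decreasing length and
#' mismatch allowance: full length (when > 33 bp) at 3 mismatches, then 33 bp
#' at 3, 30 bp at 2, 28 bp at 1 and 24 bp at 0 mismatches. The length cutoffs
#' are the empirical points below which randomly generated sequences start to
#' map uniquely to a mammalian genome at the given mismatch allowance.
#'
#' @return `data.frame` with columns `prefixLength` (`NA` = full length) and
#'   `maxMismatches`, one row per stage in order.
#' @examples
#' defaultSchedule()
#' @export
defaultSchedule <- function() {
  data.frame(prefixLength = c(NA, 33L, 30L, 28L, 24L),
             maxMismatches = c(3L, 3L, 2L, 1L, 0L))
}

#' Align a fragment prefix end-to-end against the genome
#'
#' Returns every genome position (both strands) where the first `length`
#' bases of the fragment align end-to-end with Hamming distance at most
#' `maxMismatches` (no indels). Reverse-strand hits are reported at the
#' genomic coordinate of the fragment's *first* base, so that forward and
#' reverse mappings address the same junction point.
#'
#' @param seq fragment sequence (character).
#' @param genome a [GenomeIndex-class] with sequences loaded.
#' @param length prefix length to align; defaults to the full fragment.
#' @param maxMismatches maximum Hamming mismatches.
#' @return `data.frame` with columns `chrom`, `pos` (0-based coordinate of the
#'   fragment's first base), `strand` (`"+"`/`"-"`), `mismatches`.
#' @export
alignPrefix <- function(seq, genome, length = nchar(seq), maxMismatches = 0L) {
  if (length > nchar(seq))
    stop("prefix length exceeds fragment length")
  if (!base::length(genome@seqs))
    stop("genome index has no sequences; use the SAM adapter instead")
  pat <- DNAString(substr(seq, 1L, length))
  rcp <- reverseComplement(pat)
  out <- vector("list", 2L * base::length(genome@seqs))
  k <- 0L
  for (chrom in names(genome@seqs)) {
    subject <- genome@seqs[[chrom]]
    mf <- matchPattern(pat, subject, max.mismatch = maxMismatches,
                       with.indels = FALSE)
    if (base::length(mf)) {
      k <- k + 1L
      out[[k]] <- data.frame(
        chrom = chrom, pos = start(mf) - 1L, strand = "+",
        mismatches = neditStartingAt(pat, subject, starting.at = start(mf)),
        stringsAsFactors = FALSE)
    }
    mr <- matchPattern(rcp, subject, max.mismatch = maxMismatches,
                       with.indels = FALSE)
    if (base::length(mr)) {
      k <- k + 1L
      out[[k]] <- data.frame(
        chrom = chrom, pos = end(mr) - 1L, strand = "-",
        mismatches = neditStartingAt(rcp, subject, starting.at = start(mr)),
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(k)])
}

# Batch Hamming alignment of many equal-contract patterns by pigeonhole
# seeding: each pattern contributes maxMismatches + 1 disjoint exact seeds
# (at least one must be mismatch-free in any qualifying alignment), seeds are
# located genome-wide in one Aho-Corasick pass per chromosome via matchPDict,
# and candidate positions are verified with a vectorised mismatch count.
# Returns the same hits as looping alignPrefix over `patterns`.
.alignBatch <- function(patterns, genome, maxMismatches) {
  m <- maxMismatches
  lens <- nchar(patterns)
  nSeeds <- m + 1L
  w0 <- min(lens) %/% nSeeds
  hits <- rep(list(NULL), length(patterns))
  hasN <- grepl("[^ACGT]", patterns)
  if (w0 < 4L || all(hasN)) {  # seeds too short to be selective; fall back
    for (i in seq_along(patterns))
      hits[[i]] <- alignPrefix(patterns[i], genome, lens[i], m)
    return(hits)
  }
  if (any(hasN)) {             # PDict needs a plain ACGT dictionary
    sub <- .alignBatch(patterns[!hasN], genome, m)
    hits[hasN] <- lapply(which(hasN), function(i)
      alignPrefix(patterns[i], genome, lens[i], m))
    hits[!hasN] <- sub
    return(hits)
  }
  offsets <- (seq_len(nSeeds) - 1L) * w0        # 0-based seed offsets
  buildSeeds <- function(pats) {
    seeds <- unlist(lapply(offsets, function(o)
      substr(pats, o + 1L, o + w0)), use.names = FALSE)
    list(dict = Biostrings::PDict(DNAStringSet(seeds)),
         pattern = rep(seq_along(pats), times = nSeeds),
         offset = rep(offsets, each = length(pats)))
  }
  rcPatterns <- as.character(reverseComplement(DNAStringSet(patterns)))
  rcSeedInfo <- buildSeeds(rcPatterns)
  fwSeedInfo <- buildSeeds(patterns)
  patDNA <- lapply(patterns, DNAString)
  rcpDNA <- lapply(rcPatterns, DNAString)

  for (chrom in names(genome@seqs)) {
    subject <- genome@seqs[[chrom]]
    clen <- length(subject)
    for (strand in c("+", "-")) {
      info <- if (strand == "+") fwSeedInfo else rcSeedInfo
      mi <- Biostrings::matchPDict(info$dict, subject)
      cnt <- S4Vectors::elementNROWS(mi)
      if (!sum(cnt)) next
      seedIdx <- rep(seq_along(cnt), cnt)
      starts <- unlist(IRanges::start(mi), use.names = FALSE)
      candPos <- starts - info$offset[seedIdx]      # 1-based pattern start
      candPat <- info$pattern[seedIdx]
      ok <- candPos >= 1L & candPos + lens[candPat] - 1L <= clen
      candPos <- candPos[ok]; candPat <- candPat[ok]
      if (!length(candPos)) next
      for (i in unique(candPat)) {
        pos <- sort(unique(candPos[candPat == i]))
        pat <- if (strand == "+") patDNA[[i]] else rcpDNA[[i]]
        mm <- neditStartingAt(pat, subject, starting.at = pos,
                              with.indels = FALSE)
        good <- mm <= m
        if (!any(good)) next
        df <- data.frame(
          chrom = chrom,
          pos = if (strand == "+") pos[good] - 1L
                else pos[good] + lens[i] - 2L,
          strand = strand, mismatches = mm[good],
          stringsAsFactors = FALSE)
        hits[[i]] <- rbind(hits[[i]], df)
      }
    }
  }
  lapply(hits, function(h) {
    if (is.null(h))
      data.frame(chrom = character(), pos = integer(), strand = character(),
                 mismatches = integer(), stringsAsFactors = FALSE)
    else h
  })
}

#' Map fragments with the iterative prefix schedule
#'
#' Fragments shorter than `minLength` bases are discarded outright. Each
#' remaining fragment tries the schedule stages in order, using the prefix of
#' the stage length (a stage is skipped when the fragment is shorter than its
#' prefix; the full-length stage applies only to fragments longer than 33 bp).
#' A fragment is mapped at the first stage yielding exactly one hit; two or
#' more hits retire it as a multimapper (shortening can only add hits, so
#' later stages cannot restore uniqueness); zero hits fall through to the
#' next stage.
#'
#' @param fragments collapsed fragment `data.frame` ([collapseDuplicates()]).
#' @param genome a [GenomeIndex-class] with sequences.
#' @param schedule mapping schedule (see [defaultSchedule()]).
#' @param minLength fragments shorter than this are discarded (default 24).
#' @return list with `mappings` (`data.frame`: library, directionalLibrary,
#'   side, seq, chrom, pos \[0-based\], strand, stage, mismatches, readCount)
#'   and `stats` (fragments/reads discarded as too short, multimapped,
#'   unmapped, mapped per stage).
#' @export
mapIteratively <- function(fragments, genome, schedule = defaultSchedule(),
                           minLength = 24L) {
  frags <- fragments
  len <- nchar(frags$seq)
  tooShort <- len < minLength
  stats <- list(
    too_short_fragments = sum(tooShort),
    too_short_reads = sum(frags$readCount[tooShort]),
    mapped_per_stage = integer(nrow(schedule)),
    multimapped_fragments = 0L,
    unmapped_fragments = 0L
  )
  frags <- frags[!tooShort, , drop = FALSE]
  n <- nrow(frags)
  state <- rep("active", n)       # active | mapped | multi
  res <- data.frame(chrom = rep(NA_character_, n), pos = NA_integer_,
                    strand = NA_character_, stage = NA_integer_,
                    mismatches = NA_integer_, stringsAsFactors = FALSE)
  len <- nchar(frags$seq)

  for (s in seq_len(nrow(schedule))) {
    plen <- schedule$prefixLength[s]
    mm <- schedule$maxMismatches[s]
    if (is.na(plen)) {
      idx <- which(state == "active" & len > 33L)
      prefix <- frags$seq[idx]
    } else {
      idx <- which(state == "active" & len >= plen)
      prefix <- substr(frags$seq[idx], 1L, plen)
    }
    if (!length(idx)) next
    pats <- unique(prefix)
    allHits <- .alignBatch(pats, genome, mm)
    for (pi in seq_along(pats)) {
      rows <- idx[prefix == pats[pi]]
      hits <- allHits[[pi]]
      if (nrow(hits) == 1L) {
        state[rows] <- "mapped"
        res$chrom[rows] <- hits$chrom
        res$pos[rows] <- hits$pos
        res$strand[rows] <- hits$strand
        res$stage[rows] <- s
        res$mismatches[rows] <- hits$mismatches
        stats$mapped_per_stage[s] <- stats$mapped_per_stage[s] + length(rows)
      } else if (nrow(hits) >= 2L) {
        state[rows] <- "multi"
      }
    }
  }
  stats$multimapped_fragments <- sum(state == "multi")
  stats$unmapped_fragments <- sum(state == "active")
  mapped <- state == "mapped"
  mappings <- cbind(frags[mapped, , drop = FALSE],
                    res[mapped, , drop = FALSE])
  rownames(mappings) <- NULL
  list(mappings = mappings, stats = stats)
}

#' Import external aligner output (SAM)
#'
#' Adapter for production-scale mapping through an external short-read
#' aligner: translates SAM records whose query names index the fragment table
#' into the same mapping table produced by [mapIteratively()]. Unmapped
#' records are excluded and query names with more than one aligned record are
#' dropped as multimappers. Reverse-strand records are converted so `pos` is
#' the 0-based genomic coordinate of the fragment's first base.
#'
#' @param path SAM file (with `@SQ` headers).
#' @param fragments fragment `data.frame`; query names must be
#'   `fragments$id` if present, else the row index as a character.
#' @param stage stage index recorded on the imported mappings (default `NA`).
#' @return mapping `data.frame` as in [mapIteratively()] (without mismatch
#'   counts, which SAM does not carry directly; `mismatches` is `NA`).
#' @export
importSAM <- function(path, fragments, stage = NA_integer_) {
  ids <- if (!is.null(fragments$id)) as.character(fragments$id)
         else as.character(seq_len(nrow(fragments)))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "strand",
                                        "pos", "qwidth"))
  rec <- Rsamtools::scanBam(bam, param = p)[[1L]]
  aligned <- !bitwAnd(rec$flag, 4L) & !is.na(rec$pos)
  qname <- rec$qname[aligned]
  multi <- qname %in% qname[duplicated(qname)]
  keep <- which(aligned)[!multi]
  qname <- rec$qname[keep]
  unknown <- !(qname %in% ids)
  if (any(unknown))
    stop("unknown fragment id(s) in SAM: ",
         paste(utils::head(unique(qname[unknown]), 3L), collapse = ", "))
  fidx <- match(qname, ids)
  strand <- as.character(rec$strand[keep])
  pos0 <- ifelse(strand == "-",
                 rec$pos[keep] - 1L + rec$qwidth[keep] - 1L,
                 rec$pos[keep] - 1L)
  out <- cbind(fragments[fidx, setdiff(colnames(fragments), "id"),
                         drop = FALSE],
               data.frame(chrom = as.character(rec$rname[keep]),
                          pos = as.integer(pos0), strand = strand,
                          stage = stage, mismatches = NA_integer_,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Estimate the random (false) unique-mapping rate
#'
#' Generates `n` uniform random ACGT sequences of the given length, aligns
#' them with [alignPrefix()], and returns the fraction that map uniquely.
#' Used to validate length/mismatch cutoffs on a given genome: at the default
#' schedule's cutoffs this fraction should be ~0, and it rises steeply for
#' shorter or more permissive settings.
#'
#' @param n number of random sequences (>= 1).
#' @param length sequence length in bp.
#' @param maxMismatches Hamming mismatch allowance.
#' @param genome a [GenomeIndex-class] with sequences.
#' @param seed RNG seed.
#' @return list with `uniqueFraction`, `anyHitFraction` and `n`.
#' @export
estimateFalseMappingRate <- function(n, length, maxMismatches, genome,
                                     seed = 1L) {
  if (n < 1L) stop("n must be >= 1")
  rng <- .withSeed(seed)
  on.exit(rng())
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""), character(1L))
  hits <- vapply(seqs, function(s)
    nrow(alignPrefix(s, genome, length = length,
                     maxMismatches = maxMismatches)), integer(1L))
  list(uniqueFraction = mean(hits == 1L),
       anyHitFraction = mean(hits >= 1L), n = n)
}

# Set the RNG seed locally; returns a restorer function.
.withSeed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}
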