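#' Upper-tail Poisson probability
#'
#' P(X >= x) for X ~ Poisson(u): the enrichment p-value of observing x or
#' more insertion events in a window whose expected event count is
#' u = N * windowSize / genomeSize.
#'
#' @param x observed event count (non-negative integer, vectorised).
#' @param u expected event count (> 0).
#' @return probability in (0, 1]; `x = 0` gives exactly 1.
#' @examples
#' poissonUpperTail(1, 1)   # 1 - exp(-1)
#' @export
poissonUpperTail <- function(x, u) {
  stopifnot(all(x >= 0), all(u > 0))
  stats::ppois(x - 1, lambda = u, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param p raw p-value(s).
#' @param nWindows number of windows examined (the total number of
#'   insertions); must be >= 1.
#' @return `min(1, p * nWindows)`, vectorised.
#' @export
bonferroniCorrect <- function(p, nWindows) {
  stopifnot(nWindows >= 1)
  pmin(1, p * nWindows)
}

# Smallest integer count k whose Bonferroni-corrected tail probability is
# below alpha, for expected count u and multiplier n. Floored at 2: a site
# with a single insertion is never "common", however small the corrected
# probability of one event may be at low totals.
#
# conditional = TRUE (the scan's significance rule) scores a window holding
# k events by the tail of the k - 1 events beyond its anchor: candidate
# windows are anchored at insertions, so every window contains one event by
# construction and P(X >= k) would overstate its surprise by exactly that
# event. conditional = FALSE is the plain tail, used to pick the
# window-size plan.
.minSignificantCount <- function(u, n, alpha, conditional = TRUE) {
  off <- if (conditional) 1L else 0L
  k <- 2L
  while (bonferroniCorrect(poissonUpperTail(k - off, u), n) >= alpha) {
    k <- k + 1L
    if (k > 1e7) stop("no significant count found; check configuration")
  }
  k
}

#' Determine the window sizes for a scan
#'
#' For each integer event count k, the plan keeps the largest window size in
#' the search grid at which k events are still significant (corrected
#' p < alpha); the distinct resulting sizes are scanned in decreasing order.
#' When the total event count is below `smallN` or above `largeN` the fixed
#' default window list is used instead.
#'
#' @param totalEvents total number of insertion events in the analysis set.
#' @param config a [ScanConfig-class].
#' @return numeric vector of window sizes in bp, decreasing.
#' @examples
#' determineWindowSizes(1500, scanConfig(genomeSize = 2.5e9))
#' @export
determineWindowSizes <- function(totalEvents, config) {
  stopifnot(totalEvents >= 0)
  if (totalEvents < config@smallN || totalEvents > config@largeN)
    return(sort(config@defaultWindows, decreasing = TRUE))
  ws <- seq(config@wMin, config@wMax, by = config@wStep)
  kmin <- vapply(ws, function(w)
    .minSignificantCount(totalEvents * w / config@genomeSize,
                         totalEvents, config@alpha, conditional = FALSE),
    integer(1L))
  # largest window per achievable integer count
  keep <- vapply(split(ws, kmin), max, numeric(1L))
  sort(unname(keep), decreasing = TRUE)
}

# Per-chromosome sorted 0-based event bin starts plus per-event columns used
# by the counting modes.
.eventFrame <- function(events) {
  data.frame(chrom = as.character(seqnames(events)),
             pos = start(events) - 1L,
             orientation = as.character(strand(events)),
             library = events$library,
             stringsAsFactors = FALSE)
}

#' Count events in a window under a counting scheme
#'
#' The three schemes test three null hypotheses: `insert` counts unique
#' insertion events (library x bin x orientation); `library` counts unique
#' contributing libraries; `region` counts unique 100-bp tiles regardless of
#' library and orientation.
#'
#' @param chrom,start,end window interval, 0-based half-open.
#' @param events event `GRanges` (or the `data.frame` from internal use).
#' @param countMode `"insert"`, `"library"` or `"region"`.
#' @return integer count.
#' @export
countEvents <- function(chrom, start, end, events,
                        countMode = c("insert", "library", "region")) {
  countMode <- match.arg(countMode)
  ef <- if (is.data.frame(events)) events else .eventFrame(events)
  inWin <- ef$chrom == chrom & ef$pos >= start & ef$pos < end
  switch(countMode,
         insert = sum(inWin),
         library = length(unique(ef$library[inWin])),
         region = length(unique(ef$pos[inWin])))
}

#' Scan one window size for peak windows
#'
#' Candidate windows are anchored at every event position (window =
#' `[bin_start, bin_start + windowSize)`). Windows are scored by the chosen
#' counting scheme, then non-overlapping peaks are selected greedily: take
#' the remaining window with the highest count (ties broken by lowest
#' genomic coordinate), discard everything overlapping it, repeat. Only
#' windows whose Bonferroni-corrected upper-tail Poisson probability is below
#' alpha are returned, and a window must hold at least two events — a single
#' insertion is never a *common* insertion site, however small its corrected
#' probability at low event totals.
#'
#' The p-value of a window holding x events is the upper tail of the x - 1
#' events beyond its anchor, `poissonUpperTail(x - 1, u)`: anchored windows
#' contain one insertion by construction, so the plain tail of x would
#' overstate their surprise by that event (and uniform random insertions
#' would spuriously reach significance). The Bonferroni multiplier is the
#' total number of windows examined: the number of insertions, times
#' `nWindowSizes` when the scan is part of a multi-window-size analysis.
#'
#' @param events event `GRanges`.
#' @param windowSize window size in bp.
#' @param config a [ScanConfig-class].
#' @param countMode counting scheme for the peak scores (default insert).
#' @param totals optional precomputed list (nInserts, nRegions); derived from
#'   `events` when omitted.
#' @param nWindowSizes number of window sizes in the surrounding analysis
#'   (contributes to the count of windows examined; 1 for a standalone scan).
#' @return `data.frame` of candidate windows: chrom, start, end (0-based
#'   half-open), windowSize, count, pRaw, pCorrected.
#' @export
findPeaks <- function(events, windowSize, config,
                      countMode = c("insert", "library", "region"),
                      totals = NULL, nWindowSizes = 1L) {
  countMode <- match.arg(countMode)
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), windowSize = numeric(),
                      count = integer(), pRaw = numeric(),
                      pCorrected = numeric(), stringsAsFactors = FALSE)
  if (!length(events)) return(empty)
  ef <- .eventFrame(events)
  if (is.null(totals))
    totals <- list(nInserts = nrow(ef),
                   nRegions = length(unique(paste(ef$chrom, ef$pos))))
  nCorr <- totals$nInserts * nWindowSizes
  nTotal <- switch(countMode, insert = totals$nInserts,
                   library = totals$nInserts, region = totals$nRegions)
  u <- nTotal * windowSize / config@genomeSize
  kmin <- .minSignificantCount(u, nCorr, config@alpha)

  chromLevels <- unique(ef$chrom)
  cand <- vector("list", length(chromLevels))
  for (ci in seq_along(chromLevels)) {
    ee <- ef[ef$chrom == chromLevels[ci], , drop = FALSE]
    ee <- ee[order(ee$pos), , drop = FALSE]
    anchors <- unique(ee$pos)
    if (countMode == "insert") {
      counts <- findInterval(anchors + windowSize - 0.5, ee$pos) -
        findInterval(anchors - 0.5, ee$pos)
    } else {
      counts <- vapply(anchors, function(a)
        countEvents(chromLevels[ci], a, a + windowSize, ee, countMode),
        integer(1L))
    }
    sig <- counts >= kmin
    if (!any(sig)) next
    cand[[ci]] <- data.frame(chrom = chromLevels[ci], start = anchors[sig],
                             count = counts[sig], chromIdx = ci,
                             stringsAsFactors = FALSE)
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand)) return(empty)
  cand <- cand[order(-cand$count, cand$chromIdx, cand$start), , drop = FALSE]
  selected <- logical(nrow(cand))
  blocked <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (blocked[i]) next
    selected[i] <- TRUE
    overlap <- !blocked & cand$chromIdx == cand$chromIdx[i] &
      cand$start < cand$start[i] + windowSize &
      cand$start + windowSize > cand$start[i]
    blocked[overlap] <- TRUE
  }
  sel <- cand[selected, , drop = FALSE]
  pRaw <- poissonUpperTail(sel$count - 1L, u)
  out <- data.frame(chrom = sel$chrom, start = sel$start,
                    end = sel$start + windowSize, windowSize = windowSize,
                    count = sel$count, pRaw = pRaw,
                    pCorrected = bonferroniCorrect(pRaw, nCorr),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Resolve overlapping candidates across window sizes
#'
#' Pools the per-window-size candidates and greedily selects the minimal set
#' of non-overlapping regions with the most significant probability:
#' ascending raw p-value; on an exact p tie the larger window wins; remaining
#' ties fall to the lowest genomic coordinate for determinism.
#'
#' @param candidates `data.frame` as returned by [findPeaks()], pooled over
#'   window sizes.
#' @return subset of `candidates`, pairwise non-overlapping.
#' @export
resolveAcrossWindowSizes <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  o <- order(candidates$pRaw, -candidates$windowSize, candidates$chrom,
             candidates$start)
  cand <- candidates[o, , drop = FALSE]
  selected <- logical(nrow(cand))
  blocked <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (blocked[i]) next
    selected[i] <- TRUE
    overlap <- !blocked & cand$chrom == cand$chrom[i] &
      cand$start < cand$end[i] & cand$end > cand$start[i]
    blocked[overlap] <- TRUE
  }
  out <- cand[selected, , drop = FALSE]
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Call Common Insertion Sites
#'
#' Full Poisson scan: the window-size plan is determined from the total
#' insert-event count, every size is scanned with insert-count peak finding,
#' overlapping candidates are resolved across sizes, and each final window is
#' scored under all three counting schemes. The expected count u for the
#' insert and library schemes uses the total number of insert events; the
#' region scheme uses the total number of distinct 100-bp regions
#' genome-wide. All three p-values are anchor-conditional tails (see
#' [findPeaks()]) Bonferroni-corrected by the total number of windows
#' examined — the insert-event count times the number of window sizes
#' scanned. By default a CIS must be significant under all three schemes;
#' set any alpha to `NA` to drop that requirement.
#'
#' @param events event `GRanges` (post-cutoff, post-exclusion), or an
#'   [InsertionScreen-class].
#' @param config a [ScanConfig-class]. When `events` is a screen with known
#'   chromosome sizes and `config` is omitted, the genome size is the sum of
#'   the non-excluded chromosome lengths.
#' @param alphaInsert,alphaLibrary,alphaRegion per-scheme reporting
#'   thresholds on the corrected p-values (default `config@alpha`; `NA`
#'   disables a requirement).
#' @return a [CISSet-class], sorted by ascending region p then insert p.
#' @export
callCIS <- function(events, config = NULL, alphaInsert = NULL,
                    alphaLibrary = NULL, alphaRegion = NULL) {
  if (is(events, "InsertionScreen")) {
    if (is.null(config)) {
      if (!length(events@chromSizes))
        stop("screen lacks chromosome sizes; supply a ScanConfig")
      keep <- names(events@chromSizes) %in%
        GenomeInfoDb::seqlevels(insertEvents(events))
      config <- scanConfig(genomeSize = sum(events@chromSizes[keep]))
    }
    events <- insertEvents(events)
  }
  stopifnot(is(config, "ScanConfig"))
  if (is.null(alphaInsert)) alphaInsert <- config@alpha
  if (is.null(alphaLibrary)) alphaLibrary <- config@alpha
  if (is.null(alphaRegion)) alphaRegion <- config@alpha

  emptySet <- new("CISSet", ranges = GRanges(),
                  totals = list(nInserts = length(events), nRegions = 0L,
                                genomeSize = config@genomeSize,
                                alpha = config@alpha,
                                windowSizes = numeric()))
  if (!length(events)) return(emptySet)
  ef <- .eventFrame(events)
  totals <- list(nInserts = nrow(ef),
                 nRegions = length(unique(paste(ef$chrom, ef$pos))))
  plan <- determineWindowSizes(totals$nInserts, config)
  cands <- do.call(rbind, lapply(plan, function(w)
    findPeaks(events, w, config, countMode = "insert", totals = totals,
              nWindowSizes = length(plan))))
  if (is.null(cands) || !nrow(cands)) {
    emptySet@totals$nRegions <- totals$nRegions
    emptySet@totals$windowSizes <- plan
    return(emptySet)
  }
  final <- resolveAcrossWindowSizes(cands)

  n <- nrow(final)
  insertCount <- integer(n); libCount <- integer(n); regCount <- integer(n)
  nPos <- integer(n); libs <- character(n)
  for (i in seq_len(n)) {
    inWin <- ef$chrom == final$chrom[i] & ef$pos >= final$start[i] &
      ef$pos < final$end[i]
    insertCount[i] <- sum(inWin)
    libCount[i] <- length(unique(ef$library[inWin]))
    regCount[i] <- length(unique(ef$pos[inWin]))
    nPos[i] <- sum(ef$orientation[inWin] == "+")
    libs[i] <- paste(sort(unique(ef$library[inWin])), collapse = ",")
  }
  uIns <- totals$nInserts * final$windowSize / config@genomeSize
  uReg <- totals$nRegions * final$windowSize / config@genomeSize
  nCorr <- totals$nInserts * length(plan)
  pIns <- bonferroniCorrect(poissonUpperTail(insertCount - 1L, uIns), nCorr)
  pLib <- bonferroniCorrect(poissonUpperTail(libCount - 1L, uIns), nCorr)
  pReg <- bonferroniCorrect(poissonUpperTail(regCount - 1L, uReg), nCorr)
  keep <- (is.na(alphaInsert) | pIns < alphaInsert) &
    (is.na(alphaLibrary) | pLib < alphaLibrary) &
    (is.na(alphaRegion) | pReg < alphaRegion)

  gr <- GRanges(seqnames = final$chrom[keep],
                ranges = IRanges(start = final$start[keep] + 1L,
                                 end = final$end[keep]),
                windowSize = final$windowSize[keep],
                insertCount = insertCount[keep],
                libraryCount = libCount[keep],
                regionCount = regCount[keep],
                pInsert = pIns[keep], pLibrary = pLib[keep],
                pRegion = pReg[keep],
                libraries = libs[keep], nPosStrand = nPos[keep],
                annotation = rep("", sum(keep)))
  o <- order(gr$pRegion, gr$pInsert)
  new("CISSet", ranges = gr[o],
      totals = list(nInserts = totals$nInserts, nRegions = totals$nRegions,
                    genomeSize = config@genomeSize, alpha = config@alpha,
                    windowSizes = plan))
}
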