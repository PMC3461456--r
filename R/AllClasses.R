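#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- queryHits subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom Biostrings DNAString DNAStringSet matchPattern reverseComplement
#'   readDNAStringSet writeXStringSet neditStartingAt
#' @importFrom GenomeInfoDb seqlevels seqlevels<-
NULL

#' Trimming configuration
#'
#' Holds the sequences and rules used to reduce a raw barcoded read to its
#' endogenous genomic fragment: the transposon terminal-repeat tag (IRDR for
#' Sleeping Beauty screens, LTR for proviral screens) expected immediately
#' after the barcode, the ligation linker whose first occurrence truncates the
#' 3' end, whether the genomic fragment must start with the TA dinucleotide
#' characteristic of SB integration, and how many barcode mismatches to
#' tolerate (0 by default; N never matches).
#'
#' @slot transposonTag DNA string expected directly after the barcode.
#' @slot linker ligation adapter/linker DNA string (may be empty).
#' @slot requireTA logical; require the genomic fragment to start with "TA".
#' @slot barcodeMismatches integer; maximum Hamming mismatches in the barcode.
#' @exportClass TrimConfig
setClass("TrimConfig", representation(
  transposonTag = "character",
  linker = "character",
  requireTA = "logical",
  barcodeMismatches = "integer"
))

setValidity("TrimConfig", function(object) {
  msg <- character()
  if (length(object@transposonTag) != 1L || !nzchar(object@transposonTag))
    msg <- c(msg, "transposonTag must be a single non-empty DNA string")
  if (!grepl("^[ACGTN]*$", object@transposonTag))
    msg <- c(msg, "transposonTag must use the ACGTN alphabet")
  if (length(object@linker) != 1L || !grepl("^[ACGTN]*$", object@linker))
    msg <- c(msg, "linker must be a single (possibly empty) ACGTN string")
  if (object@barcodeMismatches < 0L)
    msg <- c(msg, "barcodeMismatches must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a trimming configuration
#'
#' @param transposonTag DNA string expected immediately after the barcode
#'   (transposon IRDR / retroviral LTR terminal sequence).
#' @param linker ligation linker sequence; the genomic fragment is truncated at
#'   its first occurrence. Empty string disables linker trimming.
#' @param requireTA require the genomic fragment to start with "TA"
#'   (Sleeping Beauty integrates into TA dinucleotides).
#' @param barcodeMismatches maximum Hamming mismatches allowed when matching
#'   the barcode at the 5' end (default 0, exact matching).
#' @return A [TrimConfig-class] object.
#' @examples
#' trimConfig("GTGTATGT", linker = "CTAGACCGGT")
#' @export
trimConfig <- function(transposonTag, linker = "", requireTA = TRUE,
                       barcodeMismatches = 0L) {
  new("TrimConfig", transposonTag = toupper(transposonTag),
      linker = toupper(linker), requireTA = isTRUE(requireTA),
      barcodeMismatches = as.integer(barcodeMismatches))
}

setMethod("show", "TrimConfig", function(object) {
  cat("TrimConfig\n")
  cat("  transposonTag:", object@transposonTag, "\n")
  cat("  linker:", if (nzchar(object@linker)) object@linker else "<none>", "\n")
  cat("  requireTA:", object@requireTA,
      " barcodeMismatches:", object@barcodeMismatches, "\n")
})

#' CIS scan configuration
#'
#' Parameters of the Poisson scan. The expected event count for a window of
#' size w is u = N * w / G where N is the total number of events of the
#' relevant type and G the genome size (sum of the included chromosome
#' lengths). Raw upper-tail Poisson probabilities are Bonferroni-corrected by
#' the total number of windows examined, i.e. the total number of insertions.
#'
#' @slot genomeSize genome size in bp over the chromosomes included in the
#'   analysis.
#' @slot alpha significance level applied to corrected p-values (default 0.05).
#' @slot wMin,wMax,wStep window-size search grid in bp (10,000 to 301,000 in
#'   1,000-bp steps by default).
#' @slot defaultWindows window sizes used when the total insertion count is
#'   outside [smallN, largeN].
#' @slot smallN,largeN bounds on the total insertion count for the computed
#'   window-size plan; outside them `defaultWindows` is used.
#' @slot binSize insertion bin width in bp (100).
#' @exportClass ScanConfig
setClass("ScanConfig", representation(
  genomeSize = "numeric",
  alpha = "numeric",
  wMin = "numeric",
  wMax = "numeric",
  wStep = "numeric",
  defaultWindows = "numeric",
  smallN = "numeric",
  largeN = "numeric",
  binSize = "numeric"
))

setValidity("ScanConfig", function(object) {
  msg <- character()
  if (length(object@genomeSize) != 1L || object@genomeSize <= 0)
    msg <- c(msg, "genomeSize must be a single positive number")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (object@wMin > object@wMax) msg <- c(msg, "wMin must be <= wMax")
  if (object@wStep <= 0) msg <- c(msg, "wStep must be positive")
  if (any(object@defaultWindows <= 0)) msg <- c(msg, "defaultWindows must be positive")
  if (object@binSize <= 0) msg <- c(msg, "binSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Create a CIS scan configuration
#'
#' @param genomeSize genome size in bp (sum of included chromosome lengths;
#'   default 2.5e9, the approximate mappable mouse genome).
#' @param alpha significance level for Bonferroni-corrected p-values.
#' @param wMin,wMax,wStep window-size search grid in bp.
#' @param defaultWindows fallback window sizes used when the total event count
#'   lies outside `[smallN, largeN]`.
#' @param smallN,largeN event-count bounds for the computed window plan.
#' @param binSize insertion bin width in bp.
#' @return A [ScanConfig-class] object.
#' @examples
#' scanConfig(genomeSize = 2.5e9)
#' @export
scanConfig <- function(genomeSize = 2.5e9, alpha = 0.05,
                       wMin = 10000, wMax = 301000, wStep = 1000,
                       defaultWindows = c(12500, 25000, 50000, 100000,
                                          200000, 301000),
                       smallN = 2000, largeN = 200000, binSize = 100) {
  new("ScanConfig", genomeSize = genomeSize, alpha = alpha, wMin = wMin,
      wMax = wMax, wStep = wStep, defaultWindows = defaultWindows,
      smallN = smallN, largeN = largeN, binSize = binSize)
}

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig\n")
  cat("  genomeSize:", format(object@genomeSize, big.mark = ","),
      " alpha:", object@alpha, "\n")
  cat("  window grid:", object@wMin, "-", object@wMax, "step", object@wStep, "\n")
  cat("  defaultWindows:", paste(object@defaultWindows, collapse = ", "), "\n")
  cat("  computed plan for", object@smallN, "-", object@largeN,
      "events; binSize:", object@binSize, "\n")
})

#' Reference genome index
#'
#' Chromosome names and lengths, optionally with the sequences themselves.
#' Sequences are required by the built-in aligner and the simulator; analyses
#' that only need the genome size (e.g. the Poisson scan) work from the
#' lengths alone.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of chromosome sequences, possibly
#'   empty when only sizes are known.
#' @slot sizes named numeric vector of chromosome lengths in bp.
#' @exportClass GenomeIndex
setClass("GenomeIndex", representation(
  seqs = "DNAStringSet",
  sizes = "numeric"
))

setValidity("GenomeIndex", function(object) {
  msg <- character()
  if (is.null(names(object@sizes)) || anyDuplicated(names(object@sizes)))
    msg <- c(msg, "chromosome names must be present and unique")
  if (any(object@sizes <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
  if (length(object@seqs) &&
      !identical(unname(Biostrings::width(object@seqs)), unname(as.integer(object@sizes))))
    msg <- c(msg, "sequence lengths disagree with the sizes table")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeIndex", function(object) {
  cat("GenomeIndex with", length(object@sizes), "chromosome(s),",
      format(sum(object@sizes), big.mark = ","), "bp total",
      if (length(object@seqs)) "(sequences loaded)\n" else "(sizes only)\n")
})

#' @describeIn GenomeIndex-class total genome size in bp.
#' @param x,object a `GenomeIndex`.
#' @export
genomeSize <- function(x) sum(x@sizes)

#' @describeIn GenomeIndex-class named chromosome lengths.
#' @export
chromSizes <- function(x) x@sizes

#' @describeIn GenomeIndex-class chromosome sequences as a `DNAStringSet`.
#' @export
genomeSeqs <- function(x) x@seqs

#' An insertional mutagenesis screen (project)
#'
#' Container for one project: the demultiplexed collapsed fragments, their
#' genome mappings, the orientation-resolved binned insertion events, per-library
#' read totals, read-rejection accounting, and the library metadata groups used
#' for association testing.
#'
#' @slot project project name.
#' @slot fragments `data.frame` of collapsed fragments (library, side,
#'   directionalLibrary, seq, readCount).
#' @slot mappings `data.frame` of unique genome mappings (library, side, chrom,
#'   pos \[0-based first genomic base 3' of the transposon\], strand, stage,
#'   mismatches, readCount).
#' @slot events [GenomicRanges::GRanges] of 100-bp insertion bins; strand holds
#'   the biological orientation, mcols hold library, readCount, nRawPositions.
#' @slot libraryStats `data.frame` with per-library totalMappedReads/totalEvents.
#' @slot rejectionStats named numeric read-accounting vector.
#' @slot metadata named list of library groups (must include the superset
#'   group `"all"` when used for associations).
#' @slot chromSizes named chromosome lengths used for mapping, if known.
#' @exportClass InsertionScreen
setClass("InsertionScreen", representation(
  project = "character",
  fragments = "data.frame",
  mappings = "data.frame",
  events = "GRanges",
  libraryStats = "data.frame",
  rejectionStats = "numeric",
  metadata = "list",
  chromSizes = "numeric"
))

setMethod("show", "InsertionScreen", function(object) {
  cat("InsertionScreen \"", object@project, "\"\n", sep = "")
  cat("  fragments:", nrow(object@fragments),
      " mappings:", nrow(object@mappings),
      " events:", length(object@events), "\n")
  if (nrow(object@libraryStats))
    cat("  libraries:", nrow(object@libraryStats), "\n")
  if (length(object@rejectionStats))
    cat("  reads in:", object@rejectionStats[["input"]],
        " assigned:", object@rejectionStats[["assigned"]], "\n")
})

#' @describeIn InsertionScreen-class collapsed fragment table.
#' @param x an `InsertionScreen`.
#' @export
fragments <- function(x) x@fragments

#' @describeIn InsertionScreen-class unique genome mappings.
#' @export
screenMappings <- function(x) x@mappings

#' @describeIn InsertionScreen-class binned insertion events (`GRanges`).
#' @export
insertEvents <- function(x) x@events

#' @describeIn InsertionScreen-class per-library read/event totals.
#' @export
screenLibraryStats <- function(x) x@libraryStats

#' @describeIn InsertionScreen-class read-rejection accounting.
#' @export
rejectionStats <- function(x) x@rejectionStats

#' @describeIn InsertionScreen-class library metadata groups.
#' @export
screenMetadata <- function(x) x@metadata

#' A set of Common Insertion Sites
#'
#' Result of the Poisson scan: non-overlapping genomic windows enriched for
#' insertion events, each scored under the three counting schemes (unique
#' insert events, unique libraries, unique 100-bp regions) with
#' Bonferroni-corrected upper-tail Poisson p-values.
#'
#' @slot ranges `GRanges` of the CIS windows; mcols carry windowSize,
#'   insertCount, libraryCount, regionCount, pInsert, pLibrary, pRegion,
#'   libraries (comma-joined), nPosStrand and annotation.
#' @slot totals list with the scan environment: nInserts, nRegions, genomeSize,
#'   alpha and the window-size plan.
#' @exportClass CISSet
setClass("CISSet", representation(
  ranges = "GRanges",
  totals = "list"
))

setValidity("CISSet", function(object) {
  gr <- object@ranges
  if (!length(gr)) return(TRUE)
  msg <- character()
  need <- c("windowSize", "insertCount", "libraryCount", "regionCount",
            "pInsert", "pLibrary", "pRegion", "libraries", "nPosStrand")
  if (!all(need %in% colnames(mcols(gr))))
    return(paste("missing CIS columns:",
                 paste(setdiff(need, colnames(mcols(gr))), collapse = ", ")))
  ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  if (any(queryHits(ov) != subjectHits(ov)))
    msg <- c(msg, "CIS intervals must be pairwise non-overlapping")
  if (any(mcols(gr)$regionCount > mcols(gr)$insertCount))
    msg <- c(msg, "regionCount must be <= insertCount")
  if (any(mcols(gr)$libraryCount > mcols(gr)$insertCount))
    msg <- c(msg, "libraryCount must be <= insertCount")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CISSet", function(object) {
  cat("CISSet with", length(object@ranges), "CIS(s)\n")
  cat("  scan: nInserts =", object@totals$nInserts,
      " nRegions =", object@totals$nRegions,
      " genomeSize =", format(object@totals$genomeSize, big.mark = ","), "\n")
  if (length(object@ranges)) {
    df <- utils::head(cisTable(object), 5L)
    print(df[, c("chrom", "start", "end", "insertCount", "libraryCount",
                 "regionCount", "pInsert", "pLibrary", "pRegion")])
    if (length(object@ranges) > 5L) cat("  ...\n")
  }
})

#' @describeIn CISSet-class the CIS windows as a `GRanges`.
#' @param x a `CISSet`.
#' @export
cisRanges <- function(x) x@ranges

#' @describeIn CISSet-class scan totals (nInserts, nRegions, genomeSize,
#'   alpha, windowSizes).
#' @export
cisTotals <- function(x) x@totals

#' @describeIn CISSet-class the CIS table as a `data.frame` with 0-based
#'   half-open start/end coordinates.
#' @export
cisTable <- function(x) {
  gr <- x@ranges
  df <- data.frame(
    chrom = as.character(seqnames(gr)),
    start = start(gr) - 1L,
    end = end(gr),
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(mcols(gr)))
}

#' @describeIn CISSet-class number of CISs.
#' @export
setMethod("length", "CISSet", function(x) length(x@ranges))
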