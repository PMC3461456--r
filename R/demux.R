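#' Read raw sequence reads
#'
#' Accepts FASTA, FASTQ or a 2-column tab-delimited file (identifier,
#' sequence). Sequences are upper-cased; reads containing characters outside
#' the ACGTN alphabet are dropped with a warning that reports how many.
#'
#' @param path input file.
#' @param format one of `"auto"`, `"fasta"`, `"fastq"`, `"tab"`. `"auto"`
#'   inspects the first character (`>` FASTA, `@` FASTQ, otherwise tab).
#' @return `data.frame` with columns `id`, `seq`, `count` (all 1 on input;
#'   the count column lets callers carry pre-collapsed multiplicities).
#' @export
readReads <- function(path, format = c("auto", "fasta", "fastq", "tab")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- substr(readLines(path, n = 1L), 1L, 1L)
    format <- if (first == ">") "fasta" else if (first == "@") "fastq" else "tab"
  }
  if (format %in% c("fasta", "fastq")) {
    ss <- readDNAStringSet(path, format = format)
    reads <- data.frame(id = names(ss), seq = as.character(ss),
                        stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2L) stop("tab-delimited read file needs >= 2 columns")
    reads <- data.frame(id = tab[[1L]], seq = tab[[2L]],
                        stringsAsFactors = FALSE)
  }
  reads$seq <- toupper(reads$seq)
  reads$count <- 1
  bad <- !grepl("^[ACGTN]+$", reads$seq)
  if (any(bad)) {
    warning(sum(bad), " read(s) dropped: empty or non-ACGTN sequence")
    reads <- reads[!bad, , drop = FALSE]
  }
  rownames(reads) <- NULL
  reads
}

.validateBarcodeSpecs <- function(df) {
  if (!nrow(df)) stop("barcode table is empty")
  df$barcode <- toupper(df$barcode)
  if (!all(grepl("^[ACGT]+$", df$barcode)))
    stop("barcodes must be non-empty ACGT strings")
  if (anyDuplicated(df$barcode))
    stop("duplicate barcode(s): ",
         paste(unique(df$barcode[duplicated(df$barcode)]), collapse = ", "))
  side <- tolower(df$side)
  if (!all(side %in% c("left", "right", "l", "r")))
    stop("side must be Left or Right")
  df$side <- ifelse(side %in% c("left", "l"), "left", "right")
  suffix <- toupper(substring(df$directionalLibrary,
                              nchar(df$directionalLibrary) - 1L))
  if (!all(suffix %in% c("-L", "-R")))
    stop("directional library names must end in -L or -R")
  if (any((suffix == "-L") != (df$side == "left")))
    stop("directional library suffix inconsistent with priming side")
  df$library <- substr(df$directionalLibrary, 1L,
                       nchar(df$directionalLibrary) - 2L)
  rownames(df) <- NULL
  df
}

#' Read and validate a barcode table
#'
#' The table maps each barcode to a directional library name (ending in `-L`
#' or `-R` according to the side of the insertion that was primed) and the
#' priming side. Barcodes must be unique within a project and the name suffix
#' must agree with the side.
#'
#' @param path tab-delimited file with >= 3 columns: barcode, directional
#'   library name, side (Left/Right). A header row is detected and skipped
#'   when the first field is not a DNA string.
#' @return validated `data.frame` with columns `barcode`,
#'   `directionalLibrary`, `side` (`"left"`/`"right"`) and `library` (suffix
#'   stripped).
#' @export
readBarcodeTable <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!nrow(tab)) stop("barcode table is empty")
  if (ncol(tab) < 3L) stop("barcode table needs >= 3 columns")
  if (!grepl("^[ACGTacgt]+$", tab[1L, 1L])) tab <- tab[-1L, , drop = FALSE]
  barcodeSpecs(tab[[1L]], tab[[2L]], tab[[3L]])
}

#' Build barcode specifications from vectors
#'
#' @param barcode DNA barcode strings (unique, ACGT).
#' @param directionalLibrary library names ending in `-L`/`-R`.
#' @param side priming side, `"Left"` or `"Right"`.
#' @return validated barcode `data.frame`; see [readBarcodeTable()].
#' @examples
#' barcodeSpecs("ACGTAC", "tum1-R", "Right")
#' @export
barcodeSpecs <- function(barcode, directionalLibrary, side) {
  .validateBarcodeSpecs(data.frame(
    barcode = as.character(barcode),
    directionalLibrary = as.character(directionalLibrary),
    side = as.character(side), stringsAsFactors = FALSE))
}

# Hamming mismatch count of `pattern` against the length-matched prefix of
# each sequence; N (on either side) never matches.
.prefixMismatches <- function(seqs, pattern) {
  k <- nchar(pattern)
  mm <- integer(length(seqs))
  pat <- strsplit(pattern, "")[[1L]]
  for (i in seq_len(k)) {
    ci <- substr(seqs, i, i)
    mm <- mm + as.integer(ci != pat[i] | ci == "N" | pat[i] == "N")
  }
  mm[nchar(seqs) < k] <- NA_integer_
  mm
}

#' Demultiplex and trim barcoded junction-fragment reads
#'
#' Each read is expected to be barcode + transposon tag + genomic sequence,
#' possibly followed by the ligation linker and downstream bases. The barcode
#' is matched at the 5' end (exact by default; up to
#' `config@barcodeMismatches` Hamming mismatches, ties between barcodes
#' rejected), the transposon tag must follow exactly, the remainder is the
#' genomic fragment, truncated at the first occurrence of the linker if
#' present. With `requireTA`, fragments not starting with "TA" are rejected.
#' Rejections are counted per class, never fatal.
#'
#' @param reads `data.frame` from [readReads()] (columns `id`, `seq` and
#'   optionally `count` for pre-collapsed multiplicities).
#' @param barcodes validated barcode table from [readBarcodeTable()] /
#'   [barcodeSpecs()].
#' @param config a [TrimConfig-class].
#' @return list with `fragments` (`data.frame`: library, directionalLibrary,
#'   side, seq, readCount; one row per input read that survived) and `stats`,
#'   a named vector counting input, assigned, no_barcode, no_tag, empty_fragment
#'   and no_ta reads. `input = assigned + rejected` always holds.
#' @export
demuxTrim <- function(reads, barcodes, config) {
  stopifnot(is(config, "TrimConfig"), nrow(barcodes) > 0L)
  if (is.null(reads$count)) reads$count <- 1
  n <- nrow(reads)
  specIdx <- rep(NA_integer_, n)
  if (config@barcodeMismatches == 0L) {
    for (bl in unique(nchar(barcodes$barcode))) {
      rows <- which(nchar(barcodes$barcode) == bl)
      hit <- match(substr(reads$seq, 1L, bl), barcodes$barcode[rows])
      take <- is.na(specIdx) & !is.na(hit)
      specIdx[take] <- rows[hit[take]]
    }
  } else {
    mmMat <- vapply(barcodes$barcode,
                    function(b) .prefixMismatches(reads$seq, b),
                    integer(n))
    mmMat <- matrix(mmMat, nrow = n)
    mmMat[is.na(mmMat)] <- .Machine$integer.max
    mmMat[mmMat > config@barcodeMismatches] <- .Machine$integer.max
    best <- max.col(-mmMat, ties.method = "first")
    bestVal <- mmMat[cbind(seq_len(n), best)]
    nBest <- rowSums(mmMat == bestVal)
    ok <- bestVal <= config@barcodeMismatches & nBest == 1L
    specIdx[ok] <- best[ok]
  }

  stats <- c(input = sum(reads$count), assigned = 0, no_barcode = 0,
             no_tag = 0, empty_fragment = 0, no_ta = 0)
  stats["no_barcode"] <- sum(reads$count[is.na(specIdx)])
  keep <- !is.na(specIdx)
  reads <- reads[keep, , drop = FALSE]
  specIdx <- specIdx[keep]
  bl <- nchar(barcodes$barcode)[specIdx]
  tag <- config@transposonTag
  tl <- nchar(tag)

  tagSeen <- substr(reads$seq, bl + 1L, bl + tl)
  tagOK <- tagSeen == tag & !grepl("N", tagSeen, fixed = TRUE)
  stats["no_tag"] <- sum(reads$count[!tagOK])
  reads <- reads[tagOK, , drop = FALSE]
  specIdx <- specIdx[tagOK]
  bl <- bl[tagOK]

  genomic <- substr(reads$seq, bl + tl + 1L, nchar(reads$seq))
  if (nzchar(config@linker)) {
    hit <- regexpr(config@linker, genomic, fixed = TRUE)
    trunc <- hit > 0L
    genomic[trunc] <- substr(genomic[trunc], 1L, hit[trunc] - 1L)
  }
  nonEmpty <- nzchar(genomic)
  stats["empty_fragment"] <- sum(reads$count[!nonEmpty])
  reads <- reads[nonEmpty, , drop = FALSE]
  specIdx <- specIdx[nonEmpty]
  genomic <- genomic[nonEmpty]

  if (config@requireTA) {
    ta <- substr(genomic, 1L, 2L) == "TA"
    stats["no_ta"] <- sum(reads$count[!ta])
    reads <- reads[ta, , drop = FALSE]
    specIdx <- specIdx[ta]
    genomic <- genomic[ta]
  }
  stats["assigned"] <- sum(reads$count)

  frags <- data.frame(
    library = barcodes$library[specIdx],
    directionalLibrary = barcodes$directionalLibrary[specIdx],
    side = barcodes$side[specIdx],
    seq = genomic,
    readCount = reads$count,
    stringsAsFactors = FALSE
  )
  rownames(frags) <- NULL
  list(fragments = frags, stats = stats)
}

#' Collapse duplicate fragments within a library
#'
#' Identical genomic sequences derived from the same library (and side) are
#' condensed to a single entry retaining the total read count. Identical
#' sequences in different libraries remain separate. Idempotent; conserves
#' total read mass.
#'
#' @param fragments fragment `data.frame` from [demuxTrim()].
#' @return collapsed fragment `data.frame`, unique on
#'   (directionalLibrary, seq), ordered by library, side, sequence.
#' @export
collapseDuplicates <- function(fragments) {
  if (!nrow(fragments)) return(fragments)
  key <- paste(fragments$directionalLibrary, fragments$seq, sep = "\r")
  o <- !duplicated(key)
  out <- fragments[o, , drop = FALSE]
  counts <- rowsum(fragments$readCount, key, reorder = FALSE)
  out$readCount <- unname(counts[match(key[o], rownames(counts)), 1L])
  out <- out[order(out$library, out$side, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}
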