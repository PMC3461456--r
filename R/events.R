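#' Resolve biological insertion orientation
#'
#' The transposon is asymmetric: it drives transcription only in the
#' direction it points. A right-side read mapping to the + strand, or a
#' left-side read mapping to the - strand, indicates an insertion oriented to
#' activate transcription on the + strand; the opposite combinations indicate
#' the - orientation.
#'
#' @param side priming side, `"left"` or `"right"` (vectorised).
#' @param strand read mapping strand, `"+"` or `"-"` (vectorised).
#' @return character vector of orientations (`"+"`/`"-"`).
#' @examples
#' resolveOrientation(c("right", "left", "right"), c("+", "-", "-"))
#' @export
resolveOrientation <- function(side, strand) {
  side <- tolower(side)
  stopifnot(all(side %in% c("left", "right")), all(strand %in% c("+", "-")))
  ifelse((side == "right") == (strand == "+"), "+", "-")
}

#' Strip -L/-R suffixes to merge directional libraries
#'
#' Left- and right-primed read sets of the same tumor are merged under the
#' base library name; the side is retained on each record for orientation
#' resolution.
#'
#' @param x character vector of directional library names, or a `data.frame`
#'   with a `directionalLibrary` column (gains/overwrites `library`).
#' @return same shape as `x` with suffixes stripped.
#' @export
mergeDirectionalLibraries <- function(x) {
  if (is.data.frame(x)) {
    x$library <- mergeDirectionalLibraries(x$directionalLibrary)
    return(x)
  }
  ok <- grepl("-[LRlr]$", x)
  if (!all(ok))
    stop("directional library name(s) lacking -L/-R suffix: ",
         paste(utils::head(unique(x[!ok]), 3L), collapse = ", "))
  substr(x, 1L, nchar(x) - 2L)
}

#' Bin mappings into 100-bp insertion events
#'
#' Local hopping and early-sequence errors scatter reads from one clonal
#' insertion across neighbouring TA sites; binning mapped positions into
#' fixed genome-anchored 100-bp tiles by (library, location, orientation)
#' groups these with the dominant site. Read mass is conserved.
#'
#' @param mappings mapping `data.frame` with columns library, side, chrom,
#'   pos (0-based), strand, readCount. Orientation is resolved here from
#'   (side, strand) unless an `orientation` column is already present.
#' @param binSize bin width in bp (default 100).
#' @return `GRanges` of bins (1-based, width `binSize`); strand is the
#'   biological orientation; mcols: `library`, `readCount` (summed),
#'   `nRawPositions` (distinct mapped positions collapsed into the bin).
#' @export
binEvents <- function(mappings, binSize = 100L) {
  if (!nrow(mappings)) {
    return(GRanges(library = character(), readCount = numeric(),
                   nRawPositions = integer()))
  }
  orient <- if (!is.null(mappings$orientation)) mappings$orientation
            else resolveOrientation(mappings$side, mappings$strand)
  bin <- mappings$pos %/% binSize
  key <- paste(mappings$library, mappings$chrom, bin, orient, sep = "\r")
  first <- !duplicated(key)
  counts <- rowsum(mappings$readCount, key, reorder = FALSE)
  posKey <- paste(key, mappings$pos, sep = "\r")
  nPos <- rowsum(as.integer(!duplicated(posKey)), key, reorder = FALSE)
  idx <- match(key[first], rownames(counts))
  chrom <- mappings$chrom[first]
  gr <- GRanges(
    seqnames = chrom,
    ranges = IRanges(start = bin[first] * binSize + 1L, width = binSize),
    strand = orient[first],
    library = mappings$library[first],
    readCount = unname(counts[idx, 1L]),
    nRawPositions = as.integer(unname(nPos[idx, 1L]))
  )
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  stopifnot(sum(gr$readCount) == sum(mappings$readCount))
  gr
}

#' Per-library mapping totals
#'
#' @param mappings mapping `data.frame` (post directional-library merge).
#' @return `data.frame` with `library`, `totalMappedReads`, `totalEvents`
#'   (distinct mapped positions are not deduplicated here; totalEvents counts
#'   mapping records).
#' @export
libraryStats <- function(mappings) {
  if (!nrow(mappings))
    return(data.frame(library = character(), totalMappedReads = numeric(),
                      totalEvents = integer(), stringsAsFactors = FALSE))
  tot <- rowsum(mappings$readCount, mappings$library)
  cnt <- rowsum(rep(1L, nrow(mappings)), mappings$library)
  data.frame(library = rownames(tot),
             totalMappedReads = unname(tot[, 1L]),
             totalEvents = as.integer(unname(cnt[, 1L])),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the clonality read-fraction cutoff
#'
#' Passenger insertions occur late in tumor development, are present in few
#' cells and yield only one or two reads, unlike clonal insertions read many
#' times. An event is kept iff its read count is at least `fraction` of the
#' total mapped reads of its library. The recommended fraction is 1/10,000
#' for Illumina-depth data and `NULL` (no cutoff) for 454-depth data.
#'
#' @param events event `GRanges` from [binEvents()].
#' @param stats per-library totals from [libraryStats()].
#' @param fraction numeric in (0,1), or `NULL` to keep everything.
#' @return filtered event `GRanges`.
#' @export
applyCutoff <- function(events, stats, fraction = NULL) {
  if (is.null(fraction) || !length(events)) return(events)
  stopifnot(fraction > 0, fraction < 1)
  tot <- stats$totalMappedReads[match(events$library, stats$library)]
  if (anyNA(tot)) stop("events reference libraries absent from stats")
  events[events$readCount >= fraction * tot]
}

#' Exclude chromosomes (donor chromosome considerations)
#'
#' The chromosome carrying the donor transposon concatamer is enriched for
#' local-hopping artifacts and is commonly excluded from CIS analysis.
#'
#' @param events event `GRanges`.
#' @param excluded character vector of chromosome names (or a path to a text
#'   file with one name per line).
#' @return event `GRanges` without the listed chromosomes; the number of
#'   removed events is reported as a message.
#' @export
excludeChromosomes <- function(events, excluded) {
  if (length(excluded) == 1L && file.exists(excluded))
    excluded <- readExcludeList(excluded)
  if (!length(excluded) || !length(events)) return(events)
  drop <- as.character(seqnames(events)) %in% excluded
  if (any(drop))
    message(sum(drop), " event(s) removed on excluded chromosome(s)")
  out <- events[!drop]
  GenomeInfoDb::seqlevels(out) <- setdiff(GenomeInfoDb::seqlevels(out),
                                          excluded)
  out
}

#' Read an excluded-chromosome list (one name per line)
#' @param path text file.
#' @return character vector.
#' @export
readExcludeList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read a library-metadata group table
#'
#' Tab-delimited, two columns: group name, library name. The superset group
#' `"all"` must be present; it defines the analysis library set.
#'
#' @param path tab-delimited file.
#' @return named list mapping group name to a character vector of libraries.
#' @export
readMetadataTable <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("metadata table needs 2 columns: group, library")
  md <- split(tab[[2L]], tab[[1L]])
  validateMetadata(md)
}

#' Validate metadata groups
#'
#' @param metadata named list of library vectors.
#' @return the validated list (groups deduplicated).
#' @export
validateMetadata <- function(metadata) {
  if (!("all" %in% names(metadata)))
    stop("metadata must include the superset group \"all\"")
  metadata <- lapply(metadata, unique)
  unknown <- setdiff(unlist(metadata), metadata$all)
  if (length(unknown))
    stop("libraries in metadata groups but not in \"all\": ",
         paste(utils::head(unknown, 3L), collapse = ", "))
  metadata
}

#' Merge projects for meta-analysis
#'
#' Libraries are identified by name: same-named libraries across projects are
#' combined by summing bin-level read counts (and raw-position counts), so
#' reusing one barcode set across projects never causes collisions. The merge
#' is associative and commutative.
#'
#' @param ... [InsertionScreen-class] objects (or a single list of them).
#' @param project name for the merged project.
#' @return merged [InsertionScreen-class]. Fragment and mapping tables are
#'   concatenated; events are re-aggregated at the bin level; metadata groups
#'   are unioned by group name.
#' @export
mergeProjects <- function(..., project = "merged") {
  screens <- list(...)
  if (length(screens) == 1L && is.list(screens[[1L]]) &&
      !is(screens[[1L]], "InsertionScreen"))
    screens <- screens[[1L]]
  stopifnot(length(screens) >= 1L,
            all(vapply(screens, is, TRUE, "InsertionScreen")))
  ev <- lapply(screens, insertEvents)
  events <- .aggregateEvents(do.call(c, unname(ev)))
  ls <- do.call(rbind, lapply(screens, screenLibraryStats))
  libStats <- data.frame(
    library = unique(ls$library),
    totalMappedReads = unname(rowsum(ls$totalMappedReads, ls$library,
                                     reorder = FALSE)[, 1L]),
    totalEvents = as.integer(unname(rowsum(ls$totalEvents, ls$library,
                                           reorder = FALSE)[, 1L])),
    row.names = NULL, stringsAsFactors = FALSE)
  mdNames <- unique(unlist(lapply(screens, function(s) names(s@metadata))))
  metadata <- stats::setNames(lapply(mdNames, function(g)
    unique(unlist(lapply(screens, function(s) s@metadata[[g]])))), mdNames)
  rej <- Reduce(function(a, b) {
    keys <- union(names(a), names(b))
    stats::setNames(vapply(keys, function(k)
      sum(a[k], b[k], na.rm = TRUE), numeric(1L)), keys)
  }, lapply(screens, rejectionStats))
  sizes <- unlist(lapply(screens, function(s) s@chromSizes))
  sizes <- sizes[!duplicated(names(sizes))]
  new("InsertionScreen",
      project = project,
      fragments = do.call(rbind, lapply(screens, fragments)),
      mappings = do.call(rbind, lapply(screens, screenMappings)),
      events = events,
      libraryStats = libStats,
      rejectionStats = rej,
      metadata = metadata,
      chromSizes = if (length(sizes)) sizes else numeric())
}

# Re-aggregate an event GRanges on (library, chrom, bin, orientation),
# summing readCount and nRawPositions.
.aggregateEvents <- function(events) {
  if (!length(events)) return(events)
  key <- paste(events$library, as.character(seqnames(events)),
               start(events), as.character(strand(events)), sep = "\r")
  first <- !duplicated(key)
  counts <- rowsum(events$readCount, key, reorder = FALSE)
  npos <- rowsum(events$nRawPositions, key, reorder = FALSE)
  out <- events[first]
  idx <- match(key[first], rownames(counts))
  out$readCount <- unname(counts[idx, 1L])
  out$nRawPositions <- as.integer(unname(npos[idx, 1L]))
  GenomicRanges::sort(out, ignore.strand = TRUE)
}

#' Run the read-to-events pipeline for one project
#'
#' Convenience wrapper: demultiplex/trim, collapse duplicates, map with the
#' iterative schedule, resolve orientation, bin into 100-bp events, apply the
#' clonality cutoff and chromosome exclusions, and package everything as an
#' [InsertionScreen-class].
#'
#' @param reads read `data.frame` ([readReads()]).
#' @param barcodes barcode table ([readBarcodeTable()]).
#' @param trimCfg a [TrimConfig-class].
#' @param genome a [GenomeIndex-class].
#' @param schedule mapping schedule (default [defaultSchedule()]).
#' @param cutoffFraction clonality cutoff fraction or `NULL`
#'   (see [applyCutoff()]); the preset `"illumina"` means 1/10,000.
#' @param excludeChrom chromosomes to exclude from events.
#' @param metadata named list of library groups (optional; a superset group
#'   `"all"` is added from the observed libraries when missing).
#' @param project project name.
#' @return an [InsertionScreen-class].
#' @export
processScreen <- function(reads, barcodes, trimCfg, genome,
                          schedule = defaultSchedule(),
                          cutoffFraction = NULL,
                          excludeChrom = character(),
                          metadata = NULL, project = "project") {
  if (identical(cutoffFraction, "illumina")) cutoffFraction <- 1 / 10000
  dm <- demuxTrim(reads, barcodes, trimCfg)
  frags <- collapseDuplicates(dm$fragments)
  mp <- mapIteratively(frags, genome, schedule)
  stats <- libraryStats(mp$mappings)
  events <- binEvents(mp$mappings)
  events <- applyCutoff(events, stats, cutoffFraction)
  events <- excludeChromosomes(events, excludeChrom)
  if (is.null(metadata)) metadata <- list(all = unique(frags$library))
  metadata <- validateMetadata(metadata)
  rej <- c(dm$stats,
           too_short_fragments = mp$stats$too_short_fragments,
           multimapped_fragments = mp$stats$multimapped_fragments,
           unmapped_fragments = mp$stats$unmapped_fragments)
  new("InsertionScreen", project = project, fragments = frags,
      mappings = mp$mappings, events = events, libraryStats = stats,
      rejectionStats = rej, metadata = metadata,
      chromSizes = chromSizes(genome))
}

#' Three-level project summary
#'
#' Counts at project, directional-library and merged-library level: total
#' reads, mappable reads (fragments of mappable length), mapped reads, mapped
#' percentage, and for merged libraries the number of regions passing the
#' clonality threshold.
#'
#' @param screen an [InsertionScreen-class].
#' @param level `"project"`, `"directional"` or `"library"`.
#' @return `data.frame`; one row per unit at the requested level.
#' @export
summarizeProject <- function(screen,
                             level = c("library", "directional", "project")) {
  level <- match.arg(level)
  frags <- fragments(screen)
  maps <- screenMappings(screen)
  events <- insertEvents(screen)
  keyF <- switch(level, project = rep(screen@project, nrow(frags)),
                 directional = frags$directionalLibrary,
                 library = frags$library)
  keyM <- switch(level, project = rep(screen@project, nrow(maps)),
                 directional = maps$directionalLibrary,
                 library = maps$library)
  units <- sort(unique(keyF))
  tot <- vapply(units, function(u) sum(frags$readCount[keyF == u]), 0)
  mappable <- vapply(units, function(u)
    sum(frags$readCount[keyF == u & nchar(frags$seq) >= 24L]), 0)
  mapped <- vapply(units, function(u) sum(maps$readCount[keyM == u]), 0)
  out <- data.frame(unit = units, totalReads = tot, mappableReads = mappable,
                    mappedReads = mapped,
                    pctMapped = round(100 * mapped / pmax(tot, 1), 2),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (level == "library") {
    out$regionsAtThreshold <- vapply(units, function(u)
      sum(events$library == u), 0L)
  }
  out
}
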