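#' Read a gene annotation BED file
#'
#' @param path BED4+ file (chrom, start, end, name).
#' @return `GRanges` with a `name` metadata column.
#' @export
readGeneBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) gr$name <- rep("", length(gr))
  gr
}

#' Annotate CISs with nearby gene names
#'
#' Each CIS is annotated with the comma-joined names of all gene records
#' within `radius` bases of the CIS interval (edge-to-edge distance;
#' overlap counts as distance 0; duplicate names removed). CISs with no
#' record in range receive the literal statement
#' `"No results within a 20,000 bp window"` (with the radius formatted in).
#' Any CIS whose nearby annotations include a name containing the string
#' `"BAD"` marks a known artifact region (e.g. sequence carried inside the
#' transposon itself, or mis-assembled high-copy regions) and is removed
#' from the reported set.
#'
#' @param cisSet a [CISSet-class].
#' @param genes gene `GRanges` from [readGeneBed()].
#' @param radius annotation radius in bp (default 20,000).
#' @return the annotated [CISSet-class], with BAD-flagged CISs dropped; the
#'   number dropped is stored in `cisTotals(x)$badSuppressed`.
#' @export
annotateCIS <- function(cisSet, genes, radius = 20000) {
  gr <- cisRanges(cisSet)
  if (!length(gr)) return(cisSet)
  maxgap <- if (radius > 0) radius else -1L
  ov <- GenomicRanges::findOverlaps(gr, genes, maxgap = maxgap,
                                    ignore.strand = TRUE)
  noneMsg <- sprintf("No results within a %s bp window",
                     format(radius, big.mark = ",", scientific = FALSE))
  ann <- rep(noneMsg, length(gr))
  bad <- logical(length(gr))
  if (length(ov)) {
    hits <- split(genes$name[subjectHits(ov)], queryHits(ov))
    for (q in names(hits)) {
      i <- as.integer(q)
      nm <- unique(hits[[q]])
      ann[i] <- paste(nm, collapse = ",")
      bad[i] <- any(grepl("BAD", nm, fixed = TRUE))
    }
  }
  gr$annotation <- ann
  out <- cisSet
  out@ranges <- gr[!bad]
  out@totals$badSuppressed <- sum(bad)
  out
}

# Minimal variableStep WIG writer: one declaration line per record so that
# each CIS can carry its own span.
.writeWig <- function(gr, scores, path, trackName) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=wiggle_0 name=\"%s\"", trackName), con)
  for (i in seq_along(gr)) {
    writeLines(sprintf("variableStep chrom=%s span=%d",
                       as.character(seqnames(gr))[i], width(gr)[i]), con)
    writeLines(sprintf("%d %g", start(gr)[i], scores[i]), con)
  }
  invisible(path)
}

#' Write all track and table outputs for a project
#'
#' Emits, deterministically given its inputs: a BED of all raw sequence
#' mappings (strand = read mapping strand), a BED of the insertion events
#' used for CIS calculation (strand = biological orientation, score = read
#' count), a WIG of the CISs with peak height -log10 of the region p-value,
#' the CIS table (TSV, 0-based half-open coordinates), the association
#' tables, and the three-level project summary.
#'
#' @param dir output directory (created if needed).
#' @param screen an [InsertionScreen-class] (raw-mapping/event BEDs,
#'   summaries), optional.
#' @param cisSet a [CISSet-class] (CIS TSV + WIG), optional.
#' @param associations result of [runAssociations()], optional.
#' @param prefix file-name prefix (default the screen's project name).
#' @return character vector of the files written (invisibly).
#' @export
writeTracks <- function(dir, screen = NULL, cisSet = NULL,
                        associations = NULL, prefix = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(prefix))
    prefix <- if (!is.null(screen)) screen@project else "project"
  written <- character()
  path <- function(name) file.path(dir, paste0(prefix, ".", name))

  if (!is.null(screen)) {
    maps <- screenMappings(screen)
    if (nrow(maps)) {
      plen <- ifelse(is.na(maps$stage), nchar(maps$seq),
                     nchar(maps$seq))
      rawGr <- GRanges(maps$chrom,
                       IRanges(start = maps$pos + 1L, width = 1L),
                       strand = maps$strand,
                       name = maps$directionalLibrary,
                       score = maps$readCount)
      rtracklayer::export(rawGr, path("raw_mappings.bed"), format = "BED")
      written <- c(written, path("raw_mappings.bed"))
    }
    events <- insertEvents(screen)
    if (length(events)) {
      evGr <- events
      evGr$name <- evGr$library
      evGr$score <- evGr$readCount
      mcols(evGr) <- mcols(evGr)[, c("name", "score")]
      rtracklayer::export(evGr, path("insertions.bed"), format = "BED")
      written <- c(written, path("insertions.bed"))
    }
    for (lev in c("project", "directional", "library")) {
      f <- path(paste0("summary_", lev, ".tsv"))
      utils::write.table(summarizeProject(screen, lev), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      written <- c(written, f)
    }
  }
  if (!is.null(cisSet)) {
    tab <- cisTable(cisSet)
    f <- path("cis.tsv")
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
    if (length(cisSet)) {
      gr <- cisRanges(cisSet)
      .writeWig(gr, -log10(pmax(gr$pRegion, 1e-300)), path("cis.wig"),
                paste0(prefix, " CIS"))
      written <- c(written, path("cis.wig"))
    }
  }
  if (!is.null(associations)) {
    for (fam in names(associations)) {
      if (is.null(associations[[fam]])) next
      f <- path(paste0("assoc_", fam, ".tsv"))
      utils::write.table(associations[[fam]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
    }
  }
  invisible(written)
}

#' Save a screen to a directory of plain TSV files
#'
#' File-backed project store: fragments, mappings, events, library stats,
#' rejection stats, metadata and chromosome sizes as TSVs, re-loadable with
#' [readScreen()] and mergeable with [mergeProjects()].
#'
#' @param screen an [InsertionScreen-class].
#' @param dir destination directory.
#' @return `dir`, invisibly.
#' @export
writeScreen <- function(screen, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) utils::write.table(
    x, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(fragments(screen), "fragments.tsv")
  w(screenMappings(screen), "mappings.tsv")
  ev <- insertEvents(screen)
  w(data.frame(chrom = as.character(seqnames(ev)), start = start(ev) - 1L,
               end = end(ev), orientation = as.character(strand(ev)),
               library = ev$library, readCount = ev$readCount,
               nRawPositions = ev$nRawPositions), "events.tsv")
  w(screenLibraryStats(screen), "library_stats.tsv")
  w(data.frame(key = names(rejectionStats(screen)),
               value = unname(rejectionStats(screen))), "rejection_stats.tsv")
  md <- screenMetadata(screen)
  w(data.frame(group = rep(names(md), lengths(md)),
               library = unlist(md, use.names = FALSE)), "metadata.tsv")
  w(data.frame(chrom = names(screen@chromSizes),
               length = unname(screen@chromSizes)), "chrom_sizes.tsv")
  writeLines(screen@project, file.path(dir, "project.txt"))
  invisible(dir)
}

#' Load a screen saved by [writeScreen()]
#'
#' @param dir directory written by [writeScreen()].
#' @return an [InsertionScreen-class].
#' @export
readScreen <- function(dir) {
  r <- function(name) utils::read.delim(file.path(dir, name),
                                        stringsAsFactors = FALSE)
  ev <- r("events.tsv")
  events <- if (nrow(ev)) GRanges(ev$chrom,
                                  IRanges(start = ev$start + 1L, end = ev$end),
                                  strand = ev$orientation,
                                  library = as.character(ev$library),
                                  readCount = ev$readCount,
                                  nRawPositions = ev$nRawPositions)
            else GRanges(library = character(), readCount = numeric(),
                         nRawPositions = integer())
  rej <- r("rejection_stats.tsv")
  md <- r("metadata.tsv")
  sizes <- r("chrom_sizes.tsv")
  frag <- r("fragments.tsv")
  frag$library <- as.character(frag$library)
  maps <- r("mappings.tsv")
  maps$library <- as.character(maps$library)
  ls <- r("library_stats.tsv")
  ls$library <- as.character(ls$library)
  new("InsertionScreen",
      project = readLines(file.path(dir, "project.txt"))[1L],
      fragments = frag, mappings = maps, events = events,
      libraryStats = ls,
      rejectionStats = stats::setNames(rej$value, rej$key),
      metadata = split(as.character(md$library), md$group),
      chromSizes = stats::setNames(sizes$length, sizes$chrom))
}
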