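#' Generate a random reference genome
#'
#' Uniform random ACGT sequence split over `nChrom` chromosomes,
#' deterministic per seed. TA dinucleotide positions (the integration sites
#' of the transposon) can be listed with [taSites()].
#'
#' @param length total genome length in bp (>= 10,000).
#' @param nChrom number of chromosomes (equal sizes, remainder on the last).
#' @param seed RNG seed.
#' @return a [GenomeIndex-class] with sequences loaded.
#' @export
makeGenome <- function(length = 1e7, nChrom = 4L, seed = 1L) {
  stopifnot(length >= 10000)
  rng <- .withSeed(seed)
  on.exit(rng())
  per <- rep(length %/% nChrom, nChrom)
  per[nChrom] <- per[nChrom] + length %% nChrom
  seqs <- DNAStringSet(vapply(per, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1L)))
  names(seqs) <- paste0("chr", seq_len(nChrom))
  genomeFromSeqs(seqs)
}

#' List TA dinucleotide positions
#'
#' @param genome a [GenomeIndex-class] with sequences.
#' @return named list per chromosome of 0-based positions `i` with
#'   `genome[i..i+1] == "TA"`.
#' @export
taSites <- function(genome) {
  lapply(stats::setNames(names(genome@seqs), names(genome@seqs)),
         function(chrom)
           start(matchPattern("TA", genome@seqs[[chrom]])) - 1L)
}

# Genomic fragment of `len` bases read off the TA at 0-based `pos` on the
# given mapping strand ("+": forward from pos; "-": reverse complement ending
# at pos+1, so the fragment still starts with TA and its first base maps to
# 0-based coordinate pos+1).
.fragmentAt <- function(chromSeq, pos, len, strand) {
  if (strand == "+") {
    as.character(Biostrings::subseq(chromSeq, pos + 1L, pos + len))
  } else {
    as.character(reverseComplement(
      Biostrings::subseq(chromSeq, pos + 2L - len + 1L, pos + 2L)))
  }
}

#' Simulate a barcoded insertional mutagenesis screen
#'
#' Emulates the read structure barcode + transposon tag + genomic fragment
#' (+ linker carryover) for a set of tumor libraries, with the artifact
#' classes seen in real screens: clonal insertions with log-normal read
#' abundance, low-read passenger insertions (1-2 reads), local hops at TA
#' sites near a clonal insertion, an optional many-libraries-one-TA
#' artifact, and an optional donor chromosome carrying a dense local-hop
#' cluster in every library. Driver loci are planted in a chosen subset of
#' libraries; within a locus each participating library integrates at its
#' own TA site inside `locusSpan`, as selection acts on the locus rather
#' than a single TA. Deterministic per seed.
#'
#' @param genome a [GenomeIndex-class] with sequences.
#' @param nLibraries number of tumor libraries.
#' @param nDrivers number of driver loci to auto-place (ignored when
#'   `driverLoci` is supplied).
#' @param driverLoci optional `data.frame` (chrom, pos \[0-based TA start\],
#'   orientation) with a list-column `libraries` of participating library
#'   names; auto-placed on distinct chromosomes when `NULL`. The last locus
#'   is restricted to the `grpA` phenotype group, so that the screen carries
#'   a phenotype-associated driver.
#' @param clonalBackground clonal background insertions per library.
#' @param clonalReadsMean median read count of a clonal insertion
#'   (log-normal, `sdlog = clonalReadsSdlog`).
#' @param clonalReadsSdlog log-scale spread of clonal read counts.
#' @param passengersPerLibrary late passenger insertions per library
#'   (1 read with probability 0.7, 2 reads otherwise).
#' @param localHopRate probability that a clonal insertion spawns 1-2 local
#'   hops at TA sites within `localHopWindow`.
#' @param localHopWindow local-hop distance bound in bp.
#' @param locusSpan span of a driver locus in bp.
#' @param sharedTAArtifact plant a single TA shared by many libraries
#'   (false-priming / barcode mis-assignment artifact).
#' @param donorChrom chromosome name carrying a donor-concatamer local-hop
#'   cluster, or `NULL`.
#' @param tag,linker transposon tag and linker sequences used in the reads.
#' @param seed RNG seed.
#' @return list: `reads` (`data.frame` id/seq/count, multiplicities in
#'   `count`), `barcodes` (validated table), `metadata` (groups `all`,
#'   `grpA`, `grpB`), `truth` (`data.frame`, one row per planted insert with
#'   class, locus, position and per-side read counts), `trimConfig`,
#'   `excluded` (donor chromosome, if any).
#' @export
simulateScreen <- function(genome, nLibraries = 20L, nDrivers = 3L,
                           driverLoci = NULL, clonalBackground = 10L,
                           clonalReadsMean = 2500, clonalReadsSdlog = 0.5,
                           passengersPerLibrary = 10L, localHopRate = 0.2,
                           localHopWindow = 5000L, locusSpan = 4000L,
                           sharedTAArtifact = FALSE, donorChrom = NULL,
                           tag = "GTGTATGT", linker = "CTAGACCGGTTA",
                           seed = 1L) {
  rng <- .withSeed(seed)
  on.exit(rng())
  libs <- sprintf("tum%02d", seq_len(nLibraries))
  nA <- ceiling(0.6 * nLibraries)
  metadata <- list(all = libs, grpA = libs[seq_len(nA)],
                   grpB = libs[(nA + 1L):nLibraries])
  ta <- taSites(genome)

  # barcodes: distinct 6-mers, two per library (left/right)
  pool <- as.matrix(expand.grid(rep(list(c("A", "C", "G", "T")), 6L)))
  pool <- apply(pool[sample(nrow(pool), 2L * nLibraries), ], 1L, paste,
                collapse = "")
  barcodes <- barcodeSpecs(
    barcode = pool,
    directionalLibrary = c(paste0(libs, "-L"), paste0(libs, "-R")),
    side = rep(c("Left", "Right"), each = nLibraries))

  if (is.null(driverLoci)) {
    chroms <- names(genome@sizes)[rep_len(seq_along(genome@sizes), nDrivers)]
    driverLoci <- do.call(rbind, lapply(seq_len(nDrivers), function(i) {
      cand <- ta[[chroms[i]]]
      cand <- cand[cand > locusSpan + localHopWindow &
                   cand < genome@sizes[[chroms[i]]] - locusSpan -
                     localHopWindow - 200L]
      data.frame(chrom = chroms[i], pos = sample(cand, 1L),
                 orientation = sample(c("+", "-"), 1L),
                 stringsAsFactors = FALSE)
    }))
    members <- lapply(seq_len(nDrivers), function(i)
      sample(libs, min(nLibraries, 10L + nDrivers - i)))
    members[[nDrivers]] <- metadata$grpA   # phenotype-restricted driver
    driverLoci$libraries <- I(members)
  }

  truth <- list()
  addInsert <- function(library, chrom, pos, orientation, class, locus,
                        parent = NA_integer_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      library = library, chrom = chrom, pos = pos,
      orientation = orientation, class = class, locus = locus,
      parent = parent, stringsAsFactors = FALSE)
    length(truth)
  }
  pickTA <- function(chrom, lo, hi) {
    cand <- ta[[chrom]]
    cand <- cand[cand >= lo & cand <= hi]
    if (!length(cand)) return(NA_integer_)
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }

  for (li in seq_len(nLibraries)) {
    lib <- libs[li]
    for (d in seq_len(nrow(driverLoci))) {
      if (!(lib %in% driverLoci$libraries[[d]])) next
      p <- pickTA(driverLoci$chrom[d],
                  driverLoci$pos[d] - locusSpan %/% 2L,
                  driverLoci$pos[d] + locusSpan %/% 2L)
      addInsert(lib, driverLoci$chrom[d], p, driverLoci$orientation[d],
                "driver", paste0("locus", d))
    }
    for (b in seq_len(clonalBackground)) {
      chrom <- sample(names(genome@sizes), 1L,
                      prob = genome@sizes / sum(genome@sizes))
      p <- pickTA(chrom, 200L, genome@sizes[[chrom]] - 200L)
      addInsert(lib, chrom, p, sample(c("+", "-"), 1L), "background", NA)
    }
    for (ps in seq_len(passengersPerLibrary)) {
      chrom <- sample(names(genome@sizes), 1L,
                      prob = genome@sizes / sum(genome@sizes))
      p <- pickTA(chrom, 200L, genome@sizes[[chrom]] - 200L)
      addInsert(lib, chrom, p, sample(c("+", "-"), 1L), "passenger", NA)
    }
  }
  truthDf <- do.call(rbind, truth)

  # local hops off clonal inserts
  clonalIdx <- which(truthDf$class %in% c("driver", "background"))
  hops <- list()
  for (i in clonalIdx) {
    if (stats::runif(1L) > localHopRate) next
    for (h in seq_len(sample(1:2, 1L))) {
      p <- pickTA(truthDf$chrom[i],
                  max(0L, truthDf$pos[i] - localHopWindow),
                  truthDf$pos[i] + localHopWindow)
      if (is.na(p)) next
      hops[[length(hops) + 1L]] <- data.frame(
        library = truthDf$library[i], chrom = truthDf$chrom[i], pos = p,
        orientation = truthDf$orientation[i], class = "local_hop",
        locus = truthDf$locus[i], parent = i, stringsAsFactors = FALSE)
    }
  }
  if (length(hops)) truthDf <- rbind(truthDf, do.call(rbind, hops))

  if (isTRUE(sharedTAArtifact)) {
    chrom <- names(genome@sizes)[1L]
    p <- pickTA(chrom, 200L, genome@sizes[[chrom]] - 200L)
    for (lib in sample(libs, min(8L, nLibraries)))
      truthDf <- rbind(truthDf, data.frame(
        library = lib, chrom = chrom, pos = p, orientation = "+",
        class = "shared_ta", locus = NA, parent = NA_integer_,
        stringsAsFactors = FALSE))
  }

  if (!is.null(donorChrom)) {
    center <- pickTA(donorChrom, localHopWindow + 200L,
                     genome@sizes[[donorChrom]] - localHopWindow - 200L)
    for (lib in libs) {
      for (h in seq_len(3L)) {
        p <- pickTA(donorChrom, max(0L, center - localHopWindow),
                    center + localHopWindow)
        truthDf <- rbind(truthDf, data.frame(
          library = lib, chrom = donorChrom, pos = p, orientation = "+",
          class = "donor_hop", locus = NA, parent = NA_integer_,
          stringsAsFactors = FALSE))
      }
    }
  }
  truthDf <- truthDf[!is.na(truthDf$pos), , drop = FALSE]
  rownames(truthDf) <- NULL

  # read emission
  drawReads <- function(class) {
    switch(class,
           driver = , background = , shared_clonal =
             max(1, round(stats::rlnorm(1, log(clonalReadsMean),
                                        clonalReadsSdlog))),
           passenger = sample(1:2, 1L, prob = c(0.7, 0.3)),
           local_hop = , donor_hop = sample(1:4, 1L),
           shared_ta = sample(1:2, 1L))
  }
  bcL <- stats::setNames(barcodes$barcode[barcodes$side == "left"],
                         barcodes$library[barcodes$side == "left"])
  bcR <- stats::setNames(barcodes$barcode[barcodes$side == "right"],
                         barcodes$library[barcodes$side == "right"])
  rows <- vector("list", 2L * nrow(truthDf))
  k <- 0L
  truthDf$readsLeft <- 0
  truthDf$readsRight <- 0
  for (i in seq_len(nrow(truthDf))) {
    sides <- c("left", "right")[stats::runif(2L) < 0.85]
    if (!length(sides)) sides <- sample(c("left", "right"), 1L)
    for (side in sides) {
      nReads <- drawReads(truthDf$class[i])
      # read strand implied by side and biological orientation
      strand <- if ((side == "right") == (truthDf$orientation[i] == "+"))
        "+" else "-"
      u <- stats::runif(1L)
      glen <- if (u < 0.03) sample(15:23, 1L)
              else if (u < 0.18) sample(24:33, 1L)
              else sample(34:70, 1L)
      chromSeq <- genome@seqs[[truthDf$chrom[i]]]
      pos <- truthDf$pos[i]
      if (strand == "-" && pos + 2L - glen < 1L) glen <- pos + 1L
      if (strand == "+" && pos + glen > length(chromSeq))
        glen <- length(chromSeq) - pos
      frag <- .fragmentAt(chromSeq, pos, glen, strand)
      v <- stats::runif(1L)
      tail <- if (v < 0.4)
        paste0(linker, paste(sample(c("A", "C", "G", "T"),
                                    sample(0:8, 1L), replace = TRUE),
                             collapse = ""))
      else if (v < 0.7)
        substr(linker, 1L, sample(seq_len(nchar(linker) - 1L), 1L))
      else ""
      bc <- if (side == "left") bcL[[truthDf$library[i]]]
            else bcR[[truthDf$library[i]]]
      k <- k + 1L
      rows[[k]] <- data.frame(
        id = sprintf("ins%05d_%s", i, substr(side, 1L, 1L)),
        seq = paste0(bc, tag, frag, tail), count = nReads,
        stringsAsFactors = FALSE)
      if (side == "left") truthDf$readsLeft[i] <- nReads
      else truthDf$readsRight[i] <- nReads
    }
  }
  reads <- do.call(rbind, rows[seq_len(k)])
  list(reads = reads, barcodes = barcodes, metadata = metadata,
       truth = truthDf,
       trimConfig = trimConfig(tag, linker = linker, requireTA = TRUE),
       excluded = if (is.null(donorChrom)) character() else donorChrom)
}

#' Write the simulator outputs as pipeline input files
#'
#' Emits the four pipeline input files (reads as a 2-column id/sequence tab
#' file with multiplicities expanded, barcode table, metadata group table,
#' excluded-chromosome list) plus the genome FASTA, a chrom.sizes table and
#' the truth table.
#'
#' @param sim result of [simulateScreen()].
#' @param genome the [GenomeIndex-class] used.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSimInputs <- function(sim, genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reps <- rep(seq_len(nrow(sim$reads)), sim$reads$count)
  ids <- paste0(sim$reads$id[reps], "_",
                stats::ave(reps, reps, FUN = seq_along))
  utils::write.table(data.frame(id = ids, seq = sim$reads$seq[reps]),
                     file.path(dir, "seqs.tab"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$barcodes[, c("barcode", "directionalLibrary",
                                      "side")],
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  md <- sim$metadata
  utils::write.table(data.frame(group = rep(names(md), lengths(md)),
                                library = unlist(md, use.names = FALSE)),
                     file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(sim$excluded, file.path(dir, "exclude.txt"))
  writeXStringSet(genome@seqs, file.path(dir, "genome.fa"))
  utils::write.table(data.frame(chrom = names(chromSizes(genome)),
                                length = unname(chromSizes(genome))),
                     file.path(dir, "chrom.sizes"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate uniformly random insertion events
#'
#' Null-model generator used to validate the scan: `n` positions uniform on
#' a genome of the given size, uniform library assignment and random
#' orientation, injected directly into the CIS scan as binned events
#' (no reads, no mapping).
#'
#' @param n number of insertions (>= 1).
#' @param genomeSize genome size in bp, split over `nChrom` equal
#'   pseudo-chromosomes (interval containers cap a single chromosome below
#'   2^31 bp, and a mammalian-scale genome is multi-chromosomal anyway).
#' @param nLibraries number of libraries to assign among.
#' @param nChrom number of pseudo-chromosomes.
#' @param seed RNG seed.
#' @return event `GRanges` as produced by [binEvents()].
#' @export
simulateRandomPositions <- function(n, genomeSize, nLibraries, nChrom = 20L,
                                    seed = 1L) {
  stopifnot(n >= 1)
  rng <- .withSeed(seed)
  on.exit(rng())
  pos <- floor(stats::runif(n) * genomeSize)
  per <- ceiling(genomeSize / nChrom)
  mappings <- data.frame(
    library = sprintf("lib%04d", sample.int(nLibraries, n, replace = TRUE)),
    chrom = sprintf("chr%d", pos %/% per + 1),
    pos = pos %% per,
    orientation = sample(c("+", "-"), n, replace = TRUE),
    readCount = 1,
    stringsAsFactors = FALSE)
  binEvents(mappings)
}
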