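test_that("synthetic genomes are deterministic with a faithful TA index", {
  g1 <- makeGenome(1e5, 2, seed = 5)
  g2 <- makeGenome(1e5, 2, seed = 5)
  expect_identical(as.character(genomeSeqs(g1)), as.character(genomeSeqs(g2)))
  expect_equal(unname(sum(chromSizes(g1))), 1e5)
  expect_equal(length(chromSizes(g1)), 2L)
  ta <- taSites(g1)[["chr1"]]
  s <- as.character(genomeSeqs(g1)[["chr1"]])
  expect_true(all(substr(rep(s, length(ta)), ta + 1, ta + 2) == "TA"))
  # different seed differs
  expect_false(identical(as.character(genomeSeqs(makeGenome(1e5, 2, 6))[[1]]),
                         as.character(genomeSeqs(g1)[[1]])))
})

test_that("screen simulation honours its truth table", {
  genome <- makeGenome(2e6, 4, seed = 61)
  sim <- simulateScreen(genome, nLibraries = 10, seed = 62)
  tr <- sim$truth

  # every read row traces to a truth insert; counts match truth abundances
  ins <- as.integer(sub("^ins0*([0-9]+)_.*$", "\\1", sim$reads$id))
  expect_true(all(ins >= 1 & ins <= nrow(tr)))
  side <- sub("^.*_", "", sim$reads$id)
  expect_equal(sum(sim$reads$count),
               sum(tr$readsLeft) + sum(tr$readsRight))
  expect_equal(sim$reads$count[side == "l"], tr$readsLeft[ins[side == "l"]])

  # driver loci land in the declared member libraries at TA sites
  drv <- tr[tr$class == "driver", ]
  expect_gte(min(table(drv$locus)), 6L)
  for (i in seq_len(nrow(drv))) {
    s <- as.character(genomeSeqs(genome)[[drv$chrom[i]]])
    expect_equal(substr(s, drv$pos[i] + 1, drv$pos[i] + 2), "TA")
  }
  # same seed reproduces the same screen
  sim2 <- simulateScreen(genome, nLibraries = 10, seed = 62)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)

  # with artifact rates zeroed every insert is clonal
  clean <- simulateScreen(genome, nLibraries = 5, passengersPerLibrary = 0,
                          localHopRate = 0, seed = 63)
  expect_setequal(unique(clean$truth$class), c("driver", "background"))

  # the shared-TA artifact plants one TA hit by many libraries: many
  # low-read inserts, one region — the case the region p-value guards against
  shared <- simulateScreen(genome, nLibraries = 10, sharedTAArtifact = TRUE,
                           seed = 64)
  sa <- shared$truth[shared$truth$class == "shared_ta", ]
  expect_gte(length(unique(sa$library)), 8L)
  expect_equal(length(unique(paste(sa$chrom, sa$pos))), 1L)
  expect_lte(max(sa$readsLeft + sa$readsRight), 4)
})

test_that("orientation round trip: planted orientation is recovered from either side", {
  genome <- makeGenome(5e5, 1, seed = 71)
  sim <- simulateScreen(genome, nLibraries = 4, nDrivers = 1,
                        clonalBackground = 5, passengersPerLibrary = 0,
                        localHopRate = 0, seed = 72)
  screen <- processScreen(sim$reads, sim$barcodes, sim$trimConfig, genome,
                          metadata = sim$metadata)
  m <- screenMappings(screen)
  m$orientation <- resolveOrientation(m$side, m$strand)
  m$bin <- m$pos %/% 100
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i, ]
    rows <- m$library == t$library & m$chrom == t$chrom &
      abs(m$pos - t$pos) <= 1
    if (!any(rows)) next   # reads occasionally unmappable (too short)
    expect_true(all(m$orientation[rows] == t$orientation),
                label = paste("insert", i))
  }
  # both sides were exercised
  expect_setequal(unique(m$side), c("left", "right"))
})

test_that("the read-fraction cutoff removes nearly all passenger insertions", {
  genome <- makeGenome(2e6, 4, seed = 81)
  sim <- simulateScreen(genome, nLibraries = 10, seed = 82)
  screen <- processScreen(sim$reads, sim$barcodes, sim$trimConfig, genome,
                          cutoffFraction = 1 / 10000,
                          metadata = sim$metadata)
  ev <- insertEvents(screen)
  evKey <- paste(ev$library, as.character(GenomicRanges::seqnames(ev)),
                 GenomicRanges::start(ev) - 1L)
  tr <- sim$truth
  trKey <- paste(tr$library, tr$chrom, (tr$pos %/% 100) * 100)
  surviving <- trKey %in% evKey
  passengers <- tr$class == "passenger"
  clonal <- tr$class %in% c("driver", "background")
  expect_lte(mean(surviving[passengers]), 0.05)
  expect_gte(mean(surviving[clonal]), 0.9)
})

test_that("excluding the donor chromosome removes its local-hop cluster", {
  genome <- makeGenome(1e6, 2, seed = 91)
  sim <- simulateScreen(genome, nLibraries = 6, donorChrom = "chr2",
                        seed = 92)
  expect_equal(sim$excluded, "chr2")
  screen <- processScreen(sim$reads, sim$barcodes, sim$trimConfig, genome,
                          metadata = sim$metadata)
  ev <- insertEvents(screen)
  expect_true(any(as.character(GenomicRanges::seqnames(ev)) == "chr2"))
  kept <- excludeChromosomes(ev, sim$excluded)
  expect_false(any(as.character(GenomicRanges::seqnames(kept)) == "chr2"))
  # the donor cluster in the truth table sat on chr2
  expect_gte(sum(sim$truth$class == "donor_hop" &
                   sim$truth$chrom == "chr2"), 6L)
})

test_that("random-position simulation is uniform-ish, labelled and reproducible", {
  ev <- simulateRandomPositions(10000, 2.5e9, 20, seed = 101)
  expect_equal(sum(ev$readCount), 10000)
  expect_equal(length(ev), 10000L)          # no bin collisions at this seed
  expect_identical(
    as.data.frame(simulateRandomPositions(10000, 2.5e9, 20, seed = 101)),
    as.data.frame(ev))
  expect_false(identical(
    as.data.frame(simulateRandomPositions(10000, 2.5e9, 20, seed = 102)),
    as.data.frame(ev)))
  expect_equal(length(unique(ev$library)), 20L)
  expect_setequal(as.character(unique(GenomicRanges::strand(ev))),
                  c("+", "-"))
  expect_error(simulateRandomPositions(0, 1e6, 2))
})

test_that("simulator inputs round-trip through the pipeline input files", {
  genome <- makeGenome(3e5, 1, seed = 111)
  sim <- simulateScreen(genome, nLibraries = 3, clonalBackground = 3,
                        passengersPerLibrary = 1, clonalReadsMean = 5,
                        seed = 112)
  dir <- tempfile()
  writeSimInputs(sim, genome, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "seqs.tab", "barcodes.tsv", "metadata.tsv", "exclude.txt",
    "genome.fa", "chrom.sizes", "truth.tsv")))))
  reads <- readReads(file.path(dir, "seqs.tab"))
  expect_equal(nrow(reads), sum(sim$reads$count))  # multiplicities expanded
  bc <- readBarcodeTable(file.path(dir, "barcodes.tsv"))
  g2 <- readGenome(file.path(dir, "genome.fa"), file.path(dir, "chrom.sizes"))
  expect_equal(chromSizes(g2), chromSizes(genome))
  md <- readMetadataTable(file.path(dir, "metadata.tsv"))
  expect_equal(sort(md$all), sort(sim$metadata$all))
  a <- processScreen(reads, bc, sim$trimConfig, g2, metadata = md)
  b <- processScreen(sim$reads, sim$barcodes, sim$trimConfig, genome,
                     metadata = sim$metadata)
  expect_equal(as.data.frame(insertEvents(a)), as.data.frame(insertEvents(b)))
})
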