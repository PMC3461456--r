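test_that("default schedule matches the published length/mismatch cutoffs", {
  s <- defaultSchedule()
  expect_equal(nrow(s), 5L)
  expect_true(is.na(s$prefixLength[1]) && s$maxMismatches[1] == 3L)
  expect_equal(unlist(s[3, ]), c(prefixLength = 30L, maxMismatches = 2L))
  expect_equal(unlist(s[5, ]), c(prefixLength = 24L, maxMismatches = 0L))
})

test_that("alignPrefix finds planted fragments and agrees with brute force", {
  genome <- makeGenome(50000, 2, seed = 3)
  chr1 <- as.character(genomeSeqs(genome)[["chr1"]])

  planted <- substr(chr1, 1001, 1040)
  hits <- alignPrefix(planted, genome, 40, 0L)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$pos, 1000L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$mismatches, 0L)

  # planted twice -> two hits
  dup <- substr(chr1, 2001, 2040)
  genome2 <- genomeFromSeqs(c(chr1 = chr1,
                              chr2 = paste0(randomSeq(500), dup,
                                            randomSeq(500))))
  expect_equal(nrow(alignPrefix(dup, genome2, 40, 0L)), 2L)

  # one substitution: invisible at max 0, found at max 1
  mut <- planted
  substr(mut, 20, 20) <- chartr("ACGT", "TGCA", substr(mut, 20, 20))
  expect_equal(nrow(alignPrefix(mut, genome, 40, 0L)), 0L)
  h1 <- alignPrefix(mut, genome, 40, 1L)
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$mismatches, 1L)

  # full agreement with the brute-force Hamming oracle, both strands
  set.seed(9)
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  pats <- c(substr(chr1, 5001, 5033), revcomp(substr(chr1, 7001, 7033)),
            replicate(3, randomSeq(33)), mut)
  for (p in pats)
    for (mm in c(0L, 2L))
      expect_identical(sortHits(alignPrefix(p, genome, nchar(p), mm)),
                       sortHits(bruteAlignOracle(p, genome, nchar(p), mm)))
})

test_that("batch seeded alignment equals the single-pattern reference", {
  genome <- makeGenome(80000, 2, seed = 21)
  chr2 <- as.character(genomeSeqs(genome)[["chr2"]])
  set.seed(22)
  pats <- c(vapply(1:15, function(i) {
    p <- substr(chr2, i * 2000, i * 2000 + sample(33:60, 1))
    if (i %% 3 == 0)  # sprinkle mismatches
      substr(p, 5, 5) <- chartr("ACGT", "TGCA", substr(p, 5, 5))
    p
  }, ""), replicate(5, randomSeq(40)))
  for (mm in c(0L, 3L)) {
    batch <- tnCIS:::.alignBatch(pats, genome, mm)
    for (i in seq_along(pats))
      expect_identical(sortHits(batch[[i]]),
                       sortHits(alignPrefix(pats[i], genome,
                                            nchar(pats[i]), mm)))
  }
})

test_that("iterative mapping assigns stages, discards and retires correctly", {
  genome <- makeGenome(2e5, 1, seed = 7)
  chr1 <- as.character(genomeSeqs(genome)[["chr1"]])
  frag <- function(seq, lib = "tum1-R") data.frame(
    library = "tum1", directionalLibrary = lib, side = "right", seq = seq,
    readCount = 1, stringsAsFactors = FALSE)

  clean60 <- substr(chr1, 10001, 10060)
  # 8 corrupted tail bases: full-length fails at 3 mm, 33-bp prefix is clean
  dirty60 <- paste0(substr(clean60, 1, 52),
                    chartr("ACGT", "TGCA", substr(clean60, 53, 60)))
  short26 <- substr(chr1, 30001, 30026)
  short23 <- substr(chr1, 50001, 50023)
  # plant a duplicated 40-mer on a second chromosome -> multimapper
  dup40 <- substr(chr1, 70001, 70040)
  genome2 <- genomeFromSeqs(c(chr1 = chr1,
                              chr2 = paste0(randomSeq(300), dup40,
                                            randomSeq(300))))

  frags <- rbind(frag(clean60), frag(dirty60), frag(short26), frag(short23),
                 frag(dup40))
  out <- mapIteratively(frags, genome2)

  expect_equal(out$stats$too_short_fragments, 1L)   # 23-mer discarded
  expect_equal(out$stats$multimapped_fragments, 1L)
  expect_equal(nrow(out$mappings), 3L)

  m <- out$mappings
  expect_equal(m$stage[m$seq == clean60], 1L)
  expect_equal(m$stage[m$seq == dirty60], 2L)       # rescued by 33-bp prefix
  expect_equal(m$pos[m$seq == dirty60], 10000L)
  expect_equal(m$stage[m$seq == short26], 5L)
  expect_equal(m$mismatches[m$seq == short26], 0L)
  # invariants: mismatch allowance respected, mapped prefix >= 24
  sched <- defaultSchedule()
  expect_true(all(m$mismatches <= sched$maxMismatches[m$stage]))
  expect_true(all(nchar(m$seq) >= 24L))
})

test_that("iterative mapping is deterministic and order-independent", {
  genome <- makeGenome(1e5, 1, seed = 13)
  chr1 <- as.character(genomeSeqs(genome)[["chr1"]])
  frags <- data.frame(
    library = "t", directionalLibrary = "t-R", side = "right",
    seq = vapply(seq(1000, 40000, by = 1500), function(i)
      substr(chr1, i, i + 45), ""),
    readCount = 1, stringsAsFactors = FALSE)
  a <- mapIteratively(frags, genome)$mappings
  b <- mapIteratively(frags[rev(seq_len(nrow(frags))), ], genome)$mappings
  o <- function(x) { x <- x[order(x$seq), ]; rownames(x) <- NULL; x }
  expect_identical(o(a), o(b))
})

test_that("SAM import converts coordinates, strands and drops non-unique records", {
  frags <- data.frame(id = c("f1", "f2", "f3", "f4"),
                      library = "tum1", directionalLibrary = "tum1-R",
                      side = "right",
                      seq = replicate(4, randomSeq(33)),
                      readCount = c(5, 1, 2, 1), stringsAsFactors = FALSE)
  sam <- tempfile(fileext = ".sam")
  q <- strrep("I", 33)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:10000",
    paste("f1", 0, "chr1", 101, 42, "33M", "*", 0, 0, frags$seq[1], q,
          sep = "\t"),
    paste("f2", 4, "*", 0, 0, "*", "*", 0, 0, frags$seq[2], q, sep = "\t"),
    paste("f3", 16, "chr1", 168, 42, "33M", "*", 0, 0, frags$seq[3], q,
          sep = "\t"),
    paste("f4", 0, "chr1", 501, 3, "33M", "*", 0, 0, frags$seq[4], q,
          sep = "\t"),
    paste("f4", 256, "chr1", 901, 3, "33M", "*", 0, 0, "*", "*", sep = "\t")
  ), sam)
  m <- importSAM(sam, frags)
  expect_equal(nrow(m), 2L)                       # f2 unmapped, f4 multi
  expect_equal(m$pos[m$seq == frags$seq[1]], 100L)  # 1-based 101 -> 0-based
  expect_equal(m$strand[m$seq == frags$seq[1]], "+")
  # reverse record ends 1-based at 168+33-1=200 -> first base 0-based 199
  expect_equal(m$pos[m$seq == frags$seq[3]], 199L)
  expect_equal(m$strand[m$seq == frags$seq[3]], "-")
})

test_that("SAM adapter and built-in aligner agree on a planted fixture", {
  genome <- makeGenome(50000, 1, seed = 31)
  chr1 <- as.character(genomeSeqs(genome)[["chr1"]])
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  # reverse-strand fragment whose first base sits at 0-based 20032
  fragSeq <- revcomp(substr(chr1, 20001, 20033))
  frags <- data.frame(id = "r1", library = "tum1",
                      directionalLibrary = "tum1-R", side = "right",
                      seq = fragSeq, readCount = 1, stringsAsFactors = FALSE)
  builtin <- alignPrefix(fragSeq, genome, 33, 0L)
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               "@SQ\tSN:chr1\tLN:50000",
               paste("r1", 16, "chr1", 20001, 42, "33M", "*", 0, 0,
                     revcomp(fragSeq), strrep("I", 33), sep = "\t")), sam)
  m <- importSAM(sam, frags)
  expect_equal(m$pos, builtin$pos)
  expect_equal(m$strand, builtin$strand)
  expect_equal(m$pos, 20032L)
})

test_that("random sequences quantify the false unique-mapping rate", {
  expect_error(estimateFalseMappingRate(0, 33, 3, makeGenome(1e4, 1)), "n")
  genome <- makeGenome(5e6, 2, seed = 17)
  # at the schedule's cutoff length random sequences essentially never map
  atCutoff <- estimateFalseMappingRate(25, 33, 3, genome, seed = 18)
  expect_lte(atCutoff$uniqueFraction, 0.05)
  # far below the cutoff nearly every random sequence hits the genome
  short <- estimateFalseMappingRate(25, 10, 0, genome, seed = 19)
  expect_gte(short$anyHitFraction, 0.95)
})
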