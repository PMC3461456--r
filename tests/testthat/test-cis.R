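test_that("Poisson upper tail matches direct pmf summation and is monotone", {
  expect_equal(poissonUpperTail(0, 0.5), 1.0)
  expect_equal(poissonUpperTail(0, 7), 1.0)
  expect_equal(poissonUpperTail(1, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poissonUpperTail(7, 0.186), poisTailOracle(7, 0.186),
               tolerance = 1e-14)
  for (u in c(0.01, 0.2, 1, 4))
    for (x in c(0:5, 20, 60))
      expect_lt(abs(poissonUpperTail(x, u) - poisTailOracle(x, u)), 1e-12)
  # decreasing in x at fixed u, increasing in u at fixed x
  expect_true(all(diff(poissonUpperTail(0:30, 2)) < 0))
  expect_true(all(diff(poissonUpperTail(5, c(0.1, 0.5, 1, 2, 5))) > 0))
  expect_error(poissonUpperTail(3, 0))
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroniCorrect(0.001, 100), 0.1)
  expect_equal(bonferroniCorrect(0.5, 10), 1.0)
  expect_equal(bonferroniCorrect(0.123, 1), 0.123)
  expect_error(bonferroniCorrect(0.01, 0))
})

test_that("window plan uses defaults outside bounds, brute force within", {
  cfg <- scanConfig(genomeSize = 2.5e9)
  defaults <- c(301000, 200000, 100000, 50000, 25000, 12500)
  expect_equal(determineWindowSizes(1500, cfg), defaults)
  expect_equal(determineWindowSizes(250000, cfg), defaults)
  plan <- determineWindowSizes(20000, cfg)
  expect_equal(plan, windowPlanOracle(20000, cfg))
  expect_true(all(diff(plan) < 0))
  expect_lte(max(plan), cfg@wMax)
  expect_gte(min(plan), cfg@wMin)
  # minimal significant count is non-decreasing in window size
  ws <- seq(cfg@wMin, cfg@wMax, by = 25000)
  kmin <- vapply(ws, function(w)
    tnCIS:::.minSignificantCount(20000 * w / cfg@genomeSize, 20000, 0.05),
    integer(1))
  expect_true(all(diff(kmin) >= 0))
})

test_that("counting schemes distinguish inserts, libraries and regions", {
  # 10 inserts from 6 libraries; 6 of them share one 100-bp region and the
  # other 4 sit in 4 distinct regions
  ev <- makeEvents(
    chrom = "chr1",
    binStart = c(rep(5000, 6), 5300, 5600, 6200, 7000),
    library = c(paste0("t", 1:6), "t1", "t2", "t3", "t4"))
  expect_equal(countEvents("chr1", 4000, 14000, ev, "insert"), 10L)
  expect_equal(countEvents("chr1", 4000, 14000, ev, "library"), 6L)
  expect_equal(countEvents("chr1", 4000, 14000, ev, "region"), 5L)
  expect_equal(countEvents("chr1", 5100, 5700, ev, "insert"), 2L)
  expect_equal(countEvents("chr2", 0, 1e6, ev, "insert"), 0L)
})

test_that("peak finding selects covering non-overlapping significant windows", {
  cfg <- scanConfig(genomeSize = 2.5e9, alpha = 0.05)
  # two nearby events merge into one selected window covering both
  ev <- makeEvents("chr1", c(100, 150 + 100), paste0("t", 1:2))
  pk <- findPeaks(ev, 10000, cfg)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 100)
  expect_equal(pk$count, 2L)
  # under a dense background the same pair is no longer significant
  totals <- list(nInserts = 5000L, nRegions = 5000L)
  expect_equal(nrow(findPeaks(ev, 10000, cfg, totals = totals)), 0L)

  # 3 isolated single events: never significant (one insert is not a CIS)
  iso <- makeEvents("chr1", c(0, 50000, 120000), "t1")
  expect_equal(nrow(findPeaks(iso, 10000, cfg)), 0L)

  # clustered events among diffuse background: the peak captures the cluster
  set.seed(5)
  bg <- makeEvents("chr1", sort(sample.int(1.5e7, 200)) * 100,
                   sample(paste0("t", 1:10), 200, TRUE))
  cl <- makeEvents("chr1", 5e6 + c(0, 6, 13, 21, 28, 34, 42, 49) * 100,
                   paste0("t", 1:8))
  ev2 <- sort(c(bg, cl), ignore.strand = TRUE)
  pk2 <- findPeaks(ev2, 25000, cfg)
  expect_gte(nrow(pk2), 1L)
  top <- pk2[which.max(pk2$count), ]
  expect_equal(top$count, 8L)
  expect_lte(top$start, 5e6)
  expect_gt(top$end, 5e6 + 4900)
})

test_that("peak finding equals exhaustive greedy enumeration", {
  cfg <- scanConfig(genomeSize = 1e8, alpha = 0.05)
  set.seed(77)
  for (rep in 1:8) {
    n <- sample(30:120, 1)
    ev <- makeEvents(sample(c("chr1", "chr2"), n, TRUE),
                     sort(sample.int(5e5, n)) * 100,
                     sample(paste0("t", 1:8), n, TRUE))
    ev <- sort(ev, ignore.strand = TRUE)
    w <- sample(c(10000, 25000, 50000), 1)
    u <- n * w / cfg@genomeSize
    kmin <- tnCIS:::.minSignificantCount(u, n, cfg@alpha)
    mine <- findPeaks(ev, w, cfg)
    oracle <- exhaustivePeaksOracle(ev, w, kmin)
    expect_equal(mine$chrom, oracle$chrom)
    expect_equal(mine$start, oracle$start)
    expect_equal(mine$count, oracle$count)
  }
})

test_that("cross-window-size resolution prefers low p then larger windows", {
  cand <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000, 5000, 0),
    end = c(34000, 49000, 10000),
    windowSize = c(24000, 44000, 10000),
    count = c(7, 7, 3),
    pRaw = c(1e-8, 1e-6, 1e-3),
    pCorrected = c(1e-4, 1e-2, 1),
    stringsAsFactors = FALSE)
  out <- resolveAcrossWindowSizes(cand)
  expect_equal(out$windowSize[out$chrom == "chr1"], 24000)  # lower p wins
  expect_equal(nrow(out), 2L)                      # non-overlapping retained

  tie <- data.frame(chrom = "chr1", start = c(1000, 0),
                    end = c(11000, 44000), windowSize = c(10000, 44000),
                    count = c(5, 5), pRaw = c(1e-7, 1e-7),
                    pCorrected = c(1e-3, 1e-3), stringsAsFactors = FALSE)
  expect_equal(resolveAcrossWindowSizes(tie)$windowSize, 44000)
})

test_that("callCIS handles degenerate inputs and is deterministic", {
  cfg <- scanConfig(genomeSize = 2.5e9)
  empty <- makeEvents("chr1", numeric(), character())
  expect_equal(length(callCIS(empty, cfg)), 0L)
  one <- makeEvents("chr1", 100, "t1")
  expect_equal(length(callCIS(one, cfg)), 0L)

  set.seed(8)
  bg <- makeEvents("chr1", sort(sample.int(2e6, 2500)) * 100,
                   sample(paste0("t", 1:12), 2500, TRUE),
                   orientation = sample(c("+", "-"), 2500, TRUE))
  cl <- makeEvents("chr1", 9e7 + c(0, 4, 9, 15, 22, 30, 37, 41, 44, 48) * 100,
                   paste0("t", 1:10))
  ev <- sort(c(bg, cl), ignore.strand = TRUE)
  a <- callCIS(ev, cfg)
  b <- callCIS(ev, cfg)
  expect_identical(cisTable(a), cisTable(b))
  # the planted cluster is found with all three p-values significant
  tab <- cisTable(a)
  hit <- tab[tab$start <= 9e7 & tab$end >= 9e7 + 4900, ]
  expect_equal(nrow(hit), 1L)
  expect_lt(hit$pInsert, 0.05)
  expect_lt(hit$pLibrary, 0.05)
  expect_lt(hit$pRegion, 0.05)
  expect_gte(hit$insertCount, 10L)
  # all 10 planted events drive the + strand; background may add more
  expect_gte(hit$nPosStrand, 10L)
  expect_lte(hit$nPosStrand, hit$insertCount)
  # structural invariants
  expect_true(all(tab$regionCount <= tab$insertCount))
  expect_true(all(tab$libraryCount <= tab$insertCount))
  expect_true(!is.unsorted(tab$pRegion))
})
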