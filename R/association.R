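#' Build the library-by-(CIS, phenotype) presence matrix
#'
#' Binary incidence used by all Fisher tests: a CIS column is `TRUE` for a
#' library with at least one insertion event inside the final CIS interval
#' (read counts are not used); a phenotype column is `TRUE` for members of
#' the metadata group. CIS columns are restricted to CISs with region
#' p-value below `cisPFilter` (default 1e-5), so that only well-supported
#' CISs enter association testing.
#'
#' @param cisSet a [CISSet-class].
#' @param events event `GRanges` used for the CIS calls.
#' @param metadata named list of library groups, including the superset
#'   `"all"` (defines the library universe and row order).
#' @param cisPFilter maximum region p-value for a CIS column.
#' @return logical matrix, one row per library; CIS columns are named
#'   `chrom:start-end` (1-based), phenotype columns by group name. The
#'   column split is recorded in attributes `cisColumns` / `phenoColumns`.
#' @export
buildPresenceMatrix <- function(cisSet, events, metadata, cisPFilter = 1e-5) {
  metadata <- validateMetadata(metadata)
  libs <- metadata$all
  evLibs <- unique(events$library)
  if (length(setdiff(evLibs, libs)))
    stop("event libraries missing from metadata group \"all\": ",
         paste(utils::head(setdiff(evLibs, libs), 3L), collapse = ", "))
  gr <- cisRanges(cisSet)
  gr <- gr[gr$pRegion < cisPFilter]
  cisNames <- if (length(gr))
    paste0(seqnames(gr), ":", start(gr), "-", end(gr)) else character()
  m <- matrix(FALSE, nrow = length(libs),
              ncol = length(gr) + length(metadata),
              dimnames = list(libs, c(cisNames, names(metadata))))
  if (length(gr) && length(events)) {
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(events, gr, ignore.strand = TRUE))
    if (length(ov))
      m[cbind(match(events$library[queryHits(ov)], libs),
              subjectHits(ov))] <- TRUE
  }
  for (g in names(metadata))
    m[libs %in% metadata[[g]], length(gr) + match(g, names(metadata))] <- TRUE
  attr(m, "cisColumns") <- cisNames
  attr(m, "phenoColumns") <- names(metadata)
  m
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, of outcomes no more probable than the
#' observed one (the same rule as `stats::fisher.test`, including its 1e-7
#' relative slack on the probability comparison). A one-sided enrichment
#' test (upper tail on the co-occurrence cell) is available for directional
#' questions.
#'
#' @param a,b,c,d cell counts: a = both present, b = first only, c = second
#'   only, d = neither.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return p-value.
#' @examples
#' fisherExact2x2(5, 0, 0, 5)
#' @export
fisherExact2x2 <- function(a, b, c, d,
                           alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  n <- a + b + c + d
  if (n < 1) stop("table must contain at least one observation")
  r1 <- a + b          # white balls
  c1 <- a + c          # drawn
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  pObs <- stats::dhyper(a, r1, n - r1, c1)
  if (alternative == "greater")
    sum(probs[support >= a])
  else
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Adjust p-values for multiple testing
#'
#' @param pvals raw p-values.
#' @param method `"bonferroni"` or `"bh"` (Benjamini-Hochberg step-up).
#' @param nTests family size; defaults to `length(pvals)` but may be larger
#'   when the family formula counts tests that were not all computed.
#' @return adjusted p-values, capped at 1.
#' @examples
#' adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "bh")
#' @export
adjustPvalues <- function(pvals, method = c("bonferroni", "bh"),
                          nTests = length(pvals)) {
  method <- match.arg(method)
  stats::p.adjust(pvals, method = if (method == "bh") "BH" else "bonferroni",
                  n = max(nTests, length(pvals)))
}

.pairTests <- function(m, colsA, colsB, symmetric, nTests, alternative) {
  pairs <- if (symmetric) {
    if (length(colsA) < 2L) return(NULL)
    t(utils::combn(colsA, 2L))
  } else {
    if (!length(colsA) || !length(colsB)) return(NULL)
    as.matrix(expand.grid(colsA, colsB, stringsAsFactors = FALSE))
  }
  res <- data.frame(itemA = pairs[, 1L], itemB = pairs[, 2L],
                    a = NA_integer_, b = NA_integer_, c = NA_integer_,
                    d = NA_integer_, pRaw = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    x <- m[, res$itemA[i]]
    y <- m[, res$itemB[i]]
    res$a[i] <- sum(x & y); res$b[i] <- sum(x & !y)
    res$c[i] <- sum(!x & y); res$d[i] <- sum(!x & !y)
    res$pRaw[i] <- fisherExact2x2(res$a[i], res$b[i], res$c[i], res$d[i],
                                  alternative = alternative)
  }
  res$pBonferroni <- adjustPvalues(res$pRaw, "bonferroni", nTests)
  res$pBH <- adjustPvalues(res$pRaw, "bh", nTests)
  res$nTests <- nTests
  res[order(res$pRaw), , drop = FALSE]
}

#' Run phenotype-CIS, CIS-CIS and phenotype-phenotype associations
#'
#' Three separate test families over the presence matrix, each corrected
#' within itself: phenotype x CIS (family size = n_pheno * n_cis), CIS x CIS
#' and phenotype x phenotype (n(n-1)/2 each). The constant superset column
#' `"all"` is excluded from testing.
#'
#' @param m presence matrix from [buildPresenceMatrix()].
#' @param alternative Fisher sidedness (see [fisherExact2x2()]).
#' @param excludeColumns additional column names to drop before testing
#'   (e.g. a Y-chromosome CIS artifact).
#' @return list of three `data.frame`s (`phenoCIS`, `coCIS`, `phenoPheno`),
#'   each with the 2x2 counts, raw, Bonferroni and BH p-values, sorted by
#'   raw p.
#' @export
runAssociations <- function(m, alternative = c("two.sided", "greater"),
                            excludeColumns = character()) {
  alternative <- match.arg(alternative)
  cisCols <- setdiff(attr(m, "cisColumns"), excludeColumns)
  phenoCols <- setdiff(attr(m, "phenoColumns"), c("all", excludeColumns))
  nCis <- length(cisCols)
  nPh <- length(phenoCols)
  list(
    phenoCIS = .pairTests(m, phenoCols, cisCols, FALSE,
                          nTests = nPh * nCis, alternative),
    coCIS = .pairTests(m, cisCols, NULL, TRUE,
                       nTests = nCis * (nCis - 1) / 2, alternative),
    phenoPheno = .pairTests(m, phenoCols, NULL, TRUE,
                            nTests = nPh * (nPh - 1) / 2, alternative)
  )
}
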