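---
title: "Detecting common insertion sites in transposon screens"
author: "tnCIS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting common insertion sites in transposon screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnCIS)
```

## The problem

Forward genetic screens mobilise a transposon (Sleeping Beauty) or a
retrovirus through the genome of a mouse cohort; insertions that disrupt a
tumor suppressor or activate an oncogene give the carrying cell a growth
advantage, and the resulting tumors are sequenced by ligation-mediated PCR
of the junction fragments between the inserted element and flanking genomic
DNA. A locus hit independently in many tumors — a Common Insertion Site
(CIS) — is a candidate cancer driver. `tnCIS` turns raw barcoded junction
reads into a ranked CIS table and tests CIS–phenotype and CIS–CIS
co-occurrence.

## From reads to insertion events

A read is barcode + transposon terminal repeat (IRDR/LTR) + genomic
fragment, optionally ending in the ligation linker. `demuxTrim()` matches
the barcode at the 5' end (exact by default — `barcodeMismatches` relaxes
this, with N never matching and ties rejected), requires the transposon tag
to follow exactly, truncates at the first full linker occurrence, and (for
SB screens) rejects fragments not starting with the TA dinucleotide the
transposase integrates into. Rejections are counted per class, never fatal,
and reads are conserved: assigned + rejected = input. Identical fragments
from one directional library collapse to a single record with a total count.

Mapping requires the alignment to begin at the first base 3' of the
transposon and to be unique. Because partial linker carryover contaminates
3' ends, `mapIteratively()` runs five rounds of end-to-end prefix alignment
with decreasing length and mismatch allowance: full length (> 33 bp) at 3
mismatches, then 33/3, 30/2, 28/1 and 24/0. The cutoffs are the published
empirical lengths below which random sequences begin to map a mammalian
genome uniquely; fragments of 23 bp or fewer are discarded, and
`estimateFalseMappingRate()` reproduces that calibration on any genome. A
fragment with two or more hits at a stage is retired rather than retried:
shortening a prefix can only add hits, so uniqueness cannot be recovered
later. The built-in aligner (Biostrings matching plus a pigeonhole
seed-and-verify batch mode, both returning every hit at Hamming distance
up to the allowance on either strand) serves small genomes and simulations;
production-scale data goes through the SAM adapter `importSAM()`, which
performs the same reverse-strand coordinate conversion.

Each tumor is amplified from the left and the right side of the insertion
separately (`-L`/`-R` directional libraries). The element is asymmetric, so
a right-side read on the + strand and a left-side read on the − strand both
mean an insertion oriented to activate transcription on the + strand;
`resolveOrientation()` folds all four combinations onto that biological
orientation before the sides are merged per tumor.

Two artifact classes are then absorbed:

* **Local hopping / early sequencing errors** scatter reads from one clonal
  insertion across neighbouring TA sites. Mapped positions are binned into
  fixed genome-anchored 100-bp tiles by (library, tile, orientation); the
  tile grid (rather than insertion-centred windows) makes results
  reproducible bit for bit.
* **Passenger insertions** arise late, in few cells, and are read once or
  twice. `applyCutoff()` keeps an event only if its reads are at least a
  configurable fraction of the library's mapped total — 1/10,000 is the
  recommended setting for Illumina-depth data, and no cutoff for
  454-depth data (the default). The comparison is `>=`, so a library with
  100,000 mapped reads keeps exactly the regions with 10 or more reads at
  the 1/10,000 setting. The cutoff runs after binning, so hop reads
  collapsed into a bin count toward its survival.

The donor chromosome (where the transposon concatamer resided) is enriched
for local hops and can be excluded wholesale; the scan's genome size is
recomputed as the sum of the included chromosome lengths.

## The Poisson scan

Insertion events are modelled as uniform on the genome. For a window of
size $w$ on a genome of size $G$ carrying $N$ events in total, the expected
count is $u = N w / G$ and the surprise of observing $x$ events is the
upper Poisson tail. Windows are anchored at every event position, one
candidate per event, scored by three counting schemes that test three
nulls: unique insert events, unique contributing libraries (immune to local
hopping), and unique 100-bp regions (immune to the many-libraries-one-TA
artifact caused by false priming or barcode bleed-through). A reported CIS
must by default be significant under all three; each threshold is
user-definable.

Two refinements matter for calibration, and both are deliberate design
choices of this package:

* **Anchor conditioning.** A window anchored at an event contains that
  event by construction, so its null surprise lives in the other $x - 1$
  events: the scan uses $P(X \ge x - 1)$, not $P(X \ge x)$. Without this,
  a window holding $k_{min}$ events needs only $k_{min}-1$ chance
  neighbours, and uniformly random data yields on the order of one
  "significant" window per run.
* **The full Bonferroni family.** The multiplier is the total number of
  windows examined: $N$ anchors times the number of window sizes scanned.
  Together these control the familywise error of the whole scan at
  $\alpha$, and uniform random datasets come out empty — the property the
  method is validated against (the `null_clean_seed_pct` quantity of
  `scripts/acceptance.R`, and the null-control test).
* A lone insertion is never a *common* insertion site: the minimal
  significant count is floored at 2, whatever the arithmetic says at very
  small $N$.

Window sizes are chosen by the published rule, kept verbatim because it
defines the plan rather than the error rate: for each integer event count,
the largest $w$ in 10,000–301,000 bp (1,000-bp steps) whose plainly
corrected tail ($P(X \ge k) \cdot N$) clears $\alpha = 0.05$; datasets with
fewer than 2,000 or more than 200,000 events use the fixed list 12,500,
25,000, 50,000, 100,000, 200,000, 301,000. Within one window size, peaks
are picked greedily — highest count first, ties to the lowest genomic
coordinate, overlaps discarded — which on instances small enough to
enumerate equals exhaustive search under the same rule. Across window
sizes, candidates are resolved by ascending p-value with exact ties going
to the larger window. All three p-values are recomputed on each final
window; the insert and library schemes share $u$ based on total insert
events (keeping the library test conservative, since libraries cannot
outnumber inserts), while the region scheme draws $u$ from the genome-wide
count of distinct occupied tiles.

```{r scan-example}
ev <- simulateRandomPositions(10000, 2.5e9, nLibraries = 20, seed = 1)
callCIS(ev, scanConfig(genomeSize = 2.5e9))
```

## Associations

`buildPresenceMatrix()` reduces the screen to a binary libraries ×
(CISs ∪ phenotypes) incidence: a library carries a CIS if at least one of
its events falls in the final interval (read counts are not reused), and
CIS columns are restricted to region p-values below 1e-5 so that only
well-supported loci spend test budget. Fisher's exact test (two-sided by
default, so co-CIS picks up mutual exclusivity as well as co-occurrence;
`alternative = "greater"` gives directional enrichment) runs in three
separately corrected families — phenotype × CIS ($n_{ph} n_{cis}$ tests),
CIS × CIS and phenotype × phenotype ($n(n-1)/2$ each) — with Bonferroni and
Benjamini–Hochberg columns. The constant superset group `"all"` is excluded
from testing, and any column (e.g. a Y-chromosome artifact CIS) can be
dropped before testing.

## Annotation and outputs

`annotateCIS()` lists every gene-BED record within 20,000 bp of a CIS
(edge-to-edge; overlap is distance zero), writing the literal statement
"No results within a 20,000 bp window" when the neighbourhood is empty.
Records whose name contains the string `BAD` mark known artifact regions —
genomic sequence carried inside the transposon itself, or mis-assembled
high-copy regions that recur in selection-free control data — and any CIS
touching one is suppressed from the report. `writeTracks()` emits the raw
mapping BED (read strand), the insertion BED (biological orientation), a
variable-span WIG with peak height $-\log_{10}$ of the region p-value, and
the CIS/association/summary TSVs; BED output is 0-based half-open, matching
the package's internal convention (conversion to 1-based containers happens
only at the GRanges boundary).

## The simulator and what passing means

`simulateScreen()` is the package's test bed: it emits barcoded reads of
the real layout (barcode + tag + genomic + linker carryover of random
extent, genomic parts 15–70 bp so that every mapping stage and the
too-short discard are exercised) from a planted truth table of clonal
background insertions (log-normal read counts, median 2,500), passengers
(1–2 reads), local hops (within 5 kb of a clonal parent — the distance is
our choice; it keeps hops near but not inside the parent's bin), an
optional shared-TA artifact, an optional donor-chromosome hop cluster, and
driver loci assigned to chosen library subsets. Within a driver locus each
participating library integrates at its own TA inside a 4-kb span, since
selection acts on the gene, not on one TA — which is also what gives driver
loci honest region counts. Default screens use 20 libraries (groups `grpA`
12 / `grpB` 8) on 20-Mb four-chromosome genomes: about 250 post-cutoff
events, one per ~80 kb, comparable to the per-Mb event density of a real
screen while keeping a ten-seed recovery study inside minutes. Everything
is deterministic per seed.

The simulator emulates read structure, abundance classes and artifact
geometry; it does **not** model sequencing substitution errors, indels,
chimeric reads, restriction-site biased fragment recovery, TA-density
variation along real chromosomes, or copy-number-driven mapping artifacts.
Recovery of planted drivers therefore validates the statistics and the
plumbing, not robustness to base-call noise; the mapping stages are instead
validated directly against a brute-force Hamming oracle.

## Numerical choices and limitations

* Coordinates are 0-based half-open internally; GRanges (1-based) only at
  container boundaries; WIG/BED writers localise the conversions.
* Peak ties break to the lowest coordinate, cross-size p ties to the larger
  window, then coordinate — scans are byte-reproducible.
* `poissonUpperTail()` delegates to `ppois(lower.tail = FALSE)` (stable in
  log space) and is pinned to a direct pmf-summation oracle at 1e-12;
  `fisherExact2x2()` sums `dhyper` over the margin support with the
  standard `1 + 1e-7` relative slack of the minimum-likelihood two-sided
  rule and is pinned to full enumeration.
* Windows may overhang chromosome ends (no truncation); with event-anchored
  windows this only pads the final interval.
* Gapped or quality-aware alignment is out of scope; paired-end reads are
  not modelled (the underlying protocols are single-end LM-PCR); UMIs and
  model-based clonality deconvolution are not attempted — the read-fraction
  cutoff is a deliberately simple filter whose single parameter is exposed.
* The scan assumes insertions are exchangeable across the included genome;
  TA-density variation makes the Poisson null locally mis-specified, which
  is one reason the region p-value and the BAD-region suppression exist.
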