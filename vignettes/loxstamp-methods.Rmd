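---
title: "Timestamp barcodes: model, simulator and calling methods"
author: "loxstamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timestamp barcodes: model, simulator and calling methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxstamp)
```

## The system being modelled

Inducible genetic recording marks cells in a narrow temporal window. The
substrate is a single integrated cassette (one copy per cell, enforced
experimentally by low-MOI transduction) containing:

* a **tandem-loxP array**: spacer DNA blocks separated by loxP sites whose
  orientations alternate, giving converging site pairs. A pulse of active
  Cre (tamoxifen on Cre-ERT2) recombines the array once, at the chosen
  induction time. Same-orientation site pairs excise the intervening DNA
  irreversibly; opposite-orientation pairs invert it reversibly. The
  arrangement of oriented spacer segments left behind is the **Polylox
  barcode** — the *temporal* component;
* a **UCI** (unique clonal identifier): 10 random nucleotides fixed at
  integration, drawn from a plasmid library. Because Polylox recombination
  is strongly biased toward a limited set of products, the UCI restores the
  complexity needed to tell clones apart — the *static* component.

The (Polylox, UCI) pair is the **timestamp barcode** of a clone. Cells
carrying identical timestamps descend from one founder whose barcode was
fixed at induction; shared timestamps across transcriptome-defined lineages
therefore measure which lineages were still connected at induction time.

## Recombination model

A cassette state is an alternating token list of loxP sites and oriented
segments, beginning and ending with a site. Cre mechanics are implemented
as:

* **inversion** between opposite-orientation sites `i < j`: tokens strictly
  between them are reversed in order and orientation-flipped; boundary
  sites stay. Inversion is an involution.
* **excision** between same-orientation sites: the interval and one
  boundary site are deleted, leaving a single site at the junction;
  excision strictly reduces the token count.

These are the standard Cre-loxP biochemistry rules; they reproduce the
reversibility of inversions and the irreversibility of excisions that give
rise to the observed product bias. `enumerateBarcodes()` computes the
breadth-first closure over all legal events (memoised over full states, in
C++) and deduplicates by oriented-segment sequence, because sequencing
distinguishes products only by their spacer arrangement. The default
9-segment alternating design reaches 1,866,890 distinct arrangements, in
line with the ~1.8 million figure quoted for Polylox-scale cassettes. Note
that with ten alternating sites the two outermost sites have opposite
orientations, so the fully excised product is unreachable and every product
retains at least one segment — which is what lets a single purification
window retain all real products (below).

`simulateRecombination()` draws the number of events from Poisson(λ) and
samples each event with weight `w(i, j, kind) = kindWeight ·
exp(−bias · (j − i))`. The exponential span penalty (default `bias = 0.5`,
λ = 3) encodes the short-range preference that produces the strong bias
toward few products seen in real data; the true kinetics are not published,
so these weights are a qualitative stand-in and are fully configurable.

## Synthetic sequences and cassette geometry

The real spacer and flank sequences are not printed in any public table, so
the design generates synthetic sequences deterministically from a seed,
re-drawing until all reference blocks are pairwise well separated in edit
distance (unambiguous block mapping by construction). The default geometry —
60-nt spacers, a 300-nt pBC00 terminal block, 74-nt M13F and 104-nt
WPRE_M13R_HSV around the UCI, 20/24-nt flanks around a 12-nt cell barcode,
30-nt adapter padding — was chosen once so that

* the intact amplicon (1,484 bp) sits inside the 700–2,500 bp purification
  window, and
* the smallest reachable product (732 bp) also survives purification,

mirroring the geometry of the real cassette (2,317 bp intact) at a scale
that keeps simulation and alignment fast. Lengths are configurable per
segment; the published 2,317/621-bp lengths depend on the unpublished
sequences and are treated as design metadata, not reproducible quantities.

## The synthetic experiment

`simulateExperiment()` generates, from one seed with named per-stage
substreams:

1. **founders** (default 1,000, matching ~1,000 cells seeded per
   microwell), each receiving one UCI drawn abundance-weighted from a
   library of 5,000 distinct 10-mers with log-normal weights (σ = 0.5, a
   mildly skewed, "relatively uniform" distribution) and one recombined
   cassette. Founder UCI draws are with replacement by default — collisions
   are real and are exactly what the frequency filter exists to control —
   with `uciUnique = TRUE` available for analyses that require unique
   clonal identity;
2. **commitment**: under a day-0 induction all founders feed one shared
   pool and every cell samples its lineage independently from the global
   proportions; under a day-8 induction, founders are first committed (PGC
   by default, reflecting a lineage specified before the induction window)
   and committed founders produce only their lineage;
3. **cells**: fixed clonal expansion per founder (the linkage statistics
   depend only on shared barcodes, not pedigree depth), sampling without
   replacement, designed 12-nt cell barcodes (pairwise Hamming ≥ 3);
4. **reads**: per-cell counts are negative binomial with mean 50 — sitting
   deliberately above the >30-read consensus filter, consistent with
   saturation near 50 reads per barcode — with `readsDispersion = Inf`
   fixing counts exactly; amplicons outside the purification window are
   dropped before sequencing; each read is emitted on a random strand;
   cross-contamination swaps the embedded cell barcode with a configured
   probability; per-base substitution/insertion/deletion noise (defaults
   0.02/0.03/0.04) and uniform-position truncation of the sequenced strand
   (default probability 0.1) follow. The error and contamination defaults
   are plausible nanopore-scale placeholders, configurable because the real
   rates are not quantified.

Truth lives only in the emitted TSV tables; read identifiers carry no
information, so the caller cannot cheat.

What the generator does **not** emulate: basecalling from raw signal,
structured (homopolymer) error profiles, chimeric reads, doublets,
transcriptome-side noise in lineage labels (labels are consumed as an input
table, as in the real analysis), or branching pedigrees within clones.
Passing tests therefore demonstrate correctness of the computation under
an idealised nanopore error model, not performance on any particular real
data set.

## Barcode calling

Per read: the 20-nt upstream cell flank is located on both strands
(edit-distance search; Myers bit-parallel algorithm for patterns ≤ 64 nt,
banded-free DP otherwise); each whitelist barcode plus its 24-nt downstream
flank is scored inside the following window, and the read goes to the
unique best-scoring cell within `maxEditsCell` (ties are discarded, as are
reads without a flank hit — counted as unclassified QC). The read is then
oriented, every reference block is located on both strands (per-block
threshold 0.25 of block length, calibrated so shuffled sequences yield no
hits), ordered hits are assembled into the Polylox string (hit strand =
segment orientation; duplicate segments mark chimeras; both terminal flanks
bracketing the run mark a full-length observation), and the UCI is the
insert between M13F and WPRE_M13R_HSV when within ±2 nt of the design
length.

Per cell, both components pass three filters each:

1. **read support**: strictly more than 30 supporting reads (">30" is read
   as ≥ 31);
2. **outlier**: with ≥ 4 candidates, the top count must exceed Tukey's
   upper fence (Q3 + 1.5·IQR) of the remaining counts; with fewer, a
   dominance ratio top/second ≥ 3 (second = 0 passes). The original outlier
   statistic is not recoverable from the public description, so this
   scale-free rule is this package's own declared choice;
3. **identity**: the Polylox candidate must be observed full length in at
   least one supporting read (configurable to a majority rule — whether the
   published rule applies per read or per candidate is ambiguous); the UCI
   must be a member of the plasmid library whitelist when one is provided
   (skipped with a note otherwise).

Because every cell carries exactly one cassette, per-cell UCI observations
are collapsed before counting: sequencing-error variants within
`uciClusterDist = 3` edits are merged into the most abundant sequence
(greedy, descending-count order — the standard directional UMI-collapse
idea). Without this, a 10-mer under ~9% per-base error retains its exact
sequence in only ~40% of reads and the >30-read filter would reject most
true UCIs at 50 reads per cell; with it, the modal sequence recovers the
true UCI and the whitelist check keeps it honest. Setting
`uciClusterDist = 0` restores raw counting.

A cell receives a timestamp only when both components pass; failing cells
keep their QC row with the failing filters recorded.

## Frequency filter

Polylox recombination bias and uneven UCI abundance make some timestamps
common enough to be carried by multiple founders. Component frequencies are
computed over called cells within each scope (per embryoid body when EB
assignments exist, pooled otherwise; a reads-weighted mode is available
because the published description is ambiguous between cells and reads),
and the timestamp frequency is their **product** — the independence
estimator — with the empirical pair frequency emitted alongside for
diagnostics. Cells whose timestamp frequency strictly exceeds the cutoff
(default 5/1000) are removed; boundary values are retained; the standard
sensitivity sweep runs 1/1000, 3/1000, 5/1000 and 1/100.

## Linkage statistics

Cells with identical timestamps are connected; a barcode carried by *k*
cells yields choose(*k*, 2) edges. Lineage coupling is summarised two ways:

* **Spearman correlation** between lineage count vectors over shared
  (≥ 2 cells) barcodes; undefined correlations (constant vectors) are
  reported missing rather than zero;
* **observed-to-expected enrichment**: the published analysis names an
  observed/expected procedure without defining it, so it is reconstructed
  here as a label-permutation null — barcode assignments stay fixed,
  lineage labels are shuffled (default 1,000 seeded permutations), expected
  is the permutation mean, and two-sided empirical p-values use the add-one
  correction with Benjamini–Hochberg adjustment across lineage pairs. The
  null preserves both marginals' totals but not their joint structure;
  whether the original conditioned further is unknown.

The two structural signatures the statistics must recover: a day-0
induction connects every lineage pair (all lineages share the ESC founder
pool), and a day-8 induction with pre-committed PGC-like founders isolates
PGC — zero PGC–soma edges and an obs/exp of 0 — whenever founder UCIs are
unique.

## Numerical and design choices

* Coordinates are 1-based closed intervals and strands are `+`/`−`,
  following R/Bioconductor convention.
* All thresholds live in `callParams()` and are echoed into the run
  manifest; `runAll()` with one seed is byte-for-byte reproducible, with
  per-stage substreams derived from the top-level seed by a fixed integer
  hash.
* Lineage proportions default to EN 0.25, S.Ect 0.20, MES 0.25, BP 0.15,
  PGC 0.15 — stylised so every pairwise statistic has support at moderate
  cell counts. Real day-14 EBs have far fewer PGC-like cells (~2%); the
  defaults trade that realism for statistical power in structure tests, and
  are configurable.
* Problem sizes used by the test-suite and the acceptance script — 200
  cells × 50 reads for recovery checks, 400 sequenced cells for the
  induction-structure runs, 6,000 truth-only cells for permutation-null
  calibration — were chosen as the smallest scales at which the respective
  statistics are stable, keeping a full run in minutes on one CPU.
* The degenerate inputs all have defined behaviour: zero legal events stop
  recombination early; an all-zero bias warns and stops; empty FASTQ yields
  an empty, well-formed call table; scopes with zero calls are omitted with
  a warning; constant correlation vectors are `NA`.

## Known limitations

* The Cre event-weight model is phenomenological; absolute product
  frequencies should not be read as kinetic predictions.
* The outlier rule and the enrichment null are declared reconstructions of
  procedures the source describes only by name.
* Real-data mode expects basecalled FASTQ and a cell-barcode whitelist; no
  raw-signal processing or cross-sample demultiplexing is included.
* Counts of called/retained cells on real data (e.g. how many cells
  survive each filter) depend on read depth and library quality and are not
  reproducible from simulation; the package's guarantees are the structural
  and statistical properties exercised in `tests/`.
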