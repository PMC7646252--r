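# loxstamp

Simulation, calling and linkage analysis of **Cre-loxP timestamp barcodes**
for single-cell lineage tracing.

Rapid differentiation systems — embryoid bodies (EBs) modelling
pre-gastrulation development, for instance — complete their lineage
decisions in too few cell divisions for evolving (CRISPR-style) barcodes to
accumulate diversity. An inducible recombination cassette solves this by
writing a cell-specific barcode in a single narrow temporal window: a
tandem array of loxP sites with spacer blocks is recombined once when
Cre-ERT2 is pulsed with tamoxifen, and the arrangement of oriented spacer
segments that survives (**Polylox barcode**, *P*) records that moment. A
static 10-nt random **unique clonal identifier** (UCI, *u*), fixed at
integration, disambiguates the clones that recombination bias funnels onto
the same arrangement. The pair *(P, u)* is the **timestamp barcode** of a
clone; cells sharing it descend from one founder, so the pattern of sharing
across transcriptome-defined lineages reveals which lineages were still
connected at induction time. The package is written for people building or
analysing such recorders: it provides the recombination model, a
ground-truthed long-read experiment simulator, and the calling/statistics
pipeline, end to end.

## What it computes

* **Recombination model** — cassette states under Cre excision
  (same-orientation loxP pairs, irreversible) and inversion
  (opposite-orientation pairs, involutive); exhaustive enumeration of the
  reachable barcode space (the default 9-segment alternating cassette
  reaches 1,866,890 arrangements, the ~1.8 million-scale space quoted for
  Polylox); biased event sampling with weight
  `w(i,j,kind) = kindWeight * exp(-bias * span)`.
* **Synthetic experiments** — founders with one integrated cassette each
  (MOI < 0.1), a skewed 5,000-member UCI library, day-0 vs day-8 induction
  with pre-induction lineage commitment (e.g. a PGC-like lineage), clonal
  expansion, per-cell read sampling, nanopore-like
  substitution/insertion/deletion noise, truncation, cell-barcode
  cross-contamination, and 700–2,500 bp amplicon purification — with full
  truth tables.
* **Barcode calling** — per-read cell-barcode assignment by edit-distance
  alignment of the flank–barcode–flank construct (both strands), block
  mapping and Polylox assembly, UCI extraction between its M13F /
  WPRE_M13R_HSV flanks; per-cell consensus under three filters per
  component: **> 30 supporting reads**, the top count a statistical
  **outlier** among candidates (Tukey upper fence, dominance-ratio
  fallback), and **full-length** observation (Polylox) / **library
  membership** (UCI).
* **Clonal frequency filter** — under independence of recombination and
  UCI draw, `freq(P, u) = freq(P) * freq(u)`; cells with
  `freq > 0.005` (low-complexity clones) are excluded, with a
  1/1000–1/100 sensitivity sweep.
* **Lineage linkage** — edges between cells with identical timestamps,
  lineage-by-shared-barcode count matrices, pairwise Spearman coupling,
  and observed-to-expected sharing enrichment under a seeded
  label-permutation null with BH-adjusted empirical p-values.

## Worked example

Simulate a noisy 80-cell experiment, call timestamps, filter, and test
lineage coupling:

```r
library(loxstamp)
design <- cassetteDesign()                     # 9 segments, 10 alternating loxP sites
cfg <- simConfig(nFounders = 40, cellsSampled = 80, expansion = 4,
                 readsPerCell = 50, readsDispersion = Inf, seed = 7)
sim  <- simulateExperiment(cfg, design)
calls <- callTimestamps(sim$reads, design, sim$cellWhitelist,
                        uciWhitelist = sim$uciLibrary$uci)
head(calls[, c("cell_id", "polylox", "uci", "n_reads_cell",
               "n_reads_polylox_top", "n_reads_uci_top")], 4)
#>    cell_id        polylox        uci n_reads_cell n_reads_polylox_top n_reads_uci_top
#> 1 cell0001              9 GAATGGTGGT           46                  42              42
#> 2 cell0002 1-4-5-6-7R-8-9 ACCGGGAAAG           46                  44              40
#> 3 cell0003 1-2-5R-6-7-8-9 GTGAACAATA           44                  41              39
#> 4 cell0004    1-2R-7-8-9R ACTCTACTGT           49                  48              45
```

Each row is one cell: its called Polylox arrangement (`9` means a single
forward segment 9 survived; `R` marks inversion), its UCI, and the read
support behind each call — here 40+ of ~46 assigned reads agree despite the
~9 % per-base error model, which is why the > 30-read consensus is solid.

```r
filt <- filterHighFrequency(calls, cutoff = 0.005)
filt$report
#>   cutoff n_callable n_retained fraction_retained
#> 1  0.005         80         80                 1
```

All 80 cells pass: with near-unique UCIs, every product frequency stays
below 5/1000 (the filter bites when a common arrangement meets a reused
UCI).

```r
lineages <- data.frame(cell_id = sim$truth$cells$cell_id,
                       lineage = sim$truth$cells$lineage, confidence = "high")
ann   <- joinLineages(filt$retained, lineages)
edges <- buildLinkageEdges(ann)                # 61 cell pairs share a timestamp
set.seed(7)
enr <- sharingEnrichment(ann, nPerm = 1000)
head(enr[order(enr$p), ], 5)
#>    lineageA lineageB observed expected ratio      p     q
#> 6       MES      MES        0     2.61 0.000 0.0839 0.619
#> 9       MES      PGC        8     4.24 1.885 0.0939 0.619
#> 8        EN      PGC        2     5.61 0.357 0.1239 0.619
#> 2        BP       EN        2     4.55 0.439 0.2977 0.698
#> 10      PGC      PGC        3     1.48 2.033 0.2997 0.698
```

This is a day-0 induction: all lineages drew from one founder pool, so no
lineage pair deviates significantly from its permutation expectation
(smallest q = 0.62) — the sharing pattern is statistically uniform, as it
should be. Rerunning with
`simConfig(..., inductionTime = "day8", uciUnique = TRUE, contaminationRate = 0)`
commits PGC-like founders before induction and yields zero PGC–soma edges
with an observed/expected ratio of 0 (p ≈ 0.002 at 1,000 permutations),
the signature of a lineage already specified when the barcodes were
written.

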