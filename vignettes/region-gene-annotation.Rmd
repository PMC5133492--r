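---
title: "Rule-based annotation of genomic regions with gene areas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based annotation of genomic regions with gene areas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genearea)
```

## The problem

Peak callers and differential-methylation or accessibility pipelines emit
genomic intervals. Downstream interpretation almost always requires two
decisions that are entangled: *which gene* does an interval act on, and
*where on that gene* does it sit? `genearea` makes both decisions
explicit and configurable. It deliberately models only proximal
association — each region goes to its closest gene or genes — and leaves
distal enhancer-style multi-gene assignment (the "regulatory domain"
approach of tools like GREAT) out of scope.

## Area decomposition

Each transcript's neighborhood is decomposed into eight disjoint areas.
The exonic part is structural: the first exon (`1st_EXON`), every later
exon (`GENE_BODY`), and the gaps between consecutive exons (`INTRON`);
together these tile the transcript span exactly, a property the test
suite asserts on randomized transcripts. The intergenic part is
parametric, measured from the transcript's TSS and TTS points along the
strand:

* `TSS`: width `t`, default 200 bp. The window immediately upstream of
  the transcription start point where core-promoter-proximal binding is
  expected.
* `PROMOTER`: width `p`, default 1300 bp, immediately upstream of the TSS
  window (so the two together cover 1.5 kbp by default).
* `UPSTREAM`: the rest of the upstream flank out to the association
  cut-off `q`.
* `TTS`: width `s`, default 0 bp — disabled unless the user is interested
  in termination-site signals.
* `DOWNSTREAM`: the rest of the downstream flank out to `q`.

All widths are in base pairs on 1-based inclusive coordinates. Zero-width
areas are omitted rather than emitted empty.

Two numerical choices deserve a note:

* **Own-span clipping.** Intergenic areas are intersected with the
  complement of the *gene's own* span (the hull of all its isoforms'
  exons) and clipped at coordinate 1. A short isoform of a long gene
  therefore has no downstream area inside its own gene, while a
  neighboring gene's exons never mask anything — two genes may legitimately
  claim overlapping areas, which is exactly how quasi-overlapping genes
  end up co-reported.
* **Raw BED coordinates.** Region length is `end − start + 1` on the
  coordinates as given, with the midpoint at `floor((start+end)/2)`. No
  0/1-based conversion is applied; users converting from half-open BED
  should be aware the interval is treated inclusively.

## Association and distance

A region is matched against every gene on its chromosome. The distance to
a gene is 0 if the region intersects the gene span, otherwise the minimum
over isoforms of the distance from the region midpoint to the TSS or TTS
point. Genes farther than `q` (default 10 kbp, inclusive comparison) or
without any overlapped area are discarded; of the survivors only the
minimum-distance gene(s) are kept, and ties — every overlapped gene has
distance 0 — are all reported. Distances are unsigned; regions matching no
gene produce no rows rather than placeholders.

Every surviving region × transcript × area overlap becomes one exon-level
row carrying `PercRegion` (percent of the region in the area) and
`PercArea` (percent of the area covered). `PercArea` is −1 for introns,
upstream, and downstream: an intron's length is structural but
uninformative for coverage interpretation, and the flank lengths are
artifacts of `q`. The PercArea denominator for the other areas is the
area's realized extent after clipping, so full coverage is always 100.

## The aggregation rules

At transcript level one row must win per region × transcript:

1. areas with unrounded `PercRegion ≥ w` (default 50%): highest
   PercRegion wins;
2. otherwise areas with `PercArea ≥ v` (default 90%; −1 never qualifies):
   highest PercRegion wins;
3. otherwise — a branch the rule system leaves open — the highest
   PercRegion over all rows. This fallback was chosen as the most
   continuous extension of step 2's tie-break: it keeps the selection a
   pure function of the same two percentages.

Exact PercRegion ties at any step fall through to the priority ranking
(default `TSS > 1st_EXON > PROMOTER > TTS > INTRON > GENE_BODY >
UPSTREAM > DOWNSTREAM`). Thresholds compare unrounded percentages;
rounding to the two printed decimals (half away from zero) happens only in
the report writer, so the rules are immune to rounding artifacts.

At gene level the priority ranking arbitrates between a gene's transcript
annotations. Transcripts tying on the best-ranked area are merged into one
row: the transcript ids are comma-joined in input order, the exon index
becomes −1, and the percentages are taken from the tied transcript with
the highest PercRegion — with identical areas the values are usually
identical anyway, and taking the maximum keeps the row representative of
the strongest overlap.

Other conventions worth stating: exon indices are assigned in 5′→3′
transcript order (so exon 1 of a minus-strand gene is its rightmost);
TSS/PROMOTER/UPSTREAM rows report exon 1, TTS/DOWNSTREAM rows the last
exon, and an intron reports the index of the exon that follows it in
transcript order.

## What the generators emulate

`fig2_fixture()` reconstructs, by interval arithmetic, the canonical
worked example: two overlapping antisense genes (one with two isoforms
sharing a first exon) probed by regions on a TSS/first-exon boundary and
an exon/intron boundary, plus a quasi-overlapping gene pair whose TSS and
promoter windows interleave with each other's exons. Its coordinates were
derived by inverting the published overlap percentages under the default
widths; one denominator is ambiguous at two-decimal precision (the
second exon of the antisense gene: 1500 and 1501 bp both print the same
percentage) and is pinned at 1500 bp.

`random_scenario(seed, n_genes, n_regions)` lays seeded genes (1–2
isoforms, 1–5 exons of 80–1200 bp with 50–1500 bp introns, mixed strands)
along a chromosome with a 25% chance each of overlapping or
quasi-overlapping the previous gene, and scatters regions of 50–800 bp
uniformly over the covered span plus flanks. These sizes keep a scenario
in the tens of kilobases so that the per-base oracle stays fast while
still exercising every area type, both strands, gene ties, and empty
matches. What the generator does *not* emulate: realistic peak-width or
signal distributions, chromosome-scale gene density, fragmented
assemblies, or annotation pathologies (trans-spliced or multi-chromosome
genes are rejected by the parser). Passing tests therefore demonstrate
algorithmic correctness, not robustness to malformed real-world GTFs
beyond the documented error contract.

`brute_force_annotate()` is the independent oracle: it labels every base
of a region for every transcript by direct application of the area
definitions, counts labels to obtain overlaps and percentages, and
re-derives distances and the closest-gene filter exhaustively. It shares
no interval arithmetic with the matcher and refuses scenarios over 1 Mb.
The test suite demands exact agreement (including the aggregated levels)
over 50 seeded scenarios; the acceptance script re-measures this
agreement at run time.

## Degenerate inputs and edge behavior

Single-base exons and regions are legal; a transcript with one exon has
no intron or gene-body area. Exons overlapping *within* one transcript
are rejected as malformed, since the intron definition requires disjoint
exons. Chromosome names are compared as exact strings between GTF and
BED — no `chr` normalization — and BED chromosomes absent from the
annotation trigger a warning listing them, rather than silent empty
results. Rule thresholds use `≥`, so `w = 50` accepts an exact 50/50
split.

## Limitations

* Only `exon` GTF features are consulted; UTR/CDS substructure is not
  modeled, so "gene body" means "non-first exon", not "coding region".
* One area annotation per transcript/gene at the aggregated levels; no
  weighting across isoforms.
* Proximal association only; a region's maximum reach is `q` in either
  direction.
* The report is plain tab-separated text; interoperability with
  `GRanges`-based workflows is a matter of `parse_bed()`/`read_report()`
  round-trips, not a native container.

## Problem sizes used in the checks

The bundled checks run at desk scale by design: the worked example has 4
genes, 5 transcripts, and 3 regions; property tests and the acceptance
script use 50 seeded scenarios of 5 genes × 5 regions (≈250 region-level
oracle comparisons), which completes in seconds while covering all eight
areas, both strands, and the tie-handling paths. The matcher itself
streams regions independently, so full-genome annotations are limited by
memory for the parsed gene models, not by the region count.
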