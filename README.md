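# genearea

Functional-genomics assays — ChIP-seq peak calling, DNase-/ATAC-seq open
chromatin detection, methylation window analysis — produce genomic regions
that only become interpretable once they are tied to nearby genes. The
biological reading of a region depends strongly on *where* it sits relative
to a gene: a transcription-factor peak on a promoter means something very
different from the same peak inside a terminal intron. `genearea` associates
each region with its closest gene (or genes, when genes overlap or
quasi-overlap) and annotates every association with the gene area it
occupies, at a user-chosen aggregation level. It is aimed at analysts
integrating chromatin signals with gene-level data (expression, annotation
enrichment) in any organism with a GTF annotation.

## The model

For every transcript, the neighborhood is decomposed into eight disjoint
areas. With TSS and TTS the 5′- and 3′-most transcribed bases, and widths
*t* (TSS area, default 200 bp), *p* (promoter, default 1300 bp), *s* (TTS
area, default 0 bp), and a maximum association distance *q* (default
10 kbp):

| area       | definition                                                        |
|------------|-------------------------------------------------------------------|
| TSS        | intergenic window of width *t* immediately upstream of the TSS    |
| PROMOTER   | intergenic window of width *p* immediately upstream of the TSS area |
| UPSTREAM   | remaining intergenic flank, up to *q* from the TSS point          |
| 1st_EXON   | the whole first exon                                              |
| INTRON     | each gap between consecutive exons                                |
| GENE_BODY  | every exon after the first                                        |
| TTS        | intergenic window of width *s* immediately downstream of the TTS  |
| DOWNSTREAM | remaining intergenic flank, up to *q* from the TTS point          |

Intergenic areas are intersected with the complement of the gene's own span,
so an isoform's flank never reaches into its own gene. A region is
associated with the gene(s) minimizing the distance from the region midpoint
to the nearest transcript TSS/TTS point (0 for any gene the region
overlaps); ties are all reported. Every association carries **PercRegion**
(percent of the region inside the area) and **PercArea** (percent of the
area covered by the region; −1 for the areas without a fixed informative
length: intron, upstream, downstream).

At the *exon* level all overlapped areas are reported. At the *transcript*
level one area is chosen per region × transcript: an area with
PercRegion ≥ *w* (default 50%) wins; otherwise an area with PercArea ≥ *v*
(default 90%); among qualifying areas the highest PercRegion wins, with
exact ties broken by a configurable priority ranking (default TSS,
1st_EXON, PROMOTER, TTS, INTRON, GENE_BODY, UPSTREAM, DOWNSTREAM). At the
*gene* level the same ranking arbitrates between the transcripts of a gene;
tied transcripts are comma-joined in one row with exon index −1.

## Worked example

The packaged fixture reproduces the canonical two-chromosome scenario
(overlapping genes with isoforms; quasi-overlapping genes):

```r
library(genearea)
fx <- fig2_fixture()
assoc <- annotate_regions(parse_gtf(text = fx$gtf), parse_bed(text = fx$bed))
write_report(assoc)
```

```
Region	Midpoint	Gene	Transcript	Exon	Area	Distance	PercRegion	PercArea
1_3400_3700	3550	Gene1	Tr1_Gene1	1	TSS	0	66.45	100.00
1_3400_3700	3550	Gene1	Tr1_Gene1	1	1st_EXON	0	33.55	5.94
1_3400_3700	3550	Gene1	Tr2_Gene1	1	TSS	0	66.45	100.00
1_3400_3700	3550	Gene1	Tr2_Gene1	1	1st_EXON	0	33.55	5.94
1_3400_3700	3550	Gene2	Tr1_Gene2	2	INTRON	0	66.45	-1
1_3400_3700	3550	Gene2	Tr1_Gene2	2	GENE_BODY	0	33.55	6.73
1_5900_6250	6075	Gene1	Tr2_Gene1	2	INTRON	0	56.98	-1
1_5900_6250	6075	Gene1	Tr2_Gene1	2	GENE_BODY	0	43.02	37.66
1_5900_6250	6075	Gene2	Tr1_Gene2	1	1st_EXON	0	100.00	29.23
2_2102_2702	2402	Gene3	Tr1_Gene3	1	TSS	0	33.28	100.00
2_2102_2702	2402	Gene3	Tr1_Gene3	1	1st_EXON	0	11.65	100.00
2_2102_2702	2402	Gene3	Tr1_Gene3	1	PROMOTER	0	33.61	15.54
2_2102_2702	2402	Gene3	Tr1_Gene3	2	INTRON	0	21.46	-1
2_2102_2702	2402	Gene4	Tr1_Gene4	1	TSS	0	33.28	100.00
2_2102_2702	2402	Gene4	Tr1_Gene4	1	1st_EXON	0	18.30	80.88
2_2102_2702	2402	Gene4	Tr1_Gene4	1	PROMOTER	0	48.42	22.38
```

Region `1_3400_3700` straddles the TSS area (66.45% of its 301 bp) and
first exon of both Gene1 isoforms while also crossing an intron/exon
boundary of the overlapping antisense Gene2; all six rows share distance 0
because the region overlaps both genes. At the gene level this collapses to
one TSS row for Gene1 (`Tr1_Gene1,Tr2_Gene1`, exon −1) and one INTRON row
for Gene2. Region `2_2102_2702` is claimed by the quasi-overlapping pair
Gene3/Gene4, both resolving to TSS because that area is fully covered
(PercArea 100) with the highest PercRegion.

The same run is available from the shell:

```sh
Rscript -e 'genearea::run_cli()' --report gene annotation.gtf.gz regions.bed out.tsv
```

(an equivalent `exec/genearea` script is installed with the package).
Options: `--report`, `--distance`, `--tss`, `--tts`, `--promoter`,
`--perc-region`, `--perc-area`, `--rules`, `--gene-tag`,
`--transcript-tag`.

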