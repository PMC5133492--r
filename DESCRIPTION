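Package: genearea
Title: Associate Genomic Regions with Proximal Genes and Gene Areas
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Annotates genomic regions (ChIP-seq peaks, methylated windows,
    accessible-chromatin sites) with their closest gene or genes and with
    the gene area each association overlaps (TSS, promoter, upstream, first
    exon, intron, gene body, TTS, downstream). Associations are reported at
    the exon, transcript, or gene aggregation level under a configurable
    rule system with user-adjustable area widths, distance cut-off, overlap
    thresholds, and area priorities. Reads Ensembl-style GTF annotation and
    BED region files (plain or gzip-compressed) and writes a tab-separated
    report that preserves extra BED columns.
License: MIT
Encoding: UTF-8
Imports: optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
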