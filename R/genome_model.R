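# GTF parsing into strand-aware gene/transcript/exon models.
#
# Only "exon" feature lines are consumed: the whole algorithm is driven by
# exon structure (first exon, introns between consecutive exons, TSS/TTS
# points), so gene/transcript/CDS/UTR lines carry no extra information here.

# Extract one attribute value (key "value" syntax) from GTF attribute strings.
# Returns NA where the tag is absent. Anchored at a field boundary so that a
# tag is never matched inside a longer tag name.
extract_attr <- function(attr, tag) {
  pat <- sprintf('(^|;)[[:space:]]*%s[[:space:]]+"([^"]*)"', tag)
  m <- regexec(pat, attr)
  vapply(regmatches(attr, m),
         function(g) if (length(g) == 3L) g[[3L]] else NA_character_,
         character(1))
}

#' Parse a GTF annotation into gene/transcript/exon models
#'
#' Reads an Ensembl-dialect GTF (1-based, inclusive coordinates; attributes as
#' semicolon-separated `key "value"` pairs) and builds one model per gene.
#' Exon indices are assigned per transcript in 5'-to-3' order: on the `+`
#' strand exon 1 is the leftmost exon, on the `-` strand it is the rightmost.
#' Comment lines (`#`) and non-exon feature lines are ignored. Genes and
#' transcripts are stored sorted by identifier, so parsing is insensitive to
#' the order of exon lines in the file.
#'
#' @param file path to a GTF file, plain or gzip-compressed. Ignored when
#'   `text` is given.
#' @param text optional character vector of GTF lines (mainly for tests).
#' @param gene_tag attribute tag holding the gene identifier to report
#'   (default `"gene_id"`).
#' @param transcript_tag attribute tag holding the transcript identifier
#'   (default `"transcript_id"`).
#' @return an object of class `gene_models`: a list with `genes` (named list
#'   of gene models, each carrying `gene_id`, `chrom`, `strand`, `span`, and a
#'   named list `transcripts`; each transcript carries `exons` — a data frame
#'   with `index`, `start`, `end` in transcript order — plus `tss` and `tts`
#'   point coordinates) and `chrom_index` (gene ids grouped by chromosome).
#' @seealso [transcript_points()], [as_gtf_lines()], [parse_bed()]
#' @examples
#' fx <- fig2_fixture()
#' models <- parse_gtf(text = fx$gtf)
#' names(models$genes)
#' @export
parse_gtf <- function(file = NULL, text = NULL,
                      gene_tag = "gene_id", transcript_tag = "transcript_id") {
  if (is.null(text)) {
    if (is.null(file)) stop("either 'file' or 'text' must be supplied")
    text <- read_input_lines(file)
  }
  lineno <- seq_along(text)
  keep <- !grepl("^#", text) & nzchar(trimws(text))
  text <- text[keep]
  lineno <- lineno[keep]
  if (length(text) == 0) stop("GTF input contains no feature lines")

  fields <- strsplit(text, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    bad <- which(nf < 9)[1]
    stop(sprintf("GTF line %d: expected 9 tab-separated fields, found %d",
                 lineno[bad], nf[bad]))
  }

  feat <- vapply(fields, function(f) f[[3L]], character(1))
  is_exon <- feat == "exon"
  if (!any(is_exon)) stop("GTF input contains no exon lines")
  fields <- fields[is_exon]
  lineno <- lineno[is_exon]

  chrom <- vapply(fields, function(f) f[[1L]], character(1))
  start <- suppressWarnings(as.integer(vapply(fields, function(f) f[[4L]], character(1))))
  end <- suppressWarnings(as.integer(vapply(fields, function(f) f[[5L]], character(1))))
  strand <- vapply(fields, function(f) f[[7L]], character(1))
  # attribute column; tolerate stray tabs beyond field 9
  attr <- vapply(fields, function(f) paste(f[9:length(f)], collapse = "\t"), character(1))

  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("GTF line %d: non-integer start/end coordinate", lineno[bad]))
  }
  if (any(start > end)) {
    bad <- which(start > end)[1]
    stop(sprintf("GTF line %d: start greater than end", lineno[bad]))
  }
  ok_strand <- strand %in% c("+", "-")
  if (!all(ok_strand)) {
    bad <- which(!ok_strand)[1]
    stop(sprintf("GTF line %d: unknown strand symbol '%s'", lineno[bad], strand[bad]))
  }

  gid <- extract_attr(attr, gene_tag)
  tid <- extract_attr(attr, transcript_tag)
  if (anyNA(gid)) {
    bad <- which(is.na(gid))[1]
    stop(sprintf("GTF line %d: attribute tag '%s' not found", lineno[bad], gene_tag))
  }
  if (anyNA(tid)) {
    bad <- which(is.na(tid))[1]
    stop(sprintf("GTF line %d: attribute tag '%s' not found", lineno[bad], transcript_tag))
  }

  transcripts <- lapply(split(seq_along(tid), tid), function(rows) {
    t_id <- tid[rows][1]
    g <- unique(gid[rows])
    if (length(g) != 1)
      stop(sprintf("transcript '%s' is assigned to multiple genes (%s)",
                   t_id, paste(g, collapse = ", ")))
    ch <- unique(chrom[rows])
    if (length(ch) != 1)
      stop(sprintf("transcript '%s' spans multiple chromosomes", t_id))
    st <- unique(strand[rows])
    if (length(st) != 1)
      stop(sprintf("transcript '%s' mixes strands", t_id))
    o <- order(start[rows])
    s <- start[rows][o]
    e <- end[rows][o]
    n <- length(s)
    if (n > 1 && any(s[-1] <= e[-n]))
      stop(sprintf("transcript '%s' has overlapping exons", t_id))
    # transcript (5'->3') order: genomic order on +, reversed on -
    if (st == "-") {
      s <- rev(s)
      e <- rev(e)
    }
    exons <- data.frame(index = seq_len(n), start = s, end = e)
    list(
      transcript_id = t_id, gene_id = g, chrom = ch, strand = st,
      exons = exons,
      tss = if (st == "+") s[1] else e[1],
      tts = if (st == "+") e[n] else s[n]
    )
  })

  tx_gene <- vapply(transcripts, function(tx) tx$gene_id, character(1))
  genes <- lapply(split(transcripts, tx_gene), function(txs) {
    ch <- unique(vapply(txs, function(tx) tx$chrom, character(1)))
    g_id <- txs[[1]]$gene_id
    if (length(ch) != 1)
      stop(sprintf("gene '%s' spans multiple chromosomes", g_id))
    txs <- txs[order(vapply(txs, function(tx) tx$transcript_id, character(1)))]
    names(txs) <- vapply(txs, function(tx) tx$transcript_id, character(1))
    lo <- min(vapply(txs, function(tx) min(tx$exons$start), integer(1)))
    hi <- max(vapply(txs, function(tx) max(tx$exons$end), integer(1)))
    list(gene_id = g_id, chrom = ch, strand = txs[[1]]$strand,
         span = c(lo, hi), transcripts = txs)
  })
  genes <- genes[order(names(genes))]

  gene_chrom <- vapply(genes, function(g) g$chrom, character(1))
  structure(
    list(genes = genes, chrom_index = split(names(genes), gene_chrom)),
    class = "gene_models"
  )
}

#' @export
print.gene_models <- function(x, ...) {
  n_tx <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat(sprintf("<gene_models> %d genes, %d transcripts on %d chromosome(s)\n",
              length(x$genes), n_tx, length(x$chrom_index)))
  invisible(x)
}

#' TSS and TTS points of a transcript
#'
#' The TSS point is the 5'-most transcribed base of the transcript (minimum
#' exon start on `+`, maximum exon end on `-`); the TTS point is the 3'-most
#' transcribed base.
#'
#' @param transcript a transcript model as stored in a [parse_gtf()] result.
#' @return named integer vector `c(tss = , tts = )`.
#' @export
transcript_points <- function(transcript) {
  c(tss = transcript$tss, tts = transcript$tts)
}

#' Serialize gene models back to GTF exon lines
#'
#' Writes one `exon` feature line per exon, in genomic order per transcript.
#' Re-parsing the result with [parse_gtf()] reproduces the input models
#' exactly (a property the test suite relies on).
#'
#' @param models a `gene_models` object.
#' @param source value for the GTF source column.
#' @return character vector of GTF lines.
#' @export
as_gtf_lines <- function(models, source = "genearea") {
  out <- character(0)
  for (g in models$genes) {
    for (tx in g$transcripts) {
      ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
      out <- c(out, sprintf(
        '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
        g$chrom, source, ex$start, ex$end, tx$strand,
        g$gene_id, tx$transcript_id))
    }
  }
  out
}
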