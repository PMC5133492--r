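# Decomposition of a transcript's neighborhood into the eight gene areas.

#' Area labels
#'
#' The eight disjoint gene areas used for annotation.
#'
#' @return character vector of the eight labels.
#' @export
area_labels <- function() AREA_SET

#' Matching configuration
#'
#' Bundles every tunable parameter of the matcher. Defaults follow the
#' standard parameterization: a 200 bp TSS window and a 1300 bp promoter
#' immediately upstream of the transcription start point, no TTS window,
#' a 10 kbp maximum association distance, a 50% PercRegion and a 90%
#' PercArea rule threshold, and the priority ranking TSS, 1st_EXON,
#' PROMOTER, TTS, INTRON, GENE_BODY, UPSTREAM, DOWNSTREAM.
#'
#' @param t TSS area width in bp (intergenic window adjacent to the TSS
#'   point).
#' @param p promoter width in bp (intergenic window immediately upstream of
#'   the TSS area).
#' @param s TTS area width in bp (intergenic window adjacent to the TTS
#'   point); 0 disables the area.
#' @param q maximum distance in bp for associating a region with a gene;
#'   must exceed both `t + p` and `s`.
#' @param w PercRegion rule threshold, percent.
#' @param v PercArea rule threshold, percent.
#' @param priorities permutation of the eight area labels, highest priority
#'   first, used to break ties.
#' @param report_level `"exon"` (all overlapped areas), `"transcript"`
#'   (one area per region and transcript), or `"gene"` (one area per region
#'   and gene).
#' @param gene_tag,transcript_tag GTF attribute tags naming the identifiers
#'   to report.
#' @return an object of class `match_config`.
#' @examples
#' match_config()
#' match_config(t = 1000, p = 0, q = 1e6, report_level = "gene")
#' @export
match_config <- function(t = 200, p = 1300, s = 0, q = 10000, w = 50, v = 90,
                         priorities = DEFAULT_PRIORITIES,
                         report_level = c("exon", "transcript", "gene"),
                         gene_tag = "gene_id",
                         transcript_tag = "transcript_id") {
  report_level <- match.arg(report_level)
  if (t < 0 || p < 0 || s < 0) stop("area widths t, p, s must be non-negative")
  if (q <= t + p) stop("maximum distance q must exceed t + p")
  if (q <= s) stop("maximum distance q must exceed s")
  if (w < 0 || w > 100 || v < 0 || v > 100)
    stop("thresholds w and v must lie in [0, 100]")
  if (length(priorities) != 8 || !setequal(priorities, AREA_SET) ||
      anyDuplicated(priorities))
    stop("priorities must be a permutation of the eight area labels")
  structure(
    list(t = as.integer(t), p = as.integer(p), s = as.integer(s),
         q = as.integer(q), w = w, v = v,
         priorities = as.character(priorities),
         report_level = report_level,
         gene_tag = gene_tag, transcript_tag = transcript_tag),
    class = "match_config"
  )
}

#' @export
print.match_config <- function(x, ...) {
  cat(sprintf(
    "<match_config> t=%d p=%d s=%d q=%d w=%g v=%g level=%s\n  priorities: %s\n",
    x$t, x$p, x$s, x$q, x$w, x$v, x$report_level,
    paste(x$priorities, collapse = " > ")))
  invisible(x)
}

# Intersect an intergenic candidate interval with the complement of the
# gene's own span, clipping at coordinate 1. Flank areas sit entirely on one
# side of the transcript, and the gene span always reaches the TSS/TTS
# point, so at most one piece survives; the general two-piece form is kept
# for robustness.
clip_intergenic <- function(s, e, span) {
  s <- max(1L, s)
  if (s > e) return(list())
  pieces <- list()
  left_end <- min(e, span[1] - 1L)
  if (s <= left_end) pieces[[length(pieces) + 1L]] <- c(s, left_end)
  right_start <- max(s, span[2] + 1L)
  if (right_start <= e) pieces[[length(pieces) + 1L]] <- c(right_start, e)
  pieces
}

#' Compute the gene areas of one transcript
#'
#' Decomposes a transcript's neighborhood into the eight disjoint areas:
#' the first exon (1st_EXON), every later exon (GENE_BODY), the gaps
#' between consecutive exons (INTRON), and — on the appropriate strand
#' side — the intergenic TSS window of width `t`, the promoter of width `p`
#' upstream of it, the remaining UPSTREAM flank out to distance `q` from
#' the TSS point, the TTS window of width `s`, and the DOWNSTREAM flank
#' out to `q` from the TTS point. Zero-width areas are omitted. Each
#' intergenic area is intersected with the complement of the gene's own
#' span (other genes never mask areas) and clipped at coordinate 1;
#' empty results are dropped.
#'
#' @param transcript transcript model from [parse_gtf()].
#' @param gene_span integer vector `c(lo, hi)`: the span of the
#'   transcript's gene over all its transcripts.
#' @param config a [match_config()].
#' @return data frame with columns `area`, `start`, `end`, `exon_index`,
#'   and `denom` — the PercArea denominator (the area's extent) for
#'   TSS/PROMOTER/1st_EXON/GENE_BODY/TTS, `NA` for the areas whose
#'   PercArea is reported as -1 (INTRON, UPSTREAM, DOWNSTREAM).
#' @examples
#' fx <- fig2_fixture()
#' models <- parse_gtf(text = fx$gtf)
#' g <- models$genes$Gene1
#' compute_areas(g$transcripts$Tr1_Gene1, g$span, match_config())
#' @export
compute_areas <- function(transcript, gene_span, config = match_config()) {
  rows <- list()
  add <- function(area, s, e, idx, denominated) {
    if (s > e) return(invisible(NULL))
    rows[[length(rows) + 1L]] <<- data.frame(
      area = area, start = as.integer(s), end = as.integer(e),
      exon_index = as.integer(idx),
      denom = if (denominated) as.integer(e - s + 1L) else NA_integer_,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }
  add_flank <- function(area, s, e, idx, denominated) {
    for (piece in clip_intergenic(s, e, gene_span))
      add(area, piece[1], piece[2], idx, denominated)
  }

  ex <- transcript$exons          # transcript (5'->3') order
  n <- nrow(ex)
  plus <- transcript$strand == "+"
  tss <- transcript$tss
  tts <- transcript$tts
  t <- config$t; p <- config$p; s_w <- config$s; q <- config$q

  add("1st_EXON", ex$start[1], ex$end[1], 1L, TRUE)
  if (n > 1) {
    for (i in 2:n) add("GENE_BODY", ex$start[i], ex$end[i], i, TRUE)
    for (i in seq_len(n - 1)) {
      # gap between transcript-order exons i and i+1, in genomic coordinates
      if (plus) add("INTRON", ex$end[i] + 1L, ex$start[i + 1] - 1L, i + 1L, FALSE)
      else add("INTRON", ex$end[i + 1] + 1L, ex$start[i] - 1L, i + 1L, FALSE)
    }
  }

  if (plus) {
    if (t > 0) add_flank("TSS", tss - t, tss - 1L, 1L, TRUE)
    if (p > 0) add_flank("PROMOTER", tss - t - p, tss - t - 1L, 1L, TRUE)
    if (q > t + p) add_flank("UPSTREAM", tss - q, tss - t - p - 1L, 1L, FALSE)
    if (s_w > 0) add_flank("TTS", tts + 1L, tts + s_w, n, TRUE)
    if (q > s_w) add_flank("DOWNSTREAM", tts + s_w + 1L, tts + q, n, FALSE)
  } else {
    if (t > 0) add_flank("TSS", tss + 1L, tss + t, 1L, TRUE)
    if (p > 0) add_flank("PROMOTER", tss + t + 1L, tss + t + p, 1L, TRUE)
    if (q > t + p) add_flank("UPSTREAM", tss + t + p + 1L, tss + q, 1L, FALSE)
    if (s_w > 0) add_flank("TTS", tts - s_w, tts - 1L, n, TRUE)
    if (q > s_w) add_flank("DOWNSTREAM", tts - q, tts - s_w - 1L, n, FALSE)
  }

  if (length(rows) == 0)
    return(data.frame(area = character(0), start = integer(0), end = integer(0),
                      exon_index = integer(0), denom = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
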