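# Rule-based collapse of exon-level associations to transcript and gene
# level.
#
# Selection flowchart, per (region, transcript):
#   1. areas with PercRegion >= w: pick the one with the highest PercRegion,
#      ties broken by the priority ranking;
#   2. otherwise areas with PercArea >= v (a -1 PercArea never qualifies),
#      same pick;
#   3. otherwise (no area meets either threshold) the area with the highest
#      PercRegion, ties by priorities — the most continuous extension of
#      step 2's tie-break.
# Thresholds are compared with >= on unrounded percentages.

#' Select the annotation area for one region-transcript pair
#'
#' @param rows non-empty exon-level association data frame sharing one
#'   region and one transcript.
#' @param config a [match_config()] providing `w`, `v`, and `priorities`.
#' @return the winning row, unchanged.
#' @export
select_area <- function(rows, config = match_config()) {
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("select_area() requires at least one association row")
  cand <- which(rows$perc_region >= config$w)
  if (length(cand) == 0)
    cand <- which(rows$perc_area >= 0 & rows$perc_area >= config$v)
  if (length(cand) == 0)
    cand <- seq_len(nrow(rows))
  sub <- rows[cand, , drop = FALSE]
  top <- sub[sub$perc_region == max(sub$perc_region), , drop = FALSE]
  if (nrow(top) > 1)
    top <- top[order(match(top$area, config$priorities)), , drop = FALSE]
  out <- top[1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate associations to one row per region and transcript
#'
#' Applies [select_area()] within each (region, gene, transcript) group of
#' an exon-level report.
#'
#' @param exon_rows exon-level associations from [match_regions()].
#' @param config a [match_config()].
#' @return association data frame with exactly one row per (region,
#'   transcript) pair, deterministically ordered.
#' @export
aggregate_transcript_level <- function(exon_rows, config = match_config()) {
  if (nrow(exon_rows) == 0) return(exon_rows)
  key <- paste(exon_rows$region_idx, exon_rows$gene, exon_rows$transcript,
               sep = "\r")
  groups <- split(seq_len(nrow(exon_rows)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(groups, function(i) {
    select_area(exon_rows[i, , drop = FALSE], config)
  }))
  sort_associations(out, config)
}

#' Aggregate associations to one row per region and gene
#'
#' Within each (region, gene) group of a transcript-level report, keeps the
#' transcript rows whose area has the best priority rank. A single
#' surviving transcript is emitted verbatim. When several transcripts tie
#' (necessarily on the same area), one row is emitted whose Transcript
#' field comma-joins the tied transcript ids in input order, whose Exon is
#' -1, and whose percentages come from the tied row with the highest
#' PercRegion.
#'
#' @param transcript_rows output of [aggregate_transcript_level()].
#' @param config a [match_config()].
#' @return association data frame with exactly one row per (region, gene)
#'   pair.
#' @export
aggregate_gene_level <- function(transcript_rows, config = match_config()) {
  if (nrow(transcript_rows) == 0) return(transcript_rows)
  key <- paste(transcript_rows$region_idx, transcript_rows$gene, sep = "\r")
  groups <- split(seq_len(nrow(transcript_rows)),
                  factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(groups, function(i) {
    g <- transcript_rows[i, , drop = FALSE]
    rnk <- match(g$area, config$priorities)
    tied <- g[rnk == min(rnk), , drop = FALSE]
    if (nrow(tied) == 1) {
      rownames(tied) <- NULL
      return(tied)
    }
    pick <- tied[which.max(tied$perc_region), , drop = FALSE]
    pick$transcript <- paste(tied$transcript, collapse = ",")
    pick$exon <- -1L
    rownames(pick) <- NULL
    pick
  }))
  sort_associations(out, config)
}
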