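# Exon-level association of regions with their closest gene(s).

#' Overlap length of two inclusive intervals
#'
#' @param a_start,a_end first interval (1-based, inclusive).
#' @param b_start,b_end second interval.
#' @return number of shared bases; 0 when disjoint. Vectorized.
#' @export
overlap_length <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmin(a_end, b_end) - pmax(a_start, b_start) + 1L)
}

#' Percentage of a region overlapping an area
#'
#' @param overlap shared bases between region and area.
#' @param region_length full region length in bases.
#' @return unrounded percentage; rounding to two decimals happens only at
#'   output time.
#' @export
perc_region <- function(overlap, region_length) {
  100 * overlap / region_length
}

#' Percentage of an area overlapped by a region
#'
#' @param overlap shared bases between region and area.
#' @param denom the area's denominator length, or `NA` for areas without a
#'   fixed informative length (INTRON, UPSTREAM, DOWNSTREAM).
#' @return unrounded percentage, or -1 when the denominator is undefined.
#' @export
perc_area <- function(overlap, denom) {
  ifelse(is.na(denom), -1, 100 * overlap / denom)
}

#' Distance from a region to a gene
#'
#' Zero when the region intersects the gene span; otherwise the minimum,
#' over the gene's transcripts, of the distance from the region midpoint to
#' the transcript's TSS or TTS point. Distances are unsigned.
#'
#' @param region a single region (list or one-row data frame with `start`,
#'   `end`, `midpoint`).
#' @param gene a gene model from [parse_gtf()].
#' @return non-negative integer distance in bases.
#' @export
region_gene_distance <- function(region, gene) {
  if (overlap_length(region$start, region$end, gene$span[1], gene$span[2]) > 0)
    return(0L)
  mid <- region$midpoint
  d <- min(vapply(gene$transcripts, function(tx) {
    min(abs(mid - tx$tss), abs(mid - tx$tts))
  }, numeric(1)))
  as.integer(d)
}

# Association rows of one region against one transcript's area table.
# Pieces of a split flank area are pooled per (area, exon index): overlaps
# are summed and the denominator is the total extent over all pieces.
transcript_assoc_rows <- function(region, gene, tx, areas, distance, config,
                                  region_idx, extras) {
  ov <- overlap_length(areas$start, areas$end, region$start, region$end)
  key <- paste(areas$area, areas$exon_index, sep = "\r")
  ov_tot <- tapply(ov, key, sum)
  hit <- names(ov_tot)[ov_tot > 0]
  if (length(hit) == 0) return(NULL)
  denom_tot <- tapply(areas$denom, key, function(d) {
    if (all(is.na(d))) NA_integer_ else sum(d, na.rm = TRUE)
  })
  split_key <- strsplit(hit, "\r", fixed = TRUE)
  data.frame(
    region_idx = region_idx,
    region_id = region$region_id,
    midpoint = region$midpoint,
    gene = gene$gene_id,
    transcript = tx$transcript_id,
    exon = as.integer(vapply(split_key, `[[`, character(1), 2L)),
    area = vapply(split_key, `[[`, character(1), 1L),
    distance = as.integer(distance),
    perc_region = perc_region(as.numeric(ov_tot[hit]), region$length),
    perc_area = perc_area(as.numeric(ov_tot[hit]), as.numeric(denom_tot[hit])),
    extras = I(rep(list(extras), length(hit))),
    stringsAsFactors = FALSE
  )
}

#' Match one region against the annotation
#'
#' Finds the candidate genes on the region's chromosome that lie within the
#' maximum distance `q` and have at least one area overlapping the region,
#' keeps only the gene(s) at the minimum distance (ties are all kept — every
#' gene a region overlaps has distance 0 and is co-reported), and emits one
#' exon-level association per overlapped area of every transcript of every
#' surviving gene.
#'
#' @param region a single region: one-row data frame (or list) as produced
#'   by [parse_bed()].
#' @param genes a `gene_models` object from [parse_gtf()].
#' @param config a [match_config()].
#' @param region_idx input position of the region, used for deterministic
#'   output ordering.
#' @return exon-level association data frame (zero rows when no gene
#'   qualifies) with columns `region_idx`, `region_id`, `midpoint`, `gene`,
#'   `transcript`, `exon`, `area`, `distance`, `perc_region`, `perc_area`,
#'   `extras`. Percentages are unrounded.
#' @seealso [match_regions()], [aggregate_transcript_level()]
#' @export
match_region <- function(region, genes, config = match_config(),
                         region_idx = 1L) {
  if (is.data.frame(region)) {
    extras <- if (!is.null(region$extras)) region$extras[[1]] else character(0)
    region <- as.list(region[1, setdiff(names(region), "extras")])
  } else {
    extras <- if (!is.null(region$extras)) unlist(region$extras) else character(0)
  }
  gids <- genes$chrom_index[[region$chrom]]
  if (is.null(gids) || length(gids) == 0) return(empty_associations())

  cand <- list()
  for (gid in gids) {
    g <- genes$genes[[gid]]
    d <- region_gene_distance(region, g)
    if (d > config$q) next
    rows <- lapply(g$transcripts, function(tx) {
      transcript_assoc_rows(region, g, tx,
                            compute_areas(tx, g$span, config),
                            d, config, region_idx, extras)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0) next
    cand[[gid]] <- list(distance = d, rows = do.call(rbind, rows))
  }
  if (length(cand) == 0) return(empty_associations())

  dmin <- min(vapply(cand, function(x) x$distance, numeric(1)))
  keep <- Filter(function(x) x$distance == dmin, cand)
  out <- do.call(rbind, lapply(keep, function(x) x$rows))
  sort_associations(out, config)
}

#' Match every region against the annotation
#'
#' Applies [match_region()] to each region in input order and binds the
#' exon-level results. A warning lists BED chromosomes absent from the GTF
#' (chromosome names are compared as exact strings; no normalization).
#'
#' @param regions region data frame from [parse_bed()].
#' @param genes a `gene_models` object from [parse_gtf()].
#' @param config a [match_config()].
#' @return exon-level association data frame, deterministically ordered by
#'   region input order, gene, transcript, exon index, and area priority.
#' @export
match_regions <- function(regions, genes, config = match_config()) {
  missing_chrom <- setdiff(unique(regions$chrom), names(genes$chrom_index))
  if (length(missing_chrom) > 0)
    warning(sprintf("BED chromosomes absent from the GTF annotation: %s",
                    paste(missing_chrom, collapse = ", ")))
  parts <- lapply(seq_len(nrow(regions)), function(i) {
    match_region(regions[i, , drop = FALSE], genes, config, region_idx = i)
  })
  out <- do.call(rbind, parts)
  if (is.null(out) || nrow(out) == 0) return(empty_associations())
  sort_associations(out, config)
}

#' Run the full annotation pipeline
#'
#' Parses the annotation and the regions (when given as paths), computes
#' exon-level associations, and aggregates them to the report level set in
#' the configuration.
#'
#' @param gtf path to a GTF file (plain or gzip) or a parsed `gene_models`
#'   object.
#' @param bed path to a BED file (plain or gzip) or a parsed region data
#'   frame.
#' @param config a [match_config()]; `config$report_level` selects the
#'   aggregation level.
#' @return association data frame at the requested level.
#' @examples
#' fx <- fig2_fixture()
#' annotate_regions(parse_gtf(text = fx$gtf), parse_bed(text = fx$bed),
#'                  match_config(report_level = "gene"))
#' @export
annotate_regions <- function(gtf, bed, config = match_config()) {
  genes <- if (inherits(gtf, "gene_models")) gtf
           else parse_gtf(file = gtf, gene_tag = config$gene_tag,
                          transcript_tag = config$transcript_tag)
  regions <- if (is.data.frame(bed)) bed else parse_bed(file = bed)
  ex <- match_regions(regions, genes, config)
  switch(config$report_level,
         exon = ex,
         transcript = aggregate_transcript_level(ex, config),
         gene = aggregate_gene_level(
           aggregate_transcript_level(ex, config), config))
}
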