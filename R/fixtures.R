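# Deterministic fixtures and the per-base brute-force oracle.
#
# fig2_fixture() reconstructs the two-chromosome worked example (two
# overlapping genes with isoforms; two quasi-overlapping genes) whose exact
# coordinates were derived by inverting the published overlap percentages
# under the default area widths. random_scenario() produces seeded gene
# models and regions for property testing, and brute_force_annotate() is a
# deliberately naive per-base re-derivation of the whole exon-level
# computation, used as an independent oracle.

#' The worked-example annotation and region set
#'
#' Emits a small GTF/BED pair covering the two canonical multi-gene
#' situations: chromosome 1 carries Gene1 (+, two isoforms) overlapped by
#' Gene2 (-, two exons), chromosome 2 carries the quasi-overlapping pair
#' Gene3 (+) and Gene4 (-). Three regions probe a TSS/first-exon boundary,
#' an exon/intron boundary inside overlapping genes, and a region covered
#' by the flank areas of both quasi-overlapping genes.
#'
#' @return list with character vectors `gtf` and `bed`.
#' @examples
#' fx <- fig2_fixture()
#' annotate_regions(parse_gtf(text = fx$gtf), parse_bed(text = fx$bed))
#' @export
fig2_fixture <- function() {
  ex <- function(chrom, start, end, strand, gene, tx) {
    sprintf('%s\tfixture\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            chrom, start, end, strand, gene, tx)
  }
  gtf <- c(
    ex("1", 3600L, 5299L, "+", "Gene1", "Tr1_Gene1"),
    ex("1", 3600L, 5299L, "+", "Gene1", "Tr2_Gene1"),
    ex("1", 6100L, 6500L, "+", "Gene1", "Tr2_Gene1"),
    ex("1", 5500L, 6700L, "-", "Gene2", "Tr1_Gene2"),
    ex("1", 2001L, 3500L, "-", "Gene2", "Tr1_Gene2"),
    ex("2", 2504L, 2573L, "+", "Gene3", "Tr1_Gene3"),
    ex("2", 3200L, 3600L, "+", "Gene3", "Tr1_Gene3"),
    ex("2", 2076L, 2211L, "-", "Gene4", "Tr1_Gene4")
  )
  bed <- c("1\t3400\t3700", "1\t5900\t6250", "2\t2102\t2702")
  list(gtf = gtf, bed = bed)
}

# Run a block of code with a locally seeded RNG, restoring global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Generate a reproducible random test scenario
#'
#' Builds seeded gene models (1-2 transcripts each, 1-5 exons per
#' transcript, mixed strands) laid out along one chromosome so that some
#' neighboring genes overlap, some quasi-overlap (flank areas within reach
#' of a shared region), and some are isolated, plus regions placed
#' uniformly over the covered span. The same seed always yields the same
#' text.
#'
#' @param seed integer RNG seed.
#' @param n_genes number of genes (>= 1).
#' @param n_regions number of regions (>= 1).
#' @return list with character vectors `gtf` and `bed`.
#' @export
random_scenario <- function(seed, n_genes = 6, n_regions = 8) {
  stopifnot(n_genes >= 1, n_regions >= 1)
  with_seed(seed, {
    ex_line <- function(start, end, strand, gene, tx) {
      sprintf('chr1\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
              start, end, strand, gene, tx)
    }
    gtf <- character(0)
    prev_start <- NA_integer_
    prev_end <- 0L
    max_end <- 0L
    for (g in seq_len(n_genes)) {
      placement <- if (g == 1) "free"
                   else sample(c("overlap", "quasi", "free"), 1,
                               prob = c(0.25, 0.25, 0.5))
      gstart <- switch(placement,
        overlap = prev_start + sample(0:800, 1),
        quasi   = prev_end + sample(100:1600, 1),
        free    = prev_end + sample(2500:6000, 1))
      gstart <- max(1L, as.integer(gstart))
      strand <- sample(c("+", "-"), 1)
      gene_id <- sprintf("Gene%02d", g)
      gene_end <- gstart
      for (k in seq_len(sample(1:2, 1))) {
        n_ex <- sample(1:5, 1)
        s <- gstart + sample(0:300, 1)
        tx_id <- sprintf("Tr%d_%s", k, gene_id)
        for (j in seq_len(n_ex)) {
          e <- s + sample(80:1200, 1) - 1L
          gtf <- c(gtf, ex_line(as.integer(s), as.integer(e), strand,
                                gene_id, tx_id))
          gene_end <- max(gene_end, as.integer(e))
          s <- e + sample(50:1500, 1) + 1L
        }
      }
      prev_start <- gstart
      prev_end <- gene_end
      max_end <- max(max_end, gene_end)
    }
    rstart <- sample.int(max_end + 8000L, n_regions, replace = TRUE)
    rwidth <- sample(50:800, n_regions, replace = TRUE)
    bed <- sprintf("chr1\t%d\t%d", rstart, rstart + rwidth - 1L)
    list(gtf = gtf, bed = bed)
  })
}

# Label a vector of positions with the area (and exon index) they carry for
# one transcript, by direct application of the area definitions — written
# independently of compute_areas()'s interval arithmetic. Positions inside
# the gene span but outside the transcript's exons/introns carry no label.
oracle_base_labels <- function(pos, tx, span, config) {
  n_pos <- length(pos)
  lab <- rep(NA_character_, n_pos)
  idx <- rep(NA_integer_, n_pos)
  ex <- tx$exons
  nex <- nrow(ex)
  for (i in seq_len(nex)) {
    inside <- pos >= ex$start[i] & pos <= ex$end[i]
    lab[inside] <- if (i == 1L) "1st_EXON" else "GENE_BODY"
    idx[inside] <- i
  }
  if (nex > 1) {
    for (i in seq_len(nex - 1L)) {
      if (tx$strand == "+") {
        glo <- ex$end[i] + 1L; ghi <- ex$start[i + 1] - 1L
      } else {
        glo <- ex$end[i + 1] + 1L; ghi <- ex$start[i] - 1L
      }
      ing <- is.na(lab) & pos >= glo & pos <= ghi
      lab[ing] <- "INTRON"
      idx[ing] <- i + 1L
    }
  }
  outside <- pos < span[1] | pos > span[2]
  up_d <- if (tx$strand == "+") tx$tss - pos else pos - tx$tss
  free <- is.na(lab) & outside
  m <- free & up_d >= 1 & up_d <= config$t
  lab[m] <- "TSS"; idx[m] <- 1L
  m <- free & up_d > config$t & up_d <= config$t + config$p
  lab[m] <- "PROMOTER"; idx[m] <- 1L
  m <- free & up_d > config$t + config$p & up_d <= config$q
  lab[m] <- "UPSTREAM"; idx[m] <- 1L
  down_d <- if (tx$strand == "+") pos - tx$tts else tx$tts - pos
  free <- is.na(lab) & outside
  m <- free & down_d >= 1 & down_d <= config$s
  lab[m] <- "TTS"; idx[m] <- nex
  m <- free & down_d > config$s & down_d <= config$q
  lab[m] <- "DOWNSTREAM"; idx[m] <- nex
  list(lab = lab, idx = idx)
}

#' Brute-force per-base annotation oracle
#'
#' Recomputes the exon-level associations of one region by scanning every
#' base: each base of the region is labeled per transcript by direct
#' application of the area definitions, overlaps and percentages are
#' derived by counting labels (PercArea denominators by counting the label
#' over the whole neighborhood), distances by direct arithmetic on exon
#' coordinates, and the closest-gene filter by exhaustive evaluation. It is
#' intentionally naive and refuses large scenarios; its only job is to be
#' an independent check on [match_region()].
#'
#' @param region one region (one-row data frame from [parse_bed()] or an
#'   equivalent list).
#' @param genes a `gene_models` object.
#' @param config a [match_config()].
#' @param region_idx input position of the region (for ordering).
#' @return exon-level association data frame, ordered like
#'   [match_region()] output (without the `extras` column).
#' @export
brute_force_annotate <- function(region, genes, config = match_config(),
                                 region_idx = 1L) {
  if (is.data.frame(region)) region <- as.list(region[1, ])
  gids <- genes$chrom_index[[region$chrom]]
  if (is.null(gids) || length(gids) == 0) return(empty_associations())

  span_lo <- min(vapply(gids, function(g) genes$genes[[g]]$span[1], integer(1)))
  span_hi <- max(vapply(gids, function(g) genes$genes[[g]]$span[2], integer(1)))
  if ((span_hi + config$q) - max(1, span_lo - config$q) > 1e6)
    stop("brute-force oracle refuses scenarios spanning more than 1e6 bases")

  pos <- region$start:region$end
  region_len <- length(pos)

  cand <- list()
  for (gid in gids) {
    g <- genes$genes[[gid]]
    # distance, recomputed from raw exon coordinates
    if (region$end >= g$span[1] && region$start <= g$span[2]) {
      d <- 0L
    } else {
      d <- min(vapply(g$transcripts, function(tx) {
        es <- tx$exons$start; ee <- tx$exons$end
        tssx <- if (tx$strand == "+") min(es) else max(ee)
        ttsx <- if (tx$strand == "+") max(ee) else min(es)
        min(abs(region$midpoint - tssx), abs(region$midpoint - ttsx))
      }, numeric(1)))
    }
    if (d > config$q) next
    rows <- list()
    for (tx in g$transcripts) {
      rl <- oracle_base_labels(pos, tx, g$span, config)
      hitkey <- paste(rl$lab, rl$idx, sep = "\r")[!is.na(rl$lab)]
      if (length(hitkey) == 0) next
      counts <- table(hitkey)
      scan <- max(1L, g$span[1] - config$q):(g$span[2] + config$q)
      sl <- oracle_base_labels(scan, tx, g$span, config)
      scankey <- paste(sl$lab, sl$idx, sep = "\r")[!is.na(sl$lab)]
      sizes <- table(scankey)
      kk <- strsplit(names(counts), "\r", fixed = TRUE)
      area <- vapply(kk, `[[`, character(1), 1L)
      pa <- ifelse(area %in% UNDENOMINATED_AREAS, -1,
                   100 * as.numeric(counts) / as.numeric(sizes[names(counts)]))
      rows[[length(rows) + 1L]] <- data.frame(
        region_idx = region_idx,
        region_id = region$region_id,
        midpoint = region$midpoint,
        gene = g$gene_id,
        transcript = tx$transcript_id,
        exon = as.integer(vapply(kk, `[[`, character(1), 2L)),
        area = area,
        distance = as.integer(d),
        perc_region = 100 * as.numeric(counts) / region_len,
        perc_area = pa,
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0) next
    cand[[gid]] <- list(distance = d, rows = do.call(rbind, rows))
  }
  if (length(cand) == 0) return(empty_associations())
  dmin <- min(vapply(cand, function(x) x$distance, numeric(1)))
  keep <- Filter(function(x) x$distance == dmin, cand)
  out <- do.call(rbind, lapply(keep, function(x) x$rows))
  sort_associations(out, config)
}
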