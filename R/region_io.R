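# Region (BED) input and tabular report output.
#
# BED coordinates are used exactly as given: region length is
# end - start + 1 and no 0/1-based conversion is applied. This inclusive
# interpretation is what makes the published worked-example percentages
# (e.g. 66.45 = 200/301 for a 3400-3700 region) reproducible.

#' Parse a BED region file
#'
#' Reads a BED file with at least 3 tab-separated columns (chrom, start,
#' end). Columns beyond the third are carried verbatim into the output
#' report. `track`, `browser`, and `#` comment lines are skipped. Input
#' order is preserved.
#'
#' @param file path to a BED file, plain or gzip-compressed. Ignored when
#'   `text` is given.
#' @param text optional character vector of BED lines.
#' @return a data frame with one row per region: `chrom`, `start`, `end`,
#'   `region_id` (`chrom_start_end`), `midpoint` (floor of the coordinate
#'   mean), `length` (`end - start + 1`), and a list column `extras` holding
#'   any additional BED columns.
#' @seealso [parse_gtf()], [annotate_regions()]
#' @examples
#' parse_bed(text = c("1\t3400\t3700", "2\t2102\t2702\tpeakA\t87"))
#' @export
parse_bed <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("either 'file' or 'text' must be supplied")
    text <- read_input_lines(file)
  }
  lineno <- seq_along(text)
  skip <- grepl("^(#|track([[:space:]]|$)|browser([[:space:]]|$))", text) |
    !nzchar(trimws(text))
  text <- text[!skip]
  lineno <- lineno[!skip]

  parts <- strsplit(text, "\t", fixed = TRUE)
  # tolerate whitespace-delimited 3-column lines
  parts <- lapply(parts, function(p) {
    if (length(p) == 1L) strsplit(trimws(p), "[[:space:]]+")[[1]] else p
  })
  np <- lengths(parts)
  if (any(np < 3)) {
    bad <- which(np < 3)[1]
    stop(sprintf("BED line %d: expected at least 3 columns, found %d",
                 lineno[bad], np[bad]))
  }

  chrom <- vapply(parts, function(p) p[[1L]], character(1))
  start <- suppressWarnings(as.integer(vapply(parts, function(p) p[[2L]], character(1))))
  end <- suppressWarnings(as.integer(vapply(parts, function(p) p[[3L]], character(1))))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("BED line %d: non-integer start/end coordinate", lineno[bad]))
  }
  if (any(end < start)) {
    bad <- which(end < start)[1]
    stop(sprintf("BED line %d: end is smaller than start", lineno[bad]))
  }

  extras <- lapply(parts, function(p) {
    if (length(p) > 3L) as.character(p[-(1:3)]) else character(0)
  })
  data.frame(
    chrom = chrom, start = start, end = end,
    region_id = paste(chrom, start, end, sep = "_"),
    midpoint = as.integer((start + end) %/% 2L),
    length = end - start + 1L,
    extras = I(extras),
    stringsAsFactors = FALSE
  )
}

REPORT_HEADER <- c("Region", "Midpoint", "Gene", "Transcript", "Exon",
                   "Area", "Distance", "PercRegion", "PercArea")

fmt_perc <- function(x) {
  ifelse(x == -1, "-1", sprintf("%.2f", round_half_up(x, 2)))
}

#' Write the tab-separated association report
#'
#' Emits a header line with the nine fixed columns (Region, Midpoint, Gene,
#' Transcript, Exon, Area, Distance, PercRegion, PercArea) followed by one
#' line per association. Percentages are printed with exactly two decimals
#' (rounded half away from zero); an undefined PercArea is printed as `-1`.
#' Extra BED columns, if any, are appended after PercArea in input order.
#'
#' @param associations association data frame as produced by
#'   [match_regions()], [aggregate_transcript_level()], or
#'   [aggregate_gene_level()].
#' @param file output path or connection; `""` writes to stdout.
#' @return invisibly, the lines written.
#' @seealso [read_report()]
#' @export
write_report <- function(associations, file = "") {
  a <- associations
  extras <- if (!is.null(a$extras)) a$extras else rep(list(character(0)), nrow(a))
  body <- vapply(seq_len(nrow(a)), function(i) {
    paste(c(a$region_id[i], a$midpoint[i], a$gene[i], a$transcript[i],
            a$exon[i], a$area[i], a$distance[i],
            fmt_perc(a$perc_region[i]), fmt_perc(a$perc_area[i]),
            extras[[i]]),
          collapse = "\t")
  }, character(1))
  lines <- c(paste(REPORT_HEADER, collapse = "\t"), body)
  if (identical(file, "")) writeLines(lines) else writeLines(lines, file)
  invisible(lines)
}

#' Read an association report back into a data frame
#'
#' Inverse of [write_report()] up to numeric formatting: percentages come
#' back as the 2-decimal values that were printed.
#'
#' @param file path to a report written by [write_report()].
#' @return data frame with the report columns plus an `extras` list column.
#' @export
read_report <- function(file) {
  lines <- read_input_lines(file)
  if (length(lines) == 0 || !identical(strsplit(lines[1], "\t")[[1]], REPORT_HEADER))
    stop("not an association report: header line missing or malformed")
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  data.frame(
    region_id = vapply(parts, `[[`, character(1), 1L),
    midpoint = as.integer(vapply(parts, `[[`, character(1), 2L)),
    gene = vapply(parts, `[[`, character(1), 3L),
    transcript = vapply(parts, `[[`, character(1), 4L),
    exon = as.integer(vapply(parts, `[[`, character(1), 5L)),
    area = vapply(parts, `[[`, character(1), 6L),
    distance = as.integer(vapply(parts, `[[`, character(1), 7L)),
    perc_region = as.numeric(vapply(parts, `[[`, character(1), 8L)),
    perc_area = as.numeric(vapply(parts, `[[`, character(1), 9L)),
    extras = I(lapply(parts, function(p) {
      if (length(p) > 9L) as.character(p[-(1:9)]) else character(0)
    })),
    stringsAsFactors = FALSE
  )
}
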