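# Shared internal helpers and constants.

# The eight gene areas. AREA_SET fixes the label spelling used everywhere;
# DEFAULT_PRIORITIES is the default tie-break ranking (highest first).
AREA_SET <- c("TSS", "PROMOTER", "UPSTREAM", "1st_EXON",
              "INTRON", "GENE_BODY", "TTS", "DOWNSTREAM")
DEFAULT_PRIORITIES <- c("TSS", "1st_EXON", "PROMOTER", "TTS",
                        "INTRON", "GENE_BODY", "UPSTREAM", "DOWNSTREAM")

# Areas with no fixed genomic length: PercArea is reported as -1 for these.
UNDENOMINATED_AREAS <- c("INTRON", "UPSTREAM", "DOWNSTREAM")

#' Round half away from zero
#'
#' Percentages in the report are rounded half-away-from-zero (so 0.005 -> 0.01),
#' unlike [base::round()]'s round-half-to-even. Rule thresholds are always
#' compared on unrounded values; this is used at output time only.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  mult <- 10^digits
  sign(x) * floor(abs(x) * mult + 0.5) / mult
}

# Read all lines from a text file; gzfile() transparently handles both plain
# and gzip-compressed input.
read_input_lines <- function(file) {
  con <- gzfile(file, open = "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# Zero-row association table with the canonical column set.
empty_associations <- function() {
  data.frame(
    region_idx = integer(0), region_id = character(0), midpoint = integer(0),
    gene = character(0), transcript = character(0), exon = integer(0),
    area = character(0), distance = integer(0),
    perc_region = numeric(0), perc_area = numeric(0),
    extras = I(list()), stringsAsFactors = FALSE
  )
}

# Canonical, fully deterministic row order: region input order, then gene,
# transcript, exon index, and finally the configured area priority rank.
sort_associations <- function(assoc, config) {
  if (nrow(assoc) == 0) return(assoc)
  o <- order(assoc$region_idx, assoc$gene, assoc$transcript, assoc$exon,
             match(assoc$area, config$priorities))
  out <- assoc[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
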