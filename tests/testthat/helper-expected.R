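# Frozen expectations for the worked-example fixture, plus a small
# independently written rule selector used to cross-check the aggregation
# engine.

# The 16 exon-level association rows of the worked example (percentages as
# printed, 2 decimals). Intron rows carry NA in `exon`: the two published
# intron rows disagree on intron numbering, so the intron exon index is
# not asserted.
table1_expected <- function() {
  rows <- list(
    c("1_3400_3700", 3550, "Gene2", "Tr1_Gene2", NA, "INTRON",    0,  66.45, -1),
    c("1_3400_3700", 3550, "Gene2", "Tr1_Gene2",  2, "GENE_BODY", 0,  33.55, 6.73),
    c("1_3400_3700", 3550, "Gene1", "Tr1_Gene1",  1, "TSS",       0,  66.45, 100),
    c("1_3400_3700", 3550, "Gene1", "Tr1_Gene1",  1, "1st_EXON",  0,  33.55, 5.94),
    c("1_3400_3700", 3550, "Gene1", "Tr2_Gene1",  1, "TSS",       0,  66.45, 100),
    c("1_3400_3700", 3550, "Gene1", "Tr2_Gene1",  1, "1st_EXON",  0,  33.55, 5.94),
    c("1_5900_6250", 6075, "Gene2", "Tr1_Gene2",  1, "1st_EXON",  0, 100.00, 29.23),
    c("1_5900_6250", 6075, "Gene1", "Tr2_Gene1", NA, "INTRON",    0,  56.98, -1),
    c("1_5900_6250", 6075, "Gene1", "Tr2_Gene1",  2, "GENE_BODY", 0,  43.02, 37.66),
    c("2_2102_2702", 2402, "Gene4", "Tr1_Gene4",  1, "TSS",       0,  33.28, 100),
    c("2_2102_2702", 2402, "Gene4", "Tr1_Gene4",  1, "PROMOTER",  0,  48.42, 22.38),
    c("2_2102_2702", 2402, "Gene4", "Tr1_Gene4",  1, "1st_EXON",  0,  18.30, 80.88),
    c("2_2102_2702", 2402, "Gene3", "Tr1_Gene3",  1, "TSS",       0,  33.28, 100),
    c("2_2102_2702", 2402, "Gene3", "Tr1_Gene3",  1, "PROMOTER",  0,  33.61, 15.54),
    c("2_2102_2702", 2402, "Gene3", "Tr1_Gene3",  1, "1st_EXON",  0,  11.65, 100),
    c("2_2102_2702", 2402, "Gene3", "Tr1_Gene3", NA, "INTRON",    0,  21.46, -1)
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("region_id", "midpoint", "gene", "transcript", "exon",
                 "area", "distance", "perc_region", "perc_area")
  for (col in c("midpoint", "exon", "distance")) df[[col]] <- as.integer(df[[col]])
  for (col in c("perc_region", "perc_area")) df[[col]] <- as.numeric(df[[col]])
  df
}

# Round an association table to printed precision and put it in a
# comparison-stable order, blanking the intron exon index.
comparable <- function(assoc) {
  out <- data.frame(
    region_id = assoc$region_id,
    midpoint = as.integer(assoc$midpoint),
    gene = assoc$gene,
    transcript = assoc$transcript,
    exon = ifelse(assoc$area == "INTRON", NA_integer_, as.integer(assoc$exon)),
    area = assoc$area,
    distance = as.integer(assoc$distance),
    perc_region = round_half_up2(assoc$perc_region),
    perc_area = ifelse(assoc$perc_area == -1, -1,
                       round_half_up2(assoc$perc_area)),
    stringsAsFactors = FALSE)
  out <- out[order(out$region_id, out$gene, out$transcript, out$area,
                   out$perc_region), ]
  rownames(out) <- NULL
  out
}

round_half_up2 <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

fixture_models <- function() parse_gtf(text = fig2_fixture()$gtf)
fixture_regions <- function() parse_bed(text = fig2_fixture()$bed)

# Independent re-statement of the selection flowchart, used to cross-check
# select_area(): sorts all rows by (meets-w, meets-v, PercRegion, priority)
# instead of filtering stepwise.
oracle_select <- function(rows, config) {
  meets_w <- rows$perc_region >= config$w
  meets_v <- rows$perc_area >= 0 & rows$perc_area >= config$v
  o <- order(-meets_w, -(meets_v & !any(meets_w)), -rows$perc_region,
             match(rows$area, config$priorities))
  rows[o[1], , drop = FALSE]
}
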