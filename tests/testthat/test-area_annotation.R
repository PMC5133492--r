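# Transcript-area decomposition: the eight disjoint areas, configurable
# widths, own-gene-span clipping.

area_df <- function(tx, span, config = match_config()) {
  a <- compute_areas(tx, span, config)
  a[order(a$area, a$start), c("area", "start", "end", "exon_index")]
}

expect_area_set <- function(got, expected) {
  expected <- expected[order(expected$area, expected$start), ]
  rownames(got) <- rownames(expected) <- NULL
  expect_identical(got, expected)
}

test_that("a plus-strand single-exon transcript yields the canonical areas", {
  m <- fixture_models()
  got <- area_df(m$genes$Gene1$transcripts$Tr1_Gene1, m$genes$Gene1$span)
  expect_area_set(got, data.frame(
    area = c("TSS", "PROMOTER", "UPSTREAM", "1st_EXON", "DOWNSTREAM"),
    start = c(3400L, 2100L, 1L, 3600L, 6501L),
    end = c(3599L, 3399L, 2099L, 5299L, 15299L),
    exon_index = c(1L, 1L, 1L, 1L, 1L)))
})

test_that("a minus-strand transcript mirrors the flank areas", {
  m <- fixture_models()
  got <- area_df(m$genes$Gene4$transcripts$Tr1_Gene4, m$genes$Gene4$span)
  expect_area_set(got, data.frame(
    area = c("1st_EXON", "TSS", "PROMOTER", "UPSTREAM", "DOWNSTREAM"),
    start = c(2076L, 2212L, 2412L, 3712L, 1L),
    end = c(2211L, 2411L, 3711L, 12211L, 2075L),
    exon_index = c(1L, 1L, 1L, 1L, 1L)))
})

test_that("intergenic areas are clipped by the gene's own span only", {
  m <- fixture_models()
  # Tr1_Gene1 ends at 5299 but Gene1's span runs to 6500 through Tr2:
  # its downstream flank must start after the whole gene span
  a <- compute_areas(m$genes$Gene1$transcripts$Tr1_Gene1, m$genes$Gene1$span)
  down <- a[a$area == "DOWNSTREAM", ]
  expect_identical(c(down$start, down$end), c(6501L, 15299L))
  # Gene3's promoter/TSS overlap Gene4's exon yet are never masked by it
  a3 <- compute_areas(m$genes$Gene3$transcripts$Tr1_Gene3, m$genes$Gene3$span)
  expect_equal(a3[a3$area == "TSS", c("start", "end")],
               data.frame(start = 2304L, end = 2503L), ignore_attr = TRUE)
  expect_equal(a3[a3$area == "PROMOTER", c("start", "end")],
               data.frame(start = 1004L, end = 2303L), ignore_attr = TRUE)
})

test_that("zero-width areas are omitted", {
  m <- parse_gtf(text = c(
    'c\ts\texon\t5000\t5999\t.\t+\t.\tgene_id "G"; transcript_id "T";',
    'c\ts\texon\t7000\t7999\t.\t+\t.\tgene_id "G"; transcript_id "T";'))
  cfg <- match_config(t = 0, p = 0, s = 0)
  a <- compute_areas(m$genes$G$transcripts$T, m$genes$G$span, cfg)
  expect_setequal(unique(a$area),
                  c("1st_EXON", "GENE_BODY", "INTRON", "UPSTREAM", "DOWNSTREAM"))
  # default s = 0 also drops the TTS area
  a_def <- compute_areas(m$genes$G$transcripts$T, m$genes$G$span)
  expect_false("TTS" %in% a_def$area)
  # with s > 0 the TTS area appears adjacent to the TTS point
  a_tts <- compute_areas(m$genes$G$transcripts$T, m$genes$G$span,
                         match_config(s = 500))
  expect_equal(a_tts[a_tts$area == "TTS", c("start", "end")],
               data.frame(start = 8000L, end = 8499L), ignore_attr = TRUE)
})

random_tx <- function(seed) {
  # transcripts far from the origin so that the coordinate-1 clip is inert
  with_seed_local(seed, {
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(1:5, 1)
    s <- 100000L + sample.int(5000L, 1)
    lines <- character(0)
    for (j in seq_len(n_ex)) {
      e <- s + sample(80:900, 1) - 1L
      lines <- c(lines, sprintf(
        'c\ts\texon\t%d\t%d\t.\t%s\t.\tgene_id "G"; transcript_id "T";',
        s, e, strand))
      s <- e + sample(50:900, 1) + 1L
    }
    lines
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

test_that("areas are pairwise disjoint and exons+introns tile the transcript", {
  for (seed in 1:25) {
    m <- parse_gtf(text = random_tx(seed))
    tx <- m$genes$G$transcripts$T
    a <- compute_areas(tx, m$genes$G$span)
    covered <- unlist(Map(seq.int, a$start, a$end))
    expect_identical(anyDuplicated(covered), 0L)
    body <- a[a$area %in% c("1st_EXON", "GENE_BODY", "INTRON"), ]
    tiled <- sort(unlist(Map(seq.int, body$start, body$end)))
    expect_identical(tiled, seq.int(min(tx$exons$start), max(tx$exons$end)))
  }
})

test_that("flank areas span exactly q bases on each side of the transcript", {
  cfg <- match_config(s = 300)
  for (seed in 26:40) {
    m <- parse_gtf(text = random_tx(seed))
    tx <- m$genes$G$transcripts$T
    a <- compute_areas(tx, m$genes$G$span, cfg)  # single-tx gene: no masking
    up <- a[a$area %in% c("TSS", "PROMOTER", "UPSTREAM"), ]
    down <- a[a$area %in% c("TTS", "DOWNSTREAM"), ]
    expect_identical(sum(up$end - up$start + 1L), cfg$q)
    expect_identical(sum(down$end - down$start + 1L), cfg$q)
  }
})

test_that("reflecting coordinates and flipping strand mirrors the areas", {
  reflect <- function(x, c0 = 400000L) c0 - x
  for (seed in 41:55) {
    lines <- random_tx(seed)
    m <- parse_gtf(text = lines)
    tx <- m$genes$G$transcripts$T
    a <- compute_areas(tx, m$genes$G$span)
    # rebuild the same transcript reflected through c0, on the other strand
    f <- strsplit(lines, "\t")
    refl <- vapply(f, function(p) {
      s <- reflect(as.integer(p[5])); e <- reflect(as.integer(p[4]))
      p[4] <- s; p[5] <- e; p[7] <- if (p[7] == "+") "-" else "+"
      paste(p, collapse = "\t")
    }, character(1))
    m2 <- parse_gtf(text = refl)
    a2 <- compute_areas(m2$genes$G$transcripts$T, m2$genes$G$span)
    key <- function(d) {
      d <- d[order(d$area, d$start), ]
      paste(d$area, d$exon_index, d$start, d$end)
    }
    a_refl <- data.frame(area = a$area, exon_index = a$exon_index,
                         start = reflect(a$end), end = reflect(a$start))
    expect_setequal(key(a_refl), key(a2))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(match_config(t = -1), "non-negative")
  expect_error(match_config(q = 1000), "exceed t \\+ p")
  expect_error(match_config(s = 20000), "exceed s")
  expect_error(match_config(w = 150), "\\[0, 100\\]")
  expect_error(match_config(priorities = c("TSS", "TSS")), "permutation")
})
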