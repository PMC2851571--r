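test_that("index queries report all exact hits on both strands", {
  idx <- build_index(c(chr1 = "ACGTACGT"))
  aln <- map_reads("ACGT", idx)
  # ACGT is its own reverse complement: forward 0 and 4, minus-strand 0
  # and 4
  expect_equal(nrow(aln), 4)
  expect_equal(sort(aln$start[aln$strand == "+"]), c(0, 4))
  expect_equal(sort(aln$start[aln$strand == "-"]), c(0, 4))
  expect_equal(unique(aln$n_hits), 4L)
  oracle <- oracle_map_read("ACGT", c(chr1 = "ACGTACGT"))
  expect_equal(
    strip_aln(dplyr::arrange(aln[, c("chrom", "start", "end", "strand")],
                             start, strand)),
    as.data.frame(dplyr::arrange(
      oracle[, c("chrom", "start", "end", "strand")], start, strand
    ))
  )
})

test_that("bad queries are rejected or unmapped as appropriate", {
  idx <- build_index(c(chr1 = "ACGTACGT"))
  expect_error(map_reads("ACNT", idx), "outside")
  long <- map_reads("ACGTACGTA", idx)
  expect_equal(nrow(long), 0)
  expect_equal(unmapped_reads(long), "ACGTACGTA")
  expect_error(build_index(character()), "empty")
})

test_that("mapping agrees with the brute-force two-strand oracle on random reads", {
  w <- cached_world("micro", micro_config())
  idx <- cached_index("micro", w)
  reads <- random_reads(w, n = 200, seed = 3)
  aln <- map_reads(reads, idx)
  for (s in reads) {
    got <- strip_aln(dplyr::arrange(
      aln[aln$seq == s, c("chrom", "start", "end", "strand")],
      chrom, start, strand
    ))
    want <- as.data.frame(dplyr::arrange(
      oracle_map_read(s, w$genome)[, c("chrom", "start", "end", "strand")],
      chrom, start, strand
    ))
    expect_equal(got, want, ignore_attr = TRUE)
  }
  # every reported alignment verifies by substring comparison
  g <- unname(w$genome[1])
  for (k in sample(nrow(aln), min(50, nrow(aln)))) {
    a <- aln[k, ]
    sub <- substr(g, a$start + 1, a$end)
    expect_equal(if (a$strand == "-") reverse_complement(sub) else sub,
                 a$seq)
  }
})

test_that("category priority resolves overlaps as specified", {
  # hand-built annotations: a hairpin overlapping a repeat, one gene
  genes <- tibble::tibble(
    gene_id = "gA", chrom = "c", strand = "+", span_start = 100L,
    span_end = 300L, exons = list(tibble::tibble(start = c(100L, 220L),
                                                 end = c(180L, 300L))),
    utr3_start = 280L, utr3_end = 300L, transcript = NA_character_,
    tx_len = 160L, utr3_tx_start = 140L, utr3_tx_end = 160L,
    rde1_dependent = FALSE, role = "sirna_locus"
  )
  annotations <- tibble::tibble(
    chrom = "c",
    start = c(400L, 410L, 600L),
    end = c(480L, 500L, 640L),
    strand = c("+", "+", "+"),
    feature_class = c("mirna_hairpin", "repeat", "tRNA"),
    id = c("hp1", "rep1", "trna1")
  )
  aln <- tibble::tibble(
    seq = c("readA", "readB", "readC", "readD"),
    chrom = "c",
    start = c(120L, 130L, 420L, 800L),
    end = c(142L, 152L, 442L, 822L),
    strand = c("-", "+", "+", "+"),
    n_hits = 1L
  )
  calls <- classify_reads(aln, annotations, genes)
  expect_equal(calls$category[calls$seq == "readA"], "siRNA")
  expect_equal(calls$locus_id[calls$seq == "readA"], "gA")
  expect_equal(calls$category[calls$seq == "readB"], "sense_RNA")
  # hairpin outranks repeat
  expect_equal(calls$category[calls$seq == "readC"], "known_microRNA")
  expect_equal(calls$category[calls$seq == "readD"], "other")
})

test_that("classification matches the interval-overlap oracle on random reads", {
  w <- cached_world("micro", micro_config())
  idx <- cached_index("micro", w)
  reads <- random_reads(w, n = 500, seed = 17)
  aln <- map_reads(reads, idx)
  calls <- classify_reads(aln, w$annotations, w$genes)
  for (s in unique(aln$seq)) {
    want <- oracle_classify_read(aln[aln$seq == s, ], w$annotations,
                                 w$genes)
    expect_equal(calls$category[calls$seq == s], want, label = s)
  }
})

test_that("every mapped read receives exactly one category and the partition is exact", {
  w <- tiny_world()
  lib <- simulate_library(library_spec("N2", depth = 20000, seed = 21), w)
  ann <- annotate_library(lib, w, tiny_index())
  mapped <- ann[ann$mapped, ]
  # one category per distinct sequence (sources may share a sequence)
  expect_equal(nrow(dplyr::distinct(mapped, seq, category)),
               dplyr::n_distinct(mapped$seq))
  comp <- summarize_library(ann)
  expect_equal(sum(comp$reads), sum(mapped$count))
  expect_equal(sum(comp$fraction), 1)
  # unmapped reads are flagged, not silently dropped
  expect_equal(sum(ann$count) - sum(mapped$count),
               sum(ann$count[!ann$mapped]))
})

test_that("composition handles degenerate and simple arithmetic cases", {
  calls <- tibble::tibble(seq = c("a", "b"), count = c(3L, 7L),
                          category = "known_microRNA")
  comp <- summarize_library(calls)
  expect_equal(comp$fraction[comp$category == "known_microRNA"], 1)
  expect_equal(sum(comp$fraction), 1)
  calls2 <- tibble::tibble(
    seq = c("a", "b"), count = c(25L, 75L),
    category = c("siRNA", "known_microRNA")
  )
  comp2 <- summarize_library(calls2)
  expect_equal(comp2$fraction[comp2$category == "siRNA"], 0.25)
  expect_equal(comp2$fraction[comp2$category == "known_microRNA"], 0.75)
  expect_error(summarize_library(tibble::tibble(seq = character(),
                                                category = character())),
               "No classified reads")
})
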