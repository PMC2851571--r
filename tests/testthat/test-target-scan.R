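test_that("reverse complement recovers the mature miRNA from an antisense probe", {
  # northern probe (antisense oligo) -> mature sequence, frozen
  expect_equal(reverse_complement("ATATCCCGCCGCGATCGTACCG"),
               "CGGTACGATCGCGGCGGGATAT")
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("augc"), "GCAT")
  withr::with_seed(2, {
    for (rep in 1:20) {
      x <- paste(sample(c("A", "C", "G", "T"), sample(5:40, 1),
                        replace = TRUE), collapse = "")
      expect_equal(reverse_complement(reverse_complement(x)), x)
      expect_equal(reverse_complement(x), oracle_revcomp(x))
    }
  })
  expect_error(reverse_complement("ACGX"), "outside")
  expect_error(reverse_complement(42), "character")
})

test_that("a perfectly complementary site is found exactly once in a planted UTR", {
  mirna <- c(`mir-x` = "CGGTACGATCGCGGCGGGATAT")
  withr::with_seed(6, {
    flank1 <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                    collapse = "")
    flank2 <- paste(sample(c("A", "C", "G", "T"), 38, replace = TRUE),
                    collapse = "")
  })
  utr <- paste0(flank1, "ATATCCCGCCGCGATCGTACCG", flank2)
  sites <- scan_sites(c(utrA = utr), mirna)
  expect_equal(nrow(sites), 1)
  expect_equal(sites$start, 40)
  expect_equal(sites$end, 62)
  expect_equal(sites$mismatch_count, 0L)
  expect_equal(sites$site_seq, "ATATCCCGCCGCGATCGTACCG")
  # UTRs shorter than the miRNA yield no sites, without error
  expect_equal(nrow(scan_sites(c(short = "ACGTACGT"), mirna)), 0)
  expect_error(scan_sites(c(u = utr), c(m = "ACGT")), "18")
})

test_that("mismatch-tolerant scanning matches the per-window Hamming oracle", {
  withr::with_seed(9, {
    mirna <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
                   collapse = "")
    for (rep in 1:10) {
      utr <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                   collapse = "")
      # plant a 1-mismatch site
      site <- strsplit(oracle_revcomp(mirna), "")[[1]]
      pos <- sample(22, 1)
      site[pos] <- setdiff(c("A", "C", "G", "T"), site[pos])[1]
      utr <- paste0(substr(utr, 1, 60), paste(site, collapse = ""),
                    substr(utr, 83, 150))
      for (mm in 0:2) {
        got <- scan_sites(c(u = utr), c(m = mirna), max_mismatch = mm)
        want <- oracle_scan_sites(utr, mirna, max_mismatch = mm)
        expect_equal(got$start, want$start)
        expect_equal(got$mismatch_count, want$mismatch_count)
        expect_equal(got$site_seq, want$site_seq)
      }
      got1 <- scan_sites(c(u = utr), c(m = mirna), max_mismatch = 2)
      expect_true(1L %in% got1$mismatch_count)
    }
  })
})

test_that("site scanning is invariant to transcript order", {
  w <- tiny_world()
  utrs <- tibble::tibble(
    transcript_id = w$genes$gene_id,
    seq = substr(w$genes$transcript, w$genes$utr3_tx_start + 1,
                 w$genes$utr3_tx_end)
  )
  trig <- w$mirnas[w$mirnas$is_trigger, c("mirna_id", "mature")]
  s1 <- scan_sites(utrs, trig)
  s2 <- scan_sites(utrs[rev(seq_len(nrow(utrs))), ], trig)
  expect_equal(s1, s2)
  # the planted site is the only perfect site in the default toy world
  expect_equal(nrow(s1), 1)
  expect_equal(s1$transcript_id, w$target_gene_id)
  expect_equal(s1$start, w$trigger_site$tx_start - w$genes$utr3_tx_start[
    w$genes$gene_id == w$target_gene_id
  ])
})

test_that("trans-action hits count distinct antisense species per transcript", {
  w <- tiny_world()
  tg <- w$genes[w$genes$gene_id == w$target_gene_id, ]
  reads <- simulate_secondary_sirnas(tg, TRUE, genotype(), w$config,
                                     depth = 300000, seed = 8)
  idx <- tiny_index()
  aln <- map_reads(reads, idx)
  hits_per_seq <- dplyr::distinct(aln, seq, n_hits)
  reads <- dplyr::left_join(reads, hits_per_seq, by = "seq")
  reads$n_hits[is.na(reads$n_hits)] <- 1L # junction species map nowhere
  transcripts <- tibble::tibble(transcript_id = w$genes$gene_id,
                                seq = w$genes$transcript)
  th <- trans_hit_analysis(reads, transcripts)
  target_row <- th[th$transcript_id == w$target_gene_id, ]
  paralog_row <- th[th$transcript_id == w$paralog_gene_id, ]
  # the paralog shares exactly one 22-mer: exactly one (multi-mapping)
  # species hits it, below the decay threshold
  expect_equal(paralog_row$total_hits, 1)
  expect_false(paralog_row$flagged_for_decay)
  expect_true(target_row$flagged_for_decay)
  expect_gt(target_row$unique_hits, 10)
  # unrelated genes receive no hits
  other <- th[!th$transcript_id %in% c(w$target_gene_id,
                                       w$paralog_gene_id), ]
  expect_true(all(other$total_hits == 0))
})

test_that("trans-action hit table equals the Hamming-window oracle on a small fixture", {
  withr::with_seed(14, {
    transcripts <- tibble::tibble(
      transcript_id = sprintf("t%d", 1:5),
      seq = vapply(1:5, function(i) {
        paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
              collapse = "")
      }, character(1))
    )
    # 10 species: 6 antisense to windows of the first two transcripts,
    # 4 random
    sp <- c(
      vapply(c(3, 30, 60), function(s0) {
        oracle_revcomp(substr(transcripts$seq[1], s0 + 1, s0 + 22))
      }, character(1)),
      vapply(c(10, 50, 80), function(s0) {
        oracle_revcomp(substr(transcripts$seq[2], s0 + 1, s0 + 22))
      }, character(1)),
      vapply(1:4, function(i) {
        paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
              collapse = "")
      }, character(1))
    )
    reads <- tibble::tibble(seq = sp, count = 1L)
    th <- trans_hit_analysis(reads, transcripts)
    for (j in 1:5) {
      expect_equal(th$total_hits[th$transcript_id == sprintf("t%d", j)],
                   oracle_trans_hits(sp, transcripts$seq[j]))
    }
    expect_equal(th$flagged_for_decay, th$total_hits >= 2)
  })
})
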