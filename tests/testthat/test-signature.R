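locus_fixture <- function() {
  w <- tiny_world()
  gene <- w$genes[w$genes$gene_id == w$target_gene_id, ]
  list(w = w, gene = gene, tx = gene$transcript)
}

tx_window <- function(tx, s0, len = 22) substr(tx, s0 + 1, s0 + len)

test_that("strand polarity is the count-weighted antisense fraction", {
  fx <- locus_fixture()
  anti <- reverse_complement(vapply(c(10, 60, 110), tx_window,
                                    character(1), tx = fx$tx))
  sense <- vapply(c(200, 250, 300), tx_window, character(1), tx = fx$tx)
  equal <- tibble::tibble(seq = c(anti, sense), count = rep(2L, 6))
  expect_equal(strand_polarity(equal, fx$gene, fx$w$genome), 0.5)
  pure <- tibble::tibble(seq = anti, count = c(1L, 5L, 3L))
  expect_equal(strand_polarity(pure, fx$gene, fx$w$genome), 1.0)
  # 12-read fixture, manual tally: antisense 1+2+3+4 = 10 of 26
  fix <- tibble::tibble(
    seq = c(anti[1], anti[2], anti[3],
            reverse_complement(tx_window(fx$tx, 150)),
            sense, vapply(c(330, 360), tx_window, character(1),
                          tx = fx$tx)),
    count = c(1L, 2L, 3L, 4L, 5L, 4L, 3L, 2L, 2L)
  )
  expect_equal(strand_polarity(fix, fx$gene, fx$w$genome), 10 / 26)
  expect_true(is.na(strand_polarity(fix[0, ], fx$gene, fx$w$genome)))
})

test_that("TAP dependence statistic and flag follow the scaled-count definition", {
  full <- tap_dependence(500, 0)
  expect_equal(full$tap_statistic, log2(501), tolerance = 1e-12)
  expect_true(full$tap_secondary)
  none <- tap_dependence(100, 100)
  expect_equal(none$tap_statistic, 0)
  expect_false(none$tap_secondary)
  empty <- tap_dependence(0, 0)
  expect_true(empty$tap_insufficient)
  expect_true(is.na(empty$tap_statistic))
})

test_that("exon restriction separates exonic, intronic and junction reads", {
  fx <- locus_fixture()
  g <- unname(fx$w$genome[1])
  ex <- fx$gene$exons[[1]]
  # an intronic window (between exon 1 and exon 2 on the genome)
  intron_s0 <- ex$end[1] + 15L
  intron_read <- reverse_complement(substr(g, intron_s0 + 1,
                                           intron_s0 + 22))
  # a junction-spanning antisense read (crosses the first splice site in
  # transcript coordinates)
  lens <- ex$end - ex$start
  b1 <- if (fx$gene$strand == "-") rev(lens)[1] else lens[1]
  junction_read <- reverse_complement(tx_window(fx$tx, b1 - 10))
  expect_equal(nrow(oracle_map_read(junction_read, fx$w$genome)), 0)
  exonic_read <- reverse_complement(tx_window(fx$tx, 30))
  reads <- tibble::tibble(seq = c(exonic_read, junction_read, intron_read),
                          count = c(6L, 2L, 2L))
  er <- exon_restriction(reads, fx$gene, fx$w$genome)
  expect_equal(er$exonic_fraction, 8 / 10)
  expect_equal(er$junction_read_count, 2)
  # a fully exonic read set
  pure <- tibble::tibble(seq = c(exonic_read, junction_read),
                         count = c(1L, 1L))
  expect_equal(exon_restriction(pure, fx$gene, fx$w$genome)$exonic_fraction,
               1.0)
})

test_that("coverage gradient is zero for uniform coverage and antisymmetric under mirroring", {
  flat <- coverage_gradient(rep(3, 200))
  expect_equal(flat$gradient_stat, 0)
  withr::with_seed(4, {
    for (rep in 1:5) {
      cov <- rpois(175, lambda = seq(0.5, 8, length.out = 175))
      if (all(cov == 0)) next
      fwd <- coverage_gradient(cov)
      mir <- coverage_gradient(rev(cov))
      expect_equal(fwd$gradient_stat, -mir$gradient_stat)
    }
  })
  expect_error(coverage_gradient(rep(1, 30)), "two windows")
  zero <- coverage_gradient(rep(0, 200))
  expect_true(is.na(zero$gradient_stat) && is.na(zero$gradient_rho))
})

test_that("a 3'-weighted locus shows a positive gradient by both statistics", {
  fx <- locus_fixture()
  reads <- simulate_secondary_sirnas(fx$gene, TRUE, genotype(),
                                     fx$w$config, depth = 2500000,
                                     seed = 12)
  expect_gt(sum(reads$count), 5000)
  cov <- locus_antisense_coverage(reads, fx$gene, fx$w$genome)
  gr <- coverage_gradient(cov)
  expect_gt(gr$gradient_stat, 0)
  expect_gt(gr$gradient_rho, 0)
})

test_that("the verdict rule combines the four signatures as specified", {
  expect_equal(signature_verdict(500, 1.0, 8.9, 1.0), "secondary-like")
  expect_equal(signature_verdict(500, 0.96, 3.0, 0.95), "secondary-like")
  # mixed-polarity dsRNA-like core: not secondary, and with tap 0 primary
  expect_equal(signature_verdict(500, 0.5, 0, 1.0), "primary-like")
  expect_equal(signature_verdict(500, 0.5, 2, 1.0), "mixed")
  expect_equal(signature_verdict(10, 1.0, 8.9, 1.0), "insufficient_data")
  # purity: same inputs, same verdict
  expect_identical(signature_verdict(200, 0.97, 4, 0.99),
                   signature_verdict(200, 0.97, 4, 0.99))
})

test_that("the planted trigger locus earns a secondary-like report; a miRNA species does not", {
  fx <- locus_fixture()
  reads <- simulate_secondary_sirnas(fx$gene, TRUE, genotype(),
                                     fx$w$config, depth = 100000,
                                     seed = 40)
  sig <- locus_signature(
    reads, fx$gene, fx$w$genome,
    count_tap = sum(reads$count), count_no_tap = 0,
    trigger_tx_start = fx$w$trigger_site$tx_start
  )
  expect_s3_class(sig, "locus_signature")
  expect_equal(sig$antisense_fraction, 1.0)
  expect_equal(sig$exonic_fraction, 1.0)
  expect_gt(sig$tap_statistic, 3)
  expect_gt(sig$gradient_stat, 0)
  expect_equal(sig$verdict, "secondary-like")
  # most reads lie 5' of the 3'UTR trigger site on the transcript
  expect_gt(sig$upstream_fraction, 0.5)
  # a Dicer-made miRNA clones equally well with or without TAP
  expect_false(tap_dependence(120, 118)$tap_secondary)
  # tidy()/glance() expose the statistics
  td <- tidy(sig)
  expect_true(all(c("statistic", "value") %in% names(td)))
  expect_equal(nrow(glance(sig)), 1)
})
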