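test_that("stem mismatch count sets the Argonaute loading split", {
  cfg <- sim_config(w0 = 0.8, w_mm = 0.1)
  d <- mismatch_loading_distribution(c(0L, 2L), cfg)
  expect_equal(d$p_rde1, c(0.8, 0.1))
  expect_equal(d$p_alg, c(0.2, 0.9))
  d5 <- mismatch_loading_distribution(0:5, cfg)
  expect_equal(d5$p_rde1 + d5$p_alg, rep(1, 6))
  expect_error(mismatch_loading_distribution(-1L, cfg), ">= 0")
})

test_that("TAP cloning retains monophosphate reads and gates triphosphate reads", {
  reads <- tibble::tibble(
    seq = c("ACGT", "GGCC", "TTAA"), count = c(5L, 2L, 9L),
    five_prime = c("monoP", "triP", "monoP"), true_source = "x"
  )
  expect_identical(apply_tap(reads, TRUE), reads)
  kept <- apply_tap(reads, FALSE)
  expect_equal(kept$five_prime, c("monoP", "monoP"))
  expect_equal(sum(kept$count), 14L)
  all_mono <- dplyr::filter(reads, five_prime == "monoP")
  expect_identical(apply_tap(all_mono, FALSE), all_mono)
})

test_that("knockouts of the trigger pathway abolish secondary siRNAs", {
  w <- tiny_world()
  gene <- w$genes[w$genes$gene_id == w$target_gene_id, ]
  for (alleles in list("rde-1", "mir-243", c("rde-1", "rrf-1"))) {
    out <- simulate_secondary_sirnas(gene, TRUE, genotype(alleles),
                                     w$config, depth = 50000, seed = 3)
    expect_equal(nrow(out), 0)
  }
  expect_equal(nrow(simulate_secondary_sirnas(gene, FALSE, genotype(),
                                              w$config, depth = 50000,
                                              seed = 3)), 0)
})

test_that("genotype factors scale expected secondary siRNA output", {
  cfg <- tiny_config()
  expect_equal(genotype_factor(genotype(), cfg), 1)
  expect_equal(genotype_factor(genotype("rrf-1"), cfg), 0.05)
  expect_equal(genotype_factor(genotype("MAGO"), cfg), 0.1)
  expect_equal(genotype_factor(genotype("alg-1"), cfg), 1.2)
  expect_equal(genotype_factor(genotype(c("rrf-1", "alg-1")), cfg),
               0.05 * 1.2)
  expect_equal(genotype_factor(genotype("rrf-2"), cfg), 1)
  w <- tiny_world()
  gene <- w$genes[w$genes$gene_id == w$target_gene_id, ]
  # aggregate over seeds: totals are Poisson with mean base_rate*depth*g
  tot <- function(geno) {
    sum(vapply(1:20, function(s) {
      sum(simulate_secondary_sirnas(gene, TRUE, geno, w$config,
                                    depth = 100000, seed = s)$count)
    }, numeric(1)))
  }
  mu_wt <- w$config$sirna_base_rate * 100000 * 20
  n_wt <- tot(genotype())
  expect_lt(abs(n_wt - mu_wt), 4 * sqrt(mu_wt))
  n_rrf1 <- tot(genotype("rrf-1"))
  expect_lt(abs(n_rrf1 - mu_wt * 0.05), 4 * sqrt(mu_wt * 0.05))
})

test_that("secondary siRNAs are antisense, exonic, triphosphate; junction reads match only the spliced transcript", {
  w <- tiny_world()
  gene <- w$genes[w$genes$gene_id == w$target_gene_id, ]
  reads <- simulate_secondary_sirnas(gene, TRUE, genotype(), w$config,
                                     depth = 2500000, seed = 5)
  expect_gt(sum(reads$count), 5000)
  expect_true(all(reads$five_prime == "triP"))
  expect_true(all(nchar(reads$seq) == w$config$read_length))
  # every species' reverse complement is a substring of the transcript
  rc <- reverse_complement(reads$seq)
  expect_true(all(vapply(rc, grepl, logical(1), x = gene$transcript,
                         fixed = TRUE)))
  # none are sense-oriented
  expect_false(any(vapply(reads$seq, grepl, logical(1),
                          x = gene$transcript, fixed = TRUE)))
  # junction species: absent from the genome on both strands
  genome_hits <- vapply(reads$seq, function(s) {
    nrow(oracle_map_read(s, w$genome))
  }, numeric(1))
  junction <- genome_hits == 0
  expect_gt(sum(junction), 0)
  # non-junction species sit fully inside exonic space
  placed <- which(!junction)[1:25]
  ex <- gene$exons[[1]]
  for (i in placed) {
    occ <- oracle_map_read(reads$seq[i], w$genome)
    inside <- any(occ$start >= rep(ex$start, each = nrow(occ)) &
                    occ$end <= rep(ex$end, each = nrow(occ)))
    expect_true(inside)
  }
})

test_that("libraries are deterministic, depth-conserving and design-faithful", {
  w <- tiny_world()
  spec <- library_spec("N2", depth = 10000, seed = 42)
  l1 <- simulate_library(spec, w)
  l2 <- simulate_library(spec, w)
  expect_identical(l1, l2)
  expect_equal(sum(l1$count), 10000)
  expect_error(library_spec("bad", depth = 0), "positive")

  # untreated library: triphosphate reads lost after the depth draw
  no_tap <- simulate_library(
    library_spec("N2-noTAP", tap_treated = FALSE, depth = 10000, seed = 42),
    w
  )
  expect_true(all(no_tap$five_prime == "monoP"))
  expect_lt(sum(no_tap$count), 10000)
})

test_that("ALG-1 IP miRNA purity matches the configured binomial rate", {
  w <- tiny_world()
  lib <- simulate_library(
    library_spec("ALG1", ip_target = "ALG-1", depth = 10000, seed = 9), w
  )
  mir_frac <- sum(lib$count[lib$true_source %in% w$mirnas$mirna_id]) /
    sum(lib$count)
  se <- sqrt(0.95 * 0.05 / 10000)
  expect_lt(abs(mir_frac - 0.95), 3 * se)
})

test_that("the perfect-stem trigger miRNA is enriched in RDE-1 over ALG-1 IPs and 21U-RNAs are excluded", {
  w <- tiny_world()
  freq <- function(ip, seed) {
    lib <- simulate_library(
      library_spec(ip, ip_target = ip, depth = 10000, seed = seed), w
    )
    tibble::tibble(
      trigger = sum(lib$count[lib$true_source == w$trigger_mirna_id]) /
        sum(lib$count),
      p21 = sum(lib$count[startsWith(lib$true_source, "p21u")]) /
        sum(lib$count)
    )
  }
  rde <- freq("RDE-1", 31)
  alg <- freq("ALG-1", 32)
  expect_gt(rde$trigger, alg$trigger)
  expect_equal(rde$p21, 0)
})
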