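# Synthetic toy world: genome, annotations, gene models, miRNA precursors.
#
# The generator plants, by construction:
#   * one coding gene (the "target") whose 3'UTR carries a 22-nt site
#     exactly reverse-complementary to the mature sequence of the one
#     miRNA with a perfectly paired (0-mismatch) precursor stem;
#   * one paralog gene sharing exactly one 22-mer with the target's
#     spliced transcript (for the trans-action analysis);
#   * miRNA hairpins whose mature arms occur nowhere else in the genome
#     (the perfect-stem trigger is the necessary exception: its star arm
#     and its planted target site are exact reverse complements of the
#     mature sequence).

GENE_EXON_LENS <- c(150L, 130L, 160L)
GENE_INTRON_LENS <- c(60L, 60L)
UTR3_LEN <- 90L
HAIRPIN_LEN <- 80L
MATURE_OFFSET <- 10L # 0-based offset of the mature arm within the hairpin
STAR_OFFSET <- 46L   # 0-based offset of the star arm within the hairpin
MIN_GAP <- 40L

feature_class_lengths <- c(
  p21u_locus = 21L, scRNA = 110L, snRNA = 150L, snoRNA = 90L, tRNA = 72L,
  rRNA = 120L, repeat_ = 200L, non_hairpin_region = 150L
)

gene_span_length <- function() sum(GENE_EXON_LENS) + sum(GENE_INTRON_LENS)

# Map a spliced-transcript window [t0, t1) (0-based, window must lie within
# a single exon) to genomic coordinates. Returns list(gstart, gend).
tx_window_to_genome <- function(exons, strand, t0, t1) {
  lens <- exons$end - exons$start
  if (strand == "-") {
    ord <- rev(seq_len(nrow(exons)))
  } else {
    ord <- seq_len(nrow(exons))
  }
  cum <- cumsum(lens[ord])
  before <- c(0L, head(cum, -1))
  k <- which(t0 >= before & t1 <= cum)[1]
  if (is.na(k)) abort("Transcript window spans an exon junction.")
  ex <- exons[ord[k], ]
  o0 <- t0 - before[k]
  o1 <- t1 - before[k]
  if (strand == "+") {
    list(gstart = ex$start + o0, gend = ex$start + o1)
  } else {
    list(gstart = ex$end - o1, gend = ex$end - o0)
  }
}

# Spliced transcript (5'->3' on the gene strand) from the forward genome.
spliced_transcript <- function(genome_seq, exons, strand) {
  parts <- substr0(rep(genome_seq, nrow(exons)), exons$start, exons$end)
  s <- paste(parts, collapse = "")
  if (strand == "-") reverse_complement(s) else s
}

write_segment <- function(genome_seq, start0, seq) {
  substr(genome_seq, start0 + 1L, start0 + nchar(seq)) <- seq
  genome_seq
}

# Introduce m mismatches into a sequence at distinct positions.
mutate_bases <- function(seq, m) {
  if (m == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), m)
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_ALPHABET, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

count_occurrences_both_strands <- function(pattern, genome_seq) {
  subj <- Biostrings::DNAString(genome_seq)
  Biostrings::countPattern(pattern, subj) +
    Biostrings::countPattern(reverse_complement(pattern), subj)
}

#' Build the synthetic toy world
#'
#' Generates a random genome and lays out non-overlapping annotation
#' features: coding genes with exon/intron structure (the siRNA-producing
#' loci, a perfectly matched miRNA target among them, and a paralog
#' sharing exactly one 22-mer with the target), miRNA hairpins with
#' mismatch-annotated precursor stems, 21U-RNA loci, structural RNA genes,
#' repeat families, and annotated non-hairpin regions. All randomness is
#' controlled by `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `toy_world` with elements `genome` (named
#'   character vector), `annotations`, `genes`, `mirnas` (tibbles), `gaps`
#'   (unannotated intervals), the planted landmarks (`target_gene_id`,
#'   `paralog_gene_id`, `trigger_mirna_id`, `trigger_site`,
#'   `shared_kmer`) and the `config` used.
#' @export
build_toy_genome <- function(config = sim_config()) {
  validate_sim_config(config)
  for (attempt in 0:4) {
    world <- withr::with_seed(
      config$seed + attempt,
      build_toy_genome_once(config)
    )
    if (verify_world_plantings(world)) {
      return(world)
    }
  }
  abort("Could not build a toy world without sequence collisions; enlarge the genome.")
}

build_toy_genome_once <- function(config) {
  cfg <- config
  # --- feature blueprint ----------------------------------------------
  bp <- list()
  n_genes <- cfg$n_sirna_loci + as.integer(cfg$n_sirna_loci >= 1L)
  if (n_genes > 0) {
    ids <- c(
      sprintf("gene%03d", seq_len(cfg$n_sirna_loci)),
      if (cfg$n_sirna_loci >= 1L) "paralogA"
    )
    bp[[length(bp) + 1]] <- tibble(
      id = ids, feature_class = "coding_gene",
      length = gene_span_length(),
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    )
  }
  if (cfg$n_mirna > 0) {
    bp[[length(bp) + 1]] <- tibble(
      id = sprintf("hairpin%03d", seq_len(cfg$n_mirna)),
      feature_class = "mirna_hairpin", length = HAIRPIN_LEN,
      strand = sample(c("+", "-"), cfg$n_mirna, replace = TRUE)
    )
  }
  simple_classes <- tibble(
    feature_class = c("p21u_locus", "scRNA", "snRNA", "snoRNA", "tRNA",
                      "rRNA", "non_hairpin_region"),
    n = c(cfg$n_p21u, cfg$n_scrna, cfg$n_snrna, cfg$n_snorna, cfg$n_trna,
          cfg$n_rrna, cfg$n_non_hairpin),
    len = c(feature_class_lengths[["p21u_locus"]],
            feature_class_lengths[["scRNA"]],
            feature_class_lengths[["snRNA"]],
            feature_class_lengths[["snoRNA"]],
            feature_class_lengths[["tRNA"]],
            feature_class_lengths[["rRNA"]],
            feature_class_lengths[["non_hairpin_region"]])
  )
  for (i in seq_len(nrow(simple_classes))) {
    ni <- simple_classes$n[i]
    if (ni > 0) {
      cls <- simple_classes$feature_class[i]
      bp[[length(bp) + 1]] <- tibble(
        id = sprintf("%s%03d", cls, seq_len(ni)), feature_class = cls,
        length = simple_classes$len[i],
        strand = sample(c("+", "-"), ni, replace = TRUE)
      )
    }
  }
  n_rep <- cfg$n_repeat_families * cfg$repeat_copies
  if (n_rep > 0) {
    fam <- rep(seq_len(cfg$n_repeat_families), each = cfg$repeat_copies)
    bp[[length(bp) + 1]] <- tibble(
      id = sprintf("repeat%02d_copy%d", fam,
                   rep(seq_len(cfg$repeat_copies), cfg$n_repeat_families)),
      feature_class = "repeat", length = feature_class_lengths[["repeat_"]],
      strand = sample(c("+", "-"), n_rep, replace = TRUE)
    )
  }
  bp <- if (length(bp)) bind_rows(bp) else
    tibble(id = character(), feature_class = character(),
           length = integer(), strand = character())

  # --- placement -------------------------------------------------------
  n_feat <- nrow(bp)
  spare <- cfg$genome_size - sum(bp$length) - MIN_GAP * (n_feat + 1L)
  if (spare < 0) {
    abort(sprintf(
      "Genome of %d bp is too small for the requested features (need >= %d bp).",
      cfg$genome_size, sum(bp$length) + MIN_GAP * (n_feat + 1L)
    ))
  }
  if (n_feat > 0) {
    bp <- bp[sample(n_feat), ]
    extra <- as.vector(rmultinom(1, spare, rep(1, n_feat + 1L)))
    gaps <- MIN_GAP + extra
    starts <- integer(n_feat)
    pos <- 0L
    for (i in seq_len(n_feat)) {
      pos <- pos + gaps[i]
      starts[i] <- pos
      pos <- pos + bp$length[i]
    }
    bp$start <- starts
    bp$end <- starts + bp$length
  } else {
    bp$start <- integer()
    bp$end <- integer()
  }

  genome_seq <- random_dna(cfg$genome_size)

  # --- gene models -----------------------------------------------------
  gene_rows <- bp[bp$feature_class == "coding_gene", ]
  genes <- tibble(
    gene_id = character(), chrom = character(), strand = character(),
    span_start = integer(), span_end = integer(), exons = list(),
    utr3_start = integer(), utr3_end = integer(), transcript = character(),
    tx_len = integer(), utr3_tx_start = integer(), utr3_tx_end = integer(),
    rde1_dependent = logical(), role = character()
  )
  if (nrow(gene_rows) > 0) {
    exon_off <- cumsum(c(0L, head(GENE_EXON_LENS + c(GENE_INTRON_LENS, 0L), -1)))
    dep_ids <- sprintf("gene%03d", seq_len(cfg$n_rde1_dependent))
    genes <- purrr::pmap_dfr(gene_rows, function(id, feature_class, length,
                                                 strand, start, end) {
      ex_start <- start + exon_off
      exons <- tibble(start = ex_start, end = ex_start + GENE_EXON_LENS)
      tx_len <- sum(GENE_EXON_LENS)
      utr_g <- tx_window_to_genome(exons, strand, tx_len - UTR3_LEN, tx_len)
      tibble(
        gene_id = id, chrom = cfg$chrom_name, strand = strand,
        span_start = start, span_end = end, exons = list(exons),
        utr3_start = utr_g$gstart, utr3_end = utr_g$gend,
        transcript = NA_character_, tx_len = tx_len,
        utr3_tx_start = tx_len - UTR3_LEN, utr3_tx_end = tx_len,
        rde1_dependent = id %in% dep_ids,
        role = dplyr::case_when(
          id == "gene001" ~ "target",
          id == "paralogA" ~ "paralog",
          TRUE ~ "sirna_locus"
        )
      )
    })
  }

  # --- miRNA hairpins --------------------------------------------------
  hp_rows <- bp[bp$feature_class == "mirna_hairpin", ]
  mirnas <- tibble(
    mirna_id = character(), hairpin_id = character(), chrom = character(),
    strand = character(), hp_start = integer(), hp_end = integer(),
    mature = character(), star = character(), stem_mismatch_count = integer(),
    expression = numeric(), is_trigger = logical()
  )
  if (nrow(hp_rows) > 0) {
    n_mi <- nrow(hp_rows)
    mm <- c(0L, sample(1:3, n_mi - 1L, replace = TRUE))[seq_len(n_mi)]
    expression <- sample(2^seq(0, 4, length.out = n_mi))
    mirnas <- purrr::map_dfr(seq_len(n_mi), function(i) {
      row <- hp_rows[i, ]
      mature <- random_dna(cfg$mature_length)
      star <- mutate_bases(reverse_complement(mature), mm[i])
      hp_seq <- random_dna(HAIRPIN_LEN)
      hp_seq <- write_segment(hp_seq, MATURE_OFFSET, mature)
      hp_seq <- write_segment(hp_seq, STAR_OFFSET, star)
      gseq <- if (row$strand == "-") reverse_complement(hp_seq) else hp_seq
      tibble(
        mirna_id = sub("hairpin", "mir-sim-", row$id),
        hairpin_id = row$id, chrom = cfg$chrom_name, strand = row$strand,
        hp_start = row$start, hp_end = row$end, mature = mature,
        star = star, stem_mismatch_count = mm[i],
        expression = expression[i], is_trigger = (i == 1L),
        genome_write = gseq, write_at = row$start
      )
    })
    for (i in seq_len(nrow(mirnas))) {
      genome_seq <- write_segment(genome_seq, mirnas$write_at[i],
                                  mirnas$genome_write[i])
    }
    mirnas$genome_write <- NULL
    mirnas$write_at <- NULL
  }

  # --- repeats: identical copies per family ---------------------------
  rep_rows <- bp[bp$feature_class == "repeat", ]
  if (nrow(rep_rows) > 0) {
    fams <- unique(sub("_copy\\d+$", "", rep_rows$id))
    for (f in fams) {
      fam_seq <- random_dna(feature_class_lengths[["repeat_"]])
      rows <- rep_rows[startsWith(rep_rows$id, paste0(f, "_")), ]
      for (i in seq_len(nrow(rows))) {
        gseq <- if (rows$strand[i] == "-") reverse_complement(fam_seq) else fam_seq
        genome_seq <- write_segment(genome_seq, rows$start[i], gseq)
      }
    }
  }

  # --- 21U loci start with a U (T) on their own strand ----------------
  p21_rows <- bp[bp$feature_class == "p21u_locus", ]
  for (i in seq_len(nrow(p21_rows))) {
    if (p21_rows$strand[i] == "+") {
      genome_seq <- write_segment(genome_seq, p21_rows$start[i], "T")
    } else {
      genome_seq <- write_segment(genome_seq, p21_rows$end[i] - 1L, "A")
    }
  }

  # --- planted trigger site in the target 3'UTR -----------------------
  trigger_site <- NULL
  if (nrow(mirnas) > 0 && any(genes$role == "target")) {
    tg <- genes[genes$role == "target", ]
    mature <- mirnas$mature[mirnas$is_trigger]
    site_seq <- reverse_complement(mature)
    site_t0 <- tg$tx_len - 60L
    site_t1 <- site_t0 + cfg$mature_length
    g <- tx_window_to_genome(tg$exons[[1]], tg$strand, site_t0, site_t1)
    content <- if (tg$strand == "-") reverse_complement(site_seq) else site_seq
    genome_seq <- write_segment(genome_seq, g$gstart, content)
    trigger_site <- tibble(
      gene_id = tg$gene_id, mirna_id = mirnas$mirna_id[mirnas$is_trigger],
      tx_start = site_t0, tx_end = site_t1, site_seq = site_seq,
      gstart = g$gstart, gend = g$gend
    )
  }

  # --- paralog shares exactly one 22-mer with the target --------------
  shared_kmer <- NULL
  if (any(genes$role == "target") && any(genes$role == "paralog")) {
    tg <- genes[genes$role == "target", ]
    pg <- genes[genes$role == "paralog", ]
    tg_tx <- spliced_transcript(genome_seq, tg$exons[[1]], tg$strand)
    k <- cfg$read_length
    shared_t0 <- GENE_EXON_LENS[1] + 50L # middle of exon 2, junction-free
    shared <- substr0(tg_tx, shared_t0, shared_t0 + k)
    par_t0 <- GENE_EXON_LENS[1] + 50L
    g <- tx_window_to_genome(pg$exons[[1]], pg$strand, par_t0, par_t0 + k)
    content <- if (pg$strand == "-") reverse_complement(shared) else shared
    genome_seq <- write_segment(genome_seq, g$gstart, content)
    # Force the paralog's transcript flanks to differ from the target's so
    # the shared stretch is exactly one 22-mer long.
    for (side in c(-1L, 1L)) {
      t_flank <- if (side < 0) shared_t0 - 1L else shared_t0 + k
      p_flank <- if (side < 0) par_t0 - 1L else par_t0 + k
      tchar <- substr0(tg_tx, t_flank, t_flank + 1L)
      newchar <- setdiff(DNA_ALPHABET, tchar)[1]
      gg <- tx_window_to_genome(pg$exons[[1]], pg$strand, p_flank, p_flank + 1L)
      gcontent <- if (pg$strand == "-") reverse_complement(newchar) else newchar
      genome_seq <- write_segment(genome_seq, gg$gstart, gcontent)
    }
    shared_kmer <- list(seq = shared, target_tx_start = shared_t0,
                        paralog_tx_start = par_t0)
  }

  # --- finalize transcripts -------------------------------------------
  if (nrow(genes) > 0) {
    genes$transcript <- vapply(seq_len(nrow(genes)), function(i) {
      spliced_transcript(genome_seq, genes$exons[[i]], genes$strand[i])
    }, character(1))
  }

  annotations <- tibble(
    chrom = rep(cfg$chrom_name, nrow(bp)), start = bp$start, end = bp$end,
    strand = bp$strand, feature_class = bp$feature_class, id = bp$id
  ) |> arrange(.data$start)

  gaps <- if (nrow(annotations) > 0) {
    bounds <- annotations |> arrange(.data$start)
    tibble(
      start = c(0L, bounds$end),
      end = c(bounds$start, cfg$genome_size)
    ) |> filter(.data$end - .data$start >= cfg$read_length + 2L)
  } else {
    tibble(start = 0L, end = cfg$genome_size)
  }

  structure(
    list(
      genome = setNames(genome_seq, cfg$chrom_name),
      annotations = annotations,
      genes = genes,
      mirnas = mirnas,
      gaps = gaps,
      trigger_site = trigger_site,
      shared_kmer = shared_kmer,
      target_gene_id = if (any(genes$role == "target")) "gene001" else NA_character_,
      paralog_gene_id = if (any(genes$role == "paralog")) "paralogA" else NA_character_,
      trigger_mirna_id = if (nrow(mirnas) > 0) mirnas$mirna_id[mirnas$is_trigger] else NA_character_,
      config = cfg
    ),
    class = "toy_world"
  )
}

# Mature miRNA arms must be unique genome-wide (trigger excepted: its star
# arm and planted target site are exact reverse complements); the shared
# paralog 22-mer must occur exactly twice.
verify_world_plantings <- function(world) {
  if (nrow(world$mirnas) == 0) return(TRUE)
  g <- unname(world$genome)
  expected <- ifelse(world$mirnas$is_trigger &
                       !is.null(world$trigger_site), 3L,
                     ifelse(world$mirnas$is_trigger, 2L, 1L))
  hits <- vapply(world$mirnas$mature, function(p) {
    as.numeric(count_occurrences_both_strands(p, g))
  }, numeric(1))
  if (!all(hits == expected)) return(FALSE)
  if (!is.null(world$shared_kmer)) {
    if (count_occurrences_both_strands(world$shared_kmer$seq, g) != 2L) {
      return(FALSE)
    }
  }
  TRUE
}

#' @export
print.toy_world <- function(x, ...) {
  cat("<toy_world>\n")
  cat(sprintf("  genome: %s, %d bp\n", names(x$genome),
              nchar(x$genome[[1]])))
  cat(sprintf("  %d annotated features; %d gene models; %d miRNA hairpins\n",
              nrow(x$annotations), nrow(x$genes), nrow(x$mirnas)))
  if (!is.na(x$target_gene_id)) {
    cat(sprintf("  planted trigger: %s site in 3'UTR of %s; paralog %s\n",
                x$trigger_mirna_id, x$target_gene_id, x$paralog_gene_id))
  }
  invisible(x)
}
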