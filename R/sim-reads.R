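# Simulated small RNA reads: Argonaute loading, RdRP secondary siRNA
# production, TAP-dependent cloning, and whole-library generation.

#' Argonaute loading probabilities from precursor stem structure
#'
#' Precursors with perfectly paired stems preferentially load the
#' scavenger Argonaute (RDE-1); precursors with 1-3 stem mismatches are
#' recognized as miRNAs and load ALG-1/ALG-2.
#'
#' @param precursors A tibble with a `stem_mismatch_count` column (e.g.
#'   `world$mirnas`), or a bare integer vector of mismatch counts.
#' @param config A [sim_config()] supplying the loading weights `w0`
#'   (P(RDE-1) at 0 mismatches) and `w_mm` (P(RDE-1) at >= 1 mismatch).
#' @return The input tibble with columns `p_rde1` and `p_alg` added
#'   (summing to 1 per precursor).
#' @export
mismatch_loading_distribution <- function(precursors, config = sim_config()) {
  if (!is.data.frame(precursors)) {
    precursors <- tibble(stem_mismatch_count = as.integer(precursors))
  }
  if (!"stem_mismatch_count" %in% names(precursors)) {
    abort("`precursors` needs a `stem_mismatch_count` column.")
  }
  if (any(precursors$stem_mismatch_count < 0)) {
    abort("`stem_mismatch_count` must be >= 0.")
  }
  precursors |>
    mutate(
      p_rde1 = ifelse(.data$stem_mismatch_count == 0, config$w0, config$w_mm),
      p_alg = 1 - .data$p_rde1
    )
}

# Sample `n` antisense secondary siRNA reads from a gene's spliced
# transcript. Start positions are drawn with weight exp(lambda * x), x the
# fractional 5'->3' transcript position, realizing the 3' coverage bias.
# Returns an aggregated tibble (seq, count, five_prime, true_source).
locus_secondary_reads <- function(gene, n, config) {
  rl <- config$read_length
  tx <- gene$transcript
  lx <- nchar(tx)
  if (n == 0 || lx < rl) {
    return(tibble(seq = character(), count = integer(),
                  five_prime = character(), true_source = character()))
  }
  max_s <- lx - rl
  s0 <- 0:max_s
  w <- exp(config$gradient_lambda * s0 / max_s)
  starts <- sample(s0, n, replace = TRUE, prob = w)
  r <- rle(sort(substring(tx, starts + 1L, starts + rl)))
  tibble(
    seq = reverse_complement(r$values),
    count = r$lengths,
    five_prime = "triP",
    true_source = paste0("sirna:", gene$gene_id)
  )
}

# Base-R aggregation of identical (seq, five_prime, true_source) rows;
# returns rows sorted by that key.
aggregate_reads <- function(df) {
  if (nrow(df) == 0) return(df)
  key <- paste(df$seq, df$five_prime, df$true_source, sep = "\1")
  o <- order(key, method = "radix")
  df <- df[o, ]
  k <- key[o]
  first <- !duplicated(k)
  cnt <- as.vector(rowsum(as.numeric(df$count), cumsum(first)))
  out <- df[first, ]
  out$count <- as.integer(cnt)
  out
}

#' Simulate RdRP-made secondary siRNAs at one locus
#'
#' Emits 22-nt reads strictly antisense to the gene's spliced transcript
#' (so some span exon-exon junctions and are absent from the genome), all
#' carrying a 5' triphosphate, with start positions biased toward the
#' transcript 3' end. The expected read total is
#' `sirna_base_rate * depth * g(genotype)`, where `g` is
#' [genotype_factor()]; a locus without a trigger site yields no reads.
#'
#' @param gene One row of `world$genes` (the locus's gene model).
#' @param trigger_present Is the upstream trigger (perfectly matched
#'   miRNA site plus scavenger-Argonaute loading) available at this locus?
#' @param geno A [genotype()].
#' @param config A [sim_config()].
#' @param depth Library depth the base rate refers to.
#' @param seed Integer seed.
#' @return Tibble with columns `seq`, `count`, `five_prime`,
#'   `true_source`.
#' @export
simulate_secondary_sirnas <- function(gene, trigger_present = TRUE,
                                      geno = genotype(),
                                      config = sim_config(),
                                      depth = 100000L, seed = 1L) {
  if (is.null(gene$exons) || nrow(gene$exons[[1]]) == 0 ||
      is.na(gene$transcript)) {
    abort("Gene model has no exons/transcript; cannot template an RdRP.")
  }
  g <- if (!isTRUE(trigger_present)) 0 else genotype_factor(geno, config)
  withr::with_seed(seed, {
    n <- rpois(1, config$sirna_base_rate * depth * g)
    locus_secondary_reads(gene, n, config)
  })
}

#' Apply the TAP cloning rule to a read set
#'
#' Ligation-based cloning requires a 5' monophosphate. Tobacco acid
#' pyrophosphatase (TAP) trims 5' triphosphates to monophosphates, so
#' triphosphate (RdRP-made) reads are clonable only in TAP-treated
#' libraries; monophosphate (Dicer-made) reads are always retained.
#'
#' @param reads Tibble with a `five_prime` column (`"monoP"`/`"triP"`).
#' @param tap_treated Logical: was the library TAP treated?
#' @return The filtered tibble (counts unchanged).
#' @export
apply_tap <- function(reads, tap_treated) {
  if (isTRUE(tap_treated)) {
    return(reads)
  }
  filter(reads, .data$five_prime == "monoP")
}

# Per-locus trigger machinery factor within a library: trigger-dependent
# loci respond to the genotype; constitutive endo-siRNA loci do not.
locus_factors <- function(genes, geno, config) {
  vapply(seq_len(nrow(genes)), function(i) {
    if (!genes$rde1_dependent[i]) 1 else genotype_factor(geno, config)
  }, numeric(1))
}

# Unnormalized sampling weights over read sources for one library design.
library_source_weights <- function(spec, world, config) {
  mir <- world$mirnas
  genes <- world$genes
  sirna_genes <- genes[genes$role %in% c("target", "sirna_locus"), ]
  g_loc <- if (nrow(sirna_genes)) {
    locus_factors(sirna_genes, spec$genotype, config)
  } else {
    numeric()
  }
  sirna_w_pool <- config$sirna_base_rate * g_loc
  pf <- config$pool_fractions
  class_pool <- c(
    p21U_RNA = unname(pf["p21U_RNA"]), tRNA = unname(pf["tRNA"]),
    rRNA = unname(pf["rRNA"]), snoRNA = unname(pf["snoRNA"]),
    snRNA = unname(pf["snRNA"]), scRNA = unname(pf["scRNA"]),
    repeat_RNA = unname(pf["repeat_RNA"]),
    non_hairpin_region = unname(pf["non_hairpin_region"]),
    sense_RNA = unname(pf["sense_RNA"]), other = unname(pf["other"])
  )
  mir_expr <- if (nrow(mir)) mir$expression / sum(mir$expression) else numeric()
  loading <- if (nrow(mir)) {
    mismatch_loading_distribution(mir, config)
  } else {
    mir
  }

  src <- list()
  add <- function(kind, id, weight) {
    src[[length(src) + 1]] <<- tibble(kind = kind, id = id, weight = weight)
  }
  if (spec$ip_target == "none") {
    if (nrow(mir)) {
      add("mirna", mir$mirna_id, unname(pf["known_microRNA"]) * mir_expr)
    }
    if (nrow(sirna_genes)) add("sirna", sirna_genes$gene_id, sirna_w_pool)
    add("class", names(class_pool), unname(class_pool))
  } else if (spec$ip_target %in% c("ALG-1", "ALG-2")) {
    if (nrow(mir)) {
      w <- mir_expr * loading$p_alg
      add("mirna", mir$mirna_id, config$alg_purity * w / sum(w))
    }
    bg_pool <- c(sirna_w_pool, unname(class_pool))
    bg <- (1 - config$alg_purity) * bg_pool / sum(bg_pool)
    nb <- length(sirna_w_pool)
    if (nb) add("sirna", sirna_genes$gene_id, bg[seq_len(nb)])
    add("class", names(class_pool), bg[(nb + 1):length(bg)])
  } else { # RDE-1 IP: scavenger mixture over classes
    sb <- config$scavenger_background
    if (nrow(mir)) {
      w <- mir_expr * loading$p_rde1
      add("mirna", mir$mirna_id, unname(sb["known_microRNA"]) * w / sum(w))
    }
    if (nrow(sirna_genes) && sum(sirna_w_pool) > 0) {
      add("sirna", sirna_genes$gene_id,
          unname(sb["siRNA"]) * sirna_w_pool / sum(sirna_w_pool))
    }
    add("class", "repeat_RNA", unname(sb["repeat_RNA"]))
    add("class", "sense_RNA", unname(sb["sense_RNA"]))
    others <- class_pool[c("tRNA", "rRNA", "snoRNA", "snRNA", "scRNA",
                           "non_hairpin_region", "other")]
    add("class", names(others),
        unname(sb["other_classes"]) * unname(others) / sum(others))
  }
  out <- bind_rows(src)
  # Drop sources with no generating features in this world.
  has_feature <- function(cls) {
    map <- c(p21U_RNA = "p21u_locus", tRNA = "tRNA", rRNA = "rRNA",
             snoRNA = "snoRNA", snRNA = "snRNA", scRNA = "scRNA",
             repeat_RNA = "repeat", non_hairpin_region = "non_hairpin_region")
    if (cls == "other") return(nrow(world$gaps) > 0)
    if (cls == "sense_RNA") return(nrow(world$genes) > 0)
    sum(world$annotations$feature_class == map[[cls]]) > 0
  }
  keep <- rep(TRUE, nrow(out))
  is_class <- out$kind == "class"
  keep[is_class] <- vapply(out$id[is_class], has_feature, logical(1))
  out <- out[keep & out$weight > 0, ]
  if (nrow(out) == 0 || sum(out$weight) <= 0) {
    abort("Library design has no read sources with positive weight.")
  }
  out
}

# Sample a 22-nt feature-strand window from annotated features of a class.
class_window_reads <- function(n, cls, world, config) {
  rl <- config$read_length
  map <- c(p21U_RNA = "p21u_locus", tRNA = "tRNA", rRNA = "rRNA",
           snoRNA = "snoRNA", snRNA = "snRNA", scRNA = "scRNA",
           repeat_RNA = "repeat", non_hairpin_region = "non_hairpin_region")
  g <- unname(world$genome[1])
  if (cls == "p21U_RNA") {
    loci <- world$annotations |> filter(.data$feature_class == "p21u_locus")
    pick <- sample(nrow(loci), n, replace = TRUE)
    seqs <- vapply(unique(pick), function(i) {
      s <- substr0(g, loci$start[i], loci$end[i])
      if (loci$strand[i] == "-") reverse_complement(s) else s
    }, character(1))
    names(seqs) <- loci$id[unique(pick)]
    tab <- table(loci$id[pick])
    return(tibble(
      seq = unname(seqs[names(tab)]), count = as.integer(tab),
      five_prime = "monoP", true_source = names(tab)
    ))
  }
  if (cls == "sense_RNA") {
    genes <- world$genes
    gi <- sample(nrow(genes), n, replace = TRUE)
    seqs <- character(n)
    for (gidx in unique(gi)) {
      j <- which(gi == gidx)
      gene <- genes[gidx, ]
      ex <- gene$exons[[1]]
      wts <- pmax(ex$end - ex$start - rl + 1L, 0L)
      e <- sample.int(nrow(ex), length(j), replace = TRUE, prob = wts)
      s0 <- ex$start[e] +
        floor(runif(length(j)) * (ex$end[e] - ex$start[e] - rl + 1L))
      s <- substring(g, s0 + 1L, s0 + rl)
      if (gene$strand == "-") s <- reverse_complement(s)
      seqs[j] <- s
    }
    df <- tibble(seq = seqs, true_source = paste0("sense:", genes$gene_id[gi]))
  } else if (cls == "other") {
    gaps <- world$gaps
    wts <- gaps$end - gaps$start - rl + 1L
    gi <- sample(nrow(gaps), n, replace = TRUE, prob = wts)
    s0 <- gaps$start[gi] +
      floor(runif(n) * (gaps$end[gi] - gaps$start[gi] - rl + 1L))
    df <- tibble(seq = substring(g, s0 + 1L, s0 + rl), true_source = "other")
  } else {
    feats <- world$annotations |> filter(.data$feature_class == map[[cls]])
    fi <- sample(nrow(feats), n, replace = TRUE)
    s0 <- feats$start[fi] +
      floor(runif(n) * (feats$end[fi] - feats$start[fi] - rl + 1L))
    seqs <- substring(g, s0 + 1L, s0 + rl)
    flip <- feats$strand[fi] == "-"
    seqs[flip] <- reverse_complement(seqs[flip])
    df <- tibble(seq = seqs, true_source = feats$id[fi])
  }
  df$count <- 1L
  df$five_prime <- "monoP"
  aggregate_reads(df[, c("seq", "count", "five_prime", "true_source")])
}

#' Simulate one small RNA sequencing library
#'
#' Draws exactly `spec$depth` reads from a mixture over read sources
#' determined by the library design: total-RNA libraries sample the
#' cellular pool (miRNAs, per-locus secondary siRNAs scaled by the
#' genotype, 21U-RNAs, structural RNAs, repeats, and background classes);
#' ALG-1/ALG-2 immunoprecipitates are nearly pure miRNA, weighted toward
#' mismatched-stem precursors; RDE-1 immunoprecipitates draw the scavenger
#' mixture (majority miRNA - biased toward perfect-stem precursors -,
#' repeats, secondary siRNAs, sense fragments; no 21U-RNAs). The TAP
#' cloning rule is applied last, so untreated libraries lose their
#' triphosphate reads after the depth draw.
#'
#' @param spec A [library_spec()].
#' @param world A [build_toy_genome()] world.
#' @param config A [sim_config()]; defaults to the world's.
#' @return Tibble with columns `seq`, `count`, `five_prime`,
#'   `true_source` (generator-side label, for test oracles only), sorted
#'   by `seq`; the library spec is attached as attribute `"spec"`.
#' @export
simulate_library <- function(spec, world, config = world$config) {
  stopifnot(inherits(spec, "library_spec"), inherits(world, "toy_world"))
  withr::with_seed(spec$seed, {
    src <- library_source_weights(spec, world, config)
    counts <- as.vector(rmultinom(1, spec$depth, src$weight))
    src$n <- counts
    src <- src[src$n > 0, ]
    parts <- purrr::pmap(src, function(kind, id, weight, n) {
      if (kind == "mirna") {
        m <- world$mirnas[world$mirnas$mirna_id == id, ]
        tibble(seq = m$mature, count = n, five_prime = "monoP",
               true_source = id)
      } else if (kind == "sirna") {
        gene <- world$genes[world$genes$gene_id == id, ]
        locus_secondary_reads(gene, n, config)
      } else {
        class_window_reads(n, id, world, config)
      }
    })
    reads <- aggregate_reads(bind_rows(parts))
    reads <- apply_tap(reads, spec$tap_treated)
    attr(reads, "spec") <- spec
    reads
  })
}
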