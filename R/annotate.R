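# Exact-match read mapping and twelve-class read annotation.

#' Build an exact-match genome index
#'
#' Prepares both genome strands for exact short-read matching (the
#' forward sequence and its reverse complement). Queries of any length up
#' to the chromosome length are answered; hits on the minus strand are
#' reported in forward-genome coordinates.
#'
#' @param genome Named character vector of chromosome sequences, or a
#'   `toy_world`.
#' @return An object of class `genome_index`.
#' @export
build_index <- function(genome) {
  if (inherits(genome, "toy_world")) genome <- genome$genome
  if (length(genome) == 0 || any(nchar(genome) == 0)) {
    abort("Cannot index an empty genome.")
  }
  if (is.null(names(genome))) {
    names(genome) <- paste0("chr", seq_along(genome))
  }
  assert_dna(unname(genome), "genome")
  structure(
    list(
      fwd = genome,
      rev = setNames(reverse_complement(unname(genome)), names(genome)),
      chrom_len = setNames(nchar(genome), names(genome))
    ),
    class = "genome_index"
  )
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> %d chromosome(s), %s bp total\n",
              length(x$chrom_len), format(sum(x$chrom_len), big.mark = ",")))
  invisible(x)
}

# All exact hits of `seqs` (grouped by length) on one strand of one
# chromosome, by hashing every genome window of the needed widths.
match_one_strand <- function(seqs, subject_seq) {
  L <- nchar(subject_seq)
  res <- list()
  for (wi in unique(nchar(seqs))) {
    if (wi > L || wi < 1L) next
    starts1 <- seq_len(L - wi + 1L)
    windows <- substring(subject_seq, starts1, starts1 + wi - 1L)
    m <- windows %in% seqs
    if (!any(m)) next
    res[[length(res) + 1]] <- tibble(
      seq = windows[m], start1 = starts1[m], width = wi
    )
  }
  if (length(res)) bind_rows(res) else
    tibble(seq = character(), start1 = integer(), width = integer())
}

#' Map reads to the genome by exact matching
#'
#' Reports every exact occurrence of each read on either genome strand
#' (no hit cap, no mismatches). Minus-strand hits are positions where the
#' read's reverse complement matches the forward sequence, reported in
#' forward 0-based half-open coordinates. Reads with no hit on either
#' strand are recorded in the `"unmapped"` attribute.
#'
#' @param reads Tibble with a `seq` column (e.g. from
#'   [simulate_library()]), or a character vector of read sequences.
#' @param index A [build_index()] object.
#' @return Tibble of alignments: `seq`, `chrom`, `start`, `end`,
#'   `strand`, `n_hits` (total hits of that read genome-wide), with
#'   attribute `"unmapped"` (character vector of unplaceable sequences).
#' @export
map_reads <- function(reads, index) {
  stopifnot(inherits(index, "genome_index"))
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  seqs <- unique(seqs)
  assert_dna(seqs, "read")
  aln <- list()
  for (ci in seq_along(index$fwd)) {
    chrom <- names(index$chrom_len)[ci]
    L <- index$chrom_len[[ci]]
    f <- match_one_strand(seqs, index$fwd[[ci]])
    if (nrow(f)) {
      aln[[length(aln) + 1]] <- f |>
        mutate(chrom = chrom, start = .data$start1 - 1L,
               end = .data$start1 - 1L + .data$width, strand = "+")
    }
    r <- match_one_strand(seqs, index$rev[[ci]])
    if (nrow(r)) {
      aln[[length(aln) + 1]] <- r |>
        mutate(chrom = chrom, start = L - (.data$start1 - 1L + .data$width),
               end = L - (.data$start1 - 1L), strand = "-")
    }
  }
  out <- if (length(aln)) {
    bind_rows(aln) |>
      select("seq", "chrom", "start", "end", "strand") |>
      arrange(.data$seq, .data$chrom, .data$start, .data$strand)
  } else {
    tibble(seq = character(), chrom = character(), start = integer(),
           end = integer(), strand = character())
  }
  if (nrow(out)) {
    uid <- match(out$seq, unique(out$seq))
    out$n_hits <- tabulate(uid)[uid]
  } else {
    out$n_hits <- integer()
  }
  attr(out, "unmapped") <- setdiff(seqs, out$seq)
  out
}

#' Sequences a mapping left unplaced
#'
#' @param alignments Result of [map_reads()].
#' @return Character vector of unmapped read sequences.
#' @export
unmapped_reads <- function(alignments) {
  attr(alignments, "unmapped") %||% character()
}

# GRanges of classification substrates: non-gene annotation features, gene
# exonic spans, and gene spans.
classification_ranges <- function(annotations, genes) {
  feats <- annotations |> filter(.data$feature_class != "coding_gene")
  pieces <- list()
  if (nrow(feats)) {
    pieces$feat <- GenomicRanges::GRanges(
      feats$chrom, IRanges::IRanges(feats$start + 1L, feats$end),
      strand = feats$strand, kind = feats$feature_class, id = feats$id
    )
  }
  if (!is.null(genes) && nrow(genes)) {
    ex <- genes |>
      select("gene_id", "chrom", "strand", "exons") |>
      tidyr::unnest("exons")
    pieces$exon <- GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end),
      strand = ex$strand, kind = "gene_exon", id = ex$gene_id
    )
    pieces$span <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$span_start + 1L, genes$span_end),
      strand = genes$strand, kind = "gene_span", id = genes$gene_id
    )
  }
  if (length(pieces) == 0) {
    return(GenomicRanges::GRanges())
  }
  do.call(c, unname(pieces))
}

#' Classify mapped reads into the twelve small RNA categories
#'
#' Each mapped read receives exactly one category, chosen by a fixed
#' priority over all of its alignments: known_microRNA > p21U_RNA > rRNA
#' > tRNA > snoRNA > snRNA > scRNA > repeat_RNA > siRNA > sense_RNA >
#' non_hairpin_region > other. miRNA and 21U calls require >= 90% of the
#' read's span inside the hairpin/locus on the same strand; structural
#' RNA, repeat and non-hairpin calls accept any overlap on either strand;
#' `siRNA` requires an alignment antisense to a coding gene's exonic
#' span; `sense_RNA` is a same-strand overlap of a gene span; `other`
#' means no alignment overlaps any annotation.
#'
#' @param alignments Tibble from [map_reads()].
#' @param annotations Annotation tibble (`world$annotations`).
#' @param genes Gene model tibble (`world$genes`), or `NULL`.
#' @return Tibble with one row per distinct read sequence: `seq`,
#'   `category`, supporting alignment columns (`chrom`, `start`, `end`,
#'   `strand`), `locus_id` (the gene behind an siRNA/sense call, else
#'   `NA`) and `n_hits`.
#' @export
classify_reads <- function(alignments, annotations, genes = NULL) {
  if (nrow(alignments) == 0) {
    return(tibble(seq = character(), category = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), locus_id = character(),
                  n_hits = integer()))
  }
  subj <- classification_ranges(annotations, genes)
  q <- GenomicRanges::GRanges(
    alignments$chrom,
    IRanges::IRanges(alignments$start + 1L, alignments$end),
    strand = alignments$strand
  )
  hits <- GenomicRanges::findOverlaps(q, subj, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(q[qh], subj[sh], ignore.strand = TRUE)
  pairs <- tibble(
    ai = qh,
    kind = S4Vectors::mcols(subj)$kind[sh],
    feat_id = S4Vectors::mcols(subj)$id[sh],
    feat_strand = as.character(GenomicRanges::strand(subj[sh])),
    ov_width = GenomicRanges::width(ov)
  )
  pairs$read_strand <- alignments$strand[pairs$ai]
  pairs$read_len <- alignments$end[pairs$ai] - alignments$start[pairs$ai]
  same <- pairs$feat_strand == pairs$read_strand
  frac_ok <- pairs$ov_width >= 0.9 * pairs$read_len
  pairs$category <- dplyr::case_when(
    pairs$kind == "mirna_hairpin" & same & frac_ok ~ "known_microRNA",
    pairs$kind == "p21u_locus" & same & frac_ok ~ "p21U_RNA",
    pairs$kind == "rRNA" ~ "rRNA",
    pairs$kind == "tRNA" ~ "tRNA",
    pairs$kind == "snoRNA" ~ "snoRNA",
    pairs$kind == "snRNA" ~ "snRNA",
    pairs$kind == "scRNA" ~ "scRNA",
    pairs$kind == "repeat" ~ "repeat_RNA",
    pairs$kind == "gene_exon" & !same ~ "siRNA",
    pairs$kind == "gene_span" & same ~ "sense_RNA",
    pairs$kind == "non_hairpin_region" ~ "non_hairpin_region",
    TRUE ~ NA_character_
  )
  pairs <- pairs |> filter(!is.na(.data$category))
  pairs$prio <- match(pairs$category, CATEGORY_PRIORITY)
  # best candidate per alignment, then best alignment per read
  ord <- order(pairs$ai, pairs$prio)
  first <- ord[!duplicated(pairs$ai[ord])]
  aln_category <- rep(NA_character_, nrow(alignments))
  aln_feat <- rep(NA_character_, nrow(alignments))
  aln_category[pairs$ai[first]] <- pairs$category[first]
  aln_feat[pairs$ai[first]] <- pairs$feat_id[first]
  prio <- match(aln_category, CATEGORY_PRIORITY)
  prio[is.na(prio)] <- length(CATEGORY_PRIORITY)
  ord2 <- order(alignments$seq, prio, alignments$chrom, alignments$start,
                alignments$strand, method = "radix")
  keep <- ord2[!duplicated(alignments$seq[ord2])]
  per_read <- alignments[keep, ] |>
    mutate(
      category = dplyr::coalesce(aln_category[keep], "other"),
      locus_id = ifelse(.data$category %in% c("siRNA", "sense_RNA"),
                        aln_feat[keep], NA_character_)
    ) |>
    select("seq", "category", "chrom", "start", "end", "strand",
           "locus_id", "n_hits") |>
    arrange(.data$seq)
  per_read
}

#' Map and classify a read library against a toy world
#'
#' Convenience wrapper chaining [map_reads()] and [classify_reads()] and
#' joining the calls back onto the read table. Unmapped reads (for
#' example exon-junction-spanning secondary siRNAs, which have no exact
#' genomic match) are kept with `category = NA` and `mapped = FALSE`.
#'
#' @param reads Read tibble (`seq`, `count`, ...).
#' @param world A `toy_world`.
#' @param index Optional prebuilt [build_index()].
#' @return The read tibble with `category`, supporting alignment columns,
#'   `locus_id`, `n_hits` and `mapped` added.
#' @export
annotate_library <- function(reads, world, index = NULL) {
  index <- index %||% build_index(world)
  aln <- map_reads(reads, index)
  calls <- classify_reads(aln, world$annotations, world$genes)
  out <- reads |>
    left_join(calls, by = "seq") |>
    mutate(mapped = !is.na(.data$category))
  attr(out, "unmapped") <- unmapped_reads(aln)
  out
}

#' Library composition over the twelve categories
#'
#' Aggregates classified reads (weighting each read by its `count`) into
#' the per-category composition table; fractions are over mapped reads.
#'
#' @param calls Tibble from [annotate_library()] (or any tibble with
#'   `category` and optionally `count` columns). Rows with `NA` category
#'   (unmapped reads) are excluded from the denominator.
#' @return Tibble with columns `category` (all twelve, in priority
#'   order), `reads` and `fraction` (summing to 1).
#' @export
summarize_library <- function(calls) {
  if (!"count" %in% names(calls)) calls$count <- 1L
  mapped <- calls |> filter(!is.na(.data$category))
  if (nrow(mapped) == 0) {
    abort("No classified reads; cannot summarize composition.")
  }
  mapped |>
    mutate(category = factor(.data$category, levels = CATEGORY_PRIORITY)) |>
    group_by(.data$category, .drop = FALSE) |>
    summarise(reads = sum(.data$count), .groups = "drop") |>
    mutate(fraction = .data$reads / sum(.data$reads))
}
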