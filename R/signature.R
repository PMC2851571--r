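# Per-locus secondary siRNA signature statistics: antisense polarity,
# TAP (5' triphosphate) dependence, exon restriction, 3' coverage
# gradient, and the combined verdict.

# Place locus reads on the gene: orientation relative to the gene strand,
# position on the spliced transcript, exonic status and junction status.
# A junction read matches the spliced transcript (in antisense or sense
# orientation) but has no exact occurrence in the genome.
locus_read_placement <- function(reads, gene, genome) {
  if (is.character(genome)) genome <- unname(genome[1])
  tx <- gene$transcript
  lens <- {
    ex <- gene$exons[[1]]
    ex$end - ex$start
  }
  cum <- cumsum(if (gene$strand == "-") rev(lens) else lens)
  boundaries <- head(cum, -1) # tx coords where an exon ends
  if (!"count" %in% names(reads)) reads$count <- 1L
  n <- nrow(reads)
  tx_pos <- rep(NA_integer_, n)
  orientation <- rep(NA_character_, n)
  junction <- rep(FALSE, n)
  exonic <- rep(FALSE, n)
  span_seq <- substr0(genome, gene$span_start, gene$span_end)
  for (i in seq_len(n)) {
    s <- reads$seq[i]
    rc <- reverse_complement(s)
    a <- regexpr(rc, tx, fixed = TRUE)[1]
    if (a > 0) {
      orientation[i] <- "antisense"
      tx_pos[i] <- a - 1L
      exonic[i] <- TRUE
    } else {
      sp <- regexpr(s, tx, fixed = TRUE)[1]
      if (sp > 0) {
        orientation[i] <- "sense"
        tx_pos[i] <- sp - 1L
        exonic[i] <- TRUE
      } else {
        # intronic / boundary-overlapping reads: locate within the gene
        # span on the forward genome
        f <- regexpr(s, span_seq, fixed = TRUE)[1]
        r <- regexpr(rc, span_seq, fixed = TRUE)[1]
        read_gstrand <- if (f > 0) "+" else if (r > 0) "-" else NA_character_
        if (!is.na(read_gstrand)) {
          orientation[i] <- if (read_gstrand == gene$strand) "sense" else "antisense"
        }
      }
    }
    if (!is.na(tx_pos[i])) {
      crosses <- any(boundaries > tx_pos[i] &
                       boundaries < tx_pos[i] + nchar(s))
      if (crosses && count_occurrences_both_strands(s, genome) == 0) {
        junction[i] <- TRUE
      }
    }
  }
  reads |>
    mutate(orientation = orientation, tx_pos = tx_pos, exonic = exonic,
           junction = junction)
}

#' Antisense fraction of a locus's reads
#'
#' Count-weighted fraction of the locus's placeable reads that lie
#' antisense to the gene strand. RdRP products are strictly antisense to
#' their template; Dicer products of a dsRNA region come in both
#' polarities.
#'
#' @param reads Locus read tibble (`seq`, `count`).
#' @param gene One row of `world$genes`.
#' @param genome Genome sequence (named character vector or string).
#' @return A single number in `[0, 1]`, or `NA` if no read could be
#'   oriented.
#' @export
strand_polarity <- function(reads, gene, genome) {
  if (nrow(reads) == 0) return(NA_real_)
  pl <- locus_read_placement(reads, gene, genome) |>
    filter(!is.na(.data$orientation))
  if (nrow(pl) == 0) return(NA_real_)
  sum(pl$count[pl$orientation == "antisense"]) / sum(pl$count)
}

#' TAP dependence of a locus's siRNAs
#'
#' Compares the locus's read count in a TAP-treated library against the
#' matched untreated library (both scaled to equal totals):
#' `log2((count_tap + p) / (count_no_tap + p))`. Secondary (RdRP-made,
#' 5'-triphosphate) siRNA populations require TAP for cloning, so a large
#' statistic (default >= 3, about 8-fold) flags a secondary-like locus.
#'
#' @param count_tap,count_no_tap Scaled locus counts in the TAP+ / TAP-
#'   libraries.
#' @param pseudocount Pseudocount `p` (default 1).
#' @param flag_threshold Statistic at or above which the locus is flagged
#'   secondary (default 3).
#' @return One-row tibble: `tap_statistic`, `tap_secondary`,
#'   `tap_insufficient` (both counts zero).
#' @export
tap_dependence <- function(count_tap, count_no_tap, pseudocount = 1,
                           flag_threshold = 3) {
  insufficient <- isTRUE(count_tap == 0 && count_no_tap == 0) ||
    is.na(count_tap) || is.na(count_no_tap)
  stat <- if (insufficient) NA_real_ else {
    log2((count_tap + pseudocount) / (count_no_tap + pseudocount))
  }
  tibble(
    tap_statistic = stat,
    tap_secondary = !insufficient && stat >= flag_threshold,
    tap_insufficient = insufficient
  )
}

#' Exon restriction of a locus's reads
#'
#' RdRP enzymes copying a spliced mRNA yield siRNAs confined to exons,
#' including reads spanning exon-exon junctions (absent from the genome
#' but matching the spliced transcript). Reads inside introns argue for a
#' genomic (unspliced) template instead.
#'
#' @inheritParams strand_polarity
#' @return One-row tibble: `exonic_fraction` (count-weighted),
#'   `junction_read_count` (count-weighted reads matching the transcript
#'   but absent from the genome).
#' @export
exon_restriction <- function(reads, gene, genome) {
  if (nrow(reads) == 0) {
    return(tibble(exonic_fraction = NA_real_, junction_read_count = 0))
  }
  pl <- locus_read_placement(reads, gene, genome)
  tibble(
    exonic_fraction = sum(pl$count[pl$exonic]) / sum(pl$count),
    junction_read_count = sum(pl$count[pl$junction])
  )
}

#' Antisense coverage along the spliced transcript
#'
#' @inheritParams strand_polarity
#' @return Numeric vector of per-position antisense read coverage in
#'   transcript coordinates (5' to 3').
#' @export
locus_antisense_coverage <- function(reads, gene, genome) {
  cov <- numeric(nchar(gene$transcript))
  if (nrow(reads) == 0) return(cov)
  pl <- locus_read_placement(reads, gene, genome) |>
    filter(.data$orientation == "antisense", !is.na(.data$tx_pos))
  for (i in seq_len(nrow(pl))) {
    idx <- (pl$tx_pos[i] + 1L):min(pl$tx_pos[i] + nchar(pl$seq[i]),
                                   length(cov))
    cov[idx] <- cov[idx] + pl$count[i]
  }
  cov
}

#' 3' coverage gradient statistics
#'
#' Quantifies the 3' bias expected when RdRP recruitment occurs at the
#' transcript 3' end and polymerization peters out toward the 5' end:
#' `gradient_stat` is the log2 ratio of total coverage in the 3' half
#' over the 5' half (middle base excluded for odd lengths, so mirroring
#' the profile flips the sign exactly), and `gradient_rho` is the
#' Spearman correlation between window index (5' to 3') and per-window
#' coverage.
#'
#' @param coverage Per-position coverage vector in transcript
#'   coordinates (e.g. [locus_antisense_coverage()]).
#' @param window Window size in nt (default 25).
#' @param pseudocount Pseudocount for the half-ratio (default 1).
#' @return One-row tibble: `gradient_stat`, `gradient_rho`, `n_windows`;
#'   both statistics `NA` when coverage is all zero.
#' @export
coverage_gradient <- function(coverage, window = 25L, pseudocount = 1) {
  L <- length(coverage)
  if (L < 2L * window) {
    abort("Transcript shorter than two windows; cannot assess a gradient.")
  }
  if (all(coverage == 0)) {
    return(tibble(gradient_stat = NA_real_, gradient_rho = NA_real_,
                  n_windows = 0L))
  }
  h <- L %/% 2L
  five <- sum(coverage[seq_len(h)])
  three <- sum(coverage[(L - h + 1L):L])
  win_idx <- ((seq_len(L) - 1L) %/% window) + 1L
  wc <- as.numeric(tapply(coverage, win_idx, sum))
  rho <- suppressWarnings(cor(seq_along(wc), wc, method = "spearman"))
  tibble(
    gradient_stat = log2((three + pseudocount) / (five + pseudocount)),
    gradient_rho = rho,
    n_windows = length(wc)
  )
}

#' Combined secondary-versus-primary verdict for a locus
#'
#' A pure decision rule over the computed statistics: with fewer than
#' `min_reads` reads the locus is `insufficient_data`; it is
#' `secondary-like` when the reads are (nearly) strictly antisense,
#' strongly TAP dependent and (nearly) fully exonic; `primary-like` when
#' cloning shows no meaningful TAP dependence; otherwise `mixed`.
#'
#' @param total_reads Total (count-weighted) locus reads.
#' @param antisense_fraction,tap_statistic,exonic_fraction Component
#'   statistics.
#' @param min_reads Minimum reads for any verdict (default 50).
#' @param antisense_min,tap_min,exonic_min Secondary-like thresholds
#'   (defaults 0.95, 3, 0.95).
#' @param tap_primary_max Primary-like threshold (default 1).
#' @return One of `"secondary-like"`, `"primary-like"`, `"mixed"`,
#'   `"insufficient_data"`.
#' @export
signature_verdict <- function(total_reads, antisense_fraction,
                              tap_statistic, exonic_fraction,
                              min_reads = 50, antisense_min = 0.95,
                              tap_min = 3, exonic_min = 0.95,
                              tap_primary_max = 1) {
  if (is.na(total_reads) || total_reads < min_reads) {
    return("insufficient_data")
  }
  if (!is.na(antisense_fraction) && !is.na(tap_statistic) &&
      !is.na(exonic_fraction) &&
      antisense_fraction >= antisense_min && tap_statistic >= tap_min &&
      exonic_fraction >= exonic_min) {
    return("secondary-like")
  }
  if (!is.na(tap_statistic) && tap_statistic <= tap_primary_max) {
    return("primary-like")
  }
  "mixed"
}

#' Full secondary siRNA signature report for one locus
#'
#' Computes all four signature statistics from the locus's reads in a
#' TAP-treated library plus the locus's scaled counts in a matched
#' TAP+/TAP- library pair, and renders the verdict. When the trigger
#' site's transcript position is supplied, the fraction of antisense
#' reads 5' (upstream, in target coordinates) of the site is reported as
#' an auxiliary statistic (not gated on).
#'
#' @param reads Locus reads from the TAP-treated library (`seq`,
#'   `count`).
#' @param gene One row of `world$genes`.
#' @param genome Genome sequence.
#' @param count_tap,count_no_tap Scaled locus totals in the TAP+ and
#'   TAP- libraries (default: `count_tap` from `reads`, `count_no_tap`
#'   `NA`).
#' @param trigger_tx_start Optional 0-based transcript position of the
#'   trigger site.
#' @param window,pseudocount,min_reads Passed to the component
#'   statistics.
#' @return One-row tibble of class `locus_signature`.
#' @export
locus_signature <- function(reads, gene, genome,
                            count_tap = sum(reads$count),
                            count_no_tap = NA_real_,
                            trigger_tx_start = NA_integer_,
                            window = 25L, pseudocount = 1,
                            min_reads = 50) {
  if (!"count" %in% names(reads)) reads$count <- 1L
  total <- sum(reads$count)
  pl <- locus_read_placement(reads, gene, genome)
  placed <- pl |> filter(!is.na(.data$orientation))
  af <- if (nrow(placed)) {
    sum(placed$count[placed$orientation == "antisense"]) / sum(placed$count)
  } else {
    NA_real_
  }
  ef <- if (nrow(pl)) sum(pl$count[pl$exonic]) / sum(pl$count) else NA_real_
  jc <- sum(pl$count[pl$junction])
  tap <- tap_dependence(count_tap, count_no_tap, pseudocount)
  cov <- numeric(nchar(gene$transcript))
  anti <- pl |> filter(.data$orientation == "antisense", !is.na(.data$tx_pos))
  for (i in seq_len(nrow(anti))) {
    idx <- (anti$tx_pos[i] + 1L):min(anti$tx_pos[i] + nchar(anti$seq[i]),
                                     length(cov))
    cov[idx] <- cov[idx] + anti$count[i]
  }
  gr <- coverage_gradient(cov, window = window, pseudocount = pseudocount)
  upstream <- if (!is.na(trigger_tx_start) && nrow(anti)) {
    sum(anti$count[anti$tx_pos < trigger_tx_start]) / sum(anti$count)
  } else {
    NA_real_
  }
  out <- tibble(
    locus_id = gene$gene_id,
    total_reads = total,
    antisense_fraction = af,
    tap_statistic = tap$tap_statistic,
    exonic_fraction = ef,
    junction_read_count = jc,
    gradient_stat = gr$gradient_stat,
    gradient_rho = gr$gradient_rho,
    upstream_fraction = upstream,
    verdict = signature_verdict(total, af, tap$tap_statistic, ef,
                                min_reads = min_reads)
  )
  class(out) <- c("locus_signature", class(out))
  out
}

#' @rdname locus_signature
#' @param x A `locus_signature`.
#' @param ... Unused.
#' @export
tidy.locus_signature <- function(x, ...) {
  x |>
    as_tibble() |>
    select(-"locus_id", -"verdict") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "statistic",
                        values_to = "value") |>
    mutate(locus_id = x$locus_id[1], .before = 1)
}

#' @rdname locus_signature
#' @export
glance.locus_signature <- function(x, ...) {
  as_tibble(x)
}
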