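# Library scaling and between-library log2 enrichment statistics.

#' Scale a count library to a fixed total
#'
#' Proportional scaling with largest-remainder rounding so that the
#' scaled counts are integers summing to `total` exactly, making
#' libraries of different depths directly comparable.
#'
#' @param counts Tibble with columns `species` and `count`, or a named
#'   numeric vector. May be a subset of the library (e.g. only the miRNA
#'   species, or only siRNA loci); supply `library_total` in that case.
#' @param total Target total (default 100,000 reads).
#' @param library_total The library depth the counts came from (default:
#'   the sum of `counts$count`, i.e. the table is the whole library; in
#'   that case the scaled counts sum to `total` exactly).
#' @return Tibble with columns `species`, `count`, `scaled`, carrying the
#'   scale in attribute `"scale_total"`.
#' @export
scale_library <- function(counts, total = 100000L,
                          library_total = sum(counts$count)) {
  if (!is.data.frame(counts)) {
    counts <- tibble(species = names(counts), count = as.numeric(counts))
  }
  if (!all(c("species", "count") %in% names(counts))) {
    abort("`counts` needs `species` and `count` columns.")
  }
  if (nrow(counts) == 0 || library_total <= 0) {
    abort("Cannot scale an empty library (total count must be > 0).")
  }
  exact <- counts$count * total / library_total
  base <- floor(exact)
  short <- as.integer(round(sum(exact) - sum(base)))
  scaled <- as.integer(base)
  if (short > 0) {
    frac_rank <- order(exact - base, counts$species,
                       decreasing = c(TRUE, FALSE), method = "radix")
    bump <- frac_rank[seq_len(short)]
    scaled[bump] <- scaled[bump] + 1L
  }
  out <- counts |> mutate(scaled = scaled)
  attr(out, "scale_total") <- as.numeric(total)
  out
}

#' Log2 enrichment of one scaled library over another
#'
#' For each species in the union of the two libraries, computes
#' `log2((count_a + p) / (count_b + p))` together with the abundance axis
#' `log2(count_b + p)` used in ratio-versus-abundance scatter plots. A
#' pseudocount keeps species absent from one library computable.
#'
#' @param scaled_a,scaled_b Tibbles from [scale_library()] (columns
#'   `species` and `scaled`), scaled to the same total.
#' @param pseudocount Pseudocount `p` (default 1 scaled read).
#' @return Tibble with `species`, `count_a`, `count_b`, `log2_ratio`,
#'   `log2_abundance`.
#' @export
log2_enrichment <- function(scaled_a, scaled_b, pseudocount = 1) {
  grab <- function(x, side) {
    if (!all(c("species", "scaled") %in% names(x))) {
      abort("Inputs must be scale_library() outputs with `species` and `scaled`.")
    }
    x |> select("species", "scaled") |> rename(!!side := "scaled")
  }
  ta <- attr(scaled_a, "scale_total") %||% sum(scaled_a$scaled)
  tb <- attr(scaled_b, "scale_total") %||% sum(scaled_b$scaled)
  if (ta != tb) {
    abort(sprintf("Libraries are scaled to different totals (%s vs %s).",
                  format(ta), format(tb)))
  }
  full_join(grab(scaled_a, "count_a"), grab(scaled_b, "count_b"),
            by = "species") |>
    mutate(
      count_a = dplyr::coalesce(.data$count_a, 0L),
      count_b = dplyr::coalesce(.data$count_b, 0L),
      log2_ratio = log2((.data$count_a + pseudocount) /
                          (.data$count_b + pseudocount)),
      log2_abundance = log2(.data$count_b + pseudocount)
    ) |>
    arrange(.data$species)
}

#' Per-locus antisense siRNA counts from classified reads
#'
#' Aggregates reads classified `siRNA` whose single genomic alignment
#' (unique mappers only, by default) lies antisense to a locus's exons.
#' All siRNA-capable loci are reported, zero-filled.
#'
#' @param calls Tibble from [annotate_library()].
#' @param genes Gene model tibble (`world$genes`).
#' @param unique_only Count only unique mappers (default `TRUE`).
#' @return Tibble with columns `species` (locus id) and `count`, ready
#'   for [scale_library()].
#' @export
per_locus_sirna_counts <- function(calls, genes, unique_only = TRUE) {
  loci <- genes$gene_id
  hits <- calls |>
    filter(.data$category == "siRNA",
           !unique_only | .data$n_hits == 1L,
           .data$locus_id %in% loci)
  if (!"count" %in% names(hits)) hits$count <- 1L
  hits |>
    group_by(species = .data$locus_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(species = loci, fill = list(count = 0)) |>
    arrange(.data$species)
}

#' Call loci depleted in a mutant library
#'
#' From a [log2_enrichment()] table with A = mutant and B = wild type,
#' returns the loci whose wild-type (scaled) count is at least
#' `min_count_b` and whose log2 ratio is at most `threshold`, most
#' depleted first.
#'
#' @param records [log2_enrichment()] output.
#' @param min_count_b Minimum wild-type scaled count (default 20).
#' @param threshold Maximum log2 ratio (default -2, i.e. >= 4-fold down).
#' @return The filtered records, sorted by `log2_ratio` ascending.
#' @export
call_depleted_loci <- function(records, min_count_b = 20, threshold = -2) {
  records |>
    filter(.data$count_b >= min_count_b, .data$log2_ratio <= threshold) |>
    arrange(.data$log2_ratio)
}
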