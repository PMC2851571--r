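# Perfect-complementarity miRNA target-site scanning and the
# trans-action hit analysis.

#' Scan 3'UTRs for (near-)perfectly complementary miRNA sites
#'
#' Slides a window of the miRNA's length along each UTR and reports every
#' window whose Hamming distance to the reverse complement of the miRNA
#' is at most `max_mismatch` (full-length complementarity; no G:U wobble,
#' no gaps). The default `max_mismatch = 0` finds only perfectly matched
#' sites - the configuration that can hand a transcript over to the RdRP
#' amplification machinery.
#'
#' @param utrs Tibble with columns `transcript_id` and `seq`, or a named
#'   character vector of UTR sequences.
#' @param mirnas Tibble with columns `mirna_id` and `mature` (or `seq`),
#'   or a named character vector of mature miRNA sequences (18-26 nt;
#'   `U` allowed).
#' @param max_mismatch Maximum Hamming mismatches (default 0).
#' @return Tibble of sites: `mirna_id`, `transcript_id`, `start`, `end`
#'   (0-based half-open on the UTR), `mismatch_count`, `site_seq`. UTRs
#'   shorter than the miRNA simply yield no sites.
#' @export
scan_sites <- function(utrs, mirnas, max_mismatch = 0) {
  if (!is.data.frame(utrs)) {
    utrs <- tibble(transcript_id = names(utrs), seq = unname(utrs))
  }
  if (!is.data.frame(mirnas)) {
    mirnas <- tibble(mirna_id = names(mirnas), mature = unname(mirnas))
  }
  if (!"mature" %in% names(mirnas) && "seq" %in% names(mirnas)) {
    mirnas$mature <- mirnas$seq
  }
  lens <- nchar(mirnas$mature)
  if (any(lens < 18 | lens > 26)) {
    abort("Mature miRNA lengths must lie in [18, 26] nt.")
  }
  out <- list()
  for (i in seq_len(nrow(mirnas))) {
    target <- reverse_complement(mirnas$mature[i])
    k <- nchar(target)
    pat <- Biostrings::DNAString(target)
    for (j in seq_len(nrow(utrs))) {
      useq <- chartr("Uu", "Tt", toupper(utrs$seq[j]))
      if (nchar(useq) < k) next
      m <- Biostrings::matchPattern(pat, Biostrings::DNAString(useq),
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m) == 0) next
      starts <- Biostrings::start(m)
      mm <- Biostrings::neditStartingAt(pat, Biostrings::DNAString(useq),
                                        starting.at = starts,
                                        with.indels = FALSE)
      out[[length(out) + 1]] <- tibble(
        mirna_id = mirnas$mirna_id[i],
        transcript_id = utrs$transcript_id[j],
        start = starts - 1L,
        end = starts - 1L + k,
        mismatch_count = as.integer(mm),
        site_seq = substr0(useq, starts - 1L, starts - 1L + k)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(mirna_id = character(), transcript_id = character(),
                  start = integer(), end = integer(),
                  mismatch_count = integer(), site_seq = character()))
  }
  bind_rows(out) |>
    arrange(.data$mirna_id, .data$transcript_id, .data$start)
}

#' Trans-action hit analysis for secondary siRNAs
#'
#' Counts, per transcript, the distinct secondary siRNA species with a
#' full-length antisense match on it, split into unique genomic mappers
#' and multi-mappers, and flags transcripts with at least `min_hits`
#' total hits as candidates for siRNA-driven decay. The default
#' `min_hits = 2` encodes the observation that a single secondary siRNA
#' hit does not suffice to destabilize an mRNA; the flag is advisory.
#'
#' @param reads Secondary siRNA species tibble with a `seq` column;
#'   an optional `n_hits` column (genomic hit count, as produced by
#'   [map_reads()]/[annotate_library()]) separates unique from
#'   multi-mappers (absent, all species count as unique).
#' @param transcripts Tibble with columns `transcript_id` and `seq`, or
#'   a named character vector.
#' @param min_hits Minimum total hits to flag a transcript (default 2).
#' @return Tibble: `transcript_id`, `unique_hits`, `multi_hits`,
#'   `total_hits`, `flagged_for_decay`.
#' @export
trans_hit_analysis <- function(reads, transcripts, min_hits = 2) {
  if (!is.data.frame(transcripts)) {
    transcripts <- tibble(transcript_id = names(transcripts),
                          seq = unname(transcripts))
  }
  species <- reads |> distinct(.data$seq, .keep_all = TRUE)
  if (!"n_hits" %in% names(species)) species$n_hits <- 1L
  rc <- reverse_complement(species$seq)
  purrr::map_dfr(seq_len(nrow(transcripts)), function(j) {
    hit <- vapply(rc, function(p) {
      regexpr(p, transcripts$seq[j], fixed = TRUE)[1] > 0
    }, logical(1))
    uh <- sum(hit & species$n_hits == 1L)
    mh <- sum(hit & species$n_hits > 1L)
    tibble(
      transcript_id = transcripts$transcript_id[j],
      unique_hits = uh, multi_hits = mh, total_hits = uh + mh,
      flagged_for_decay = (uh + mh) >= min_hits
    )
  })
}
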