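# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (window hashing, GenomicRanges overlap, regexpr search):
# character-by-character reverse complement, Biostrings exact matching for
# the two-strand scan, plain interval loops for classification, and
# per-window Hamming counts for site scanning.

# Drop the carry-along `unmapped` attribute so tables compare cleanly.
strip_aln <- function(df) {
  attr(df, "unmapped") <- NULL
  as.data.frame(df)
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  paste(rev(unname(comp[strsplit(toupper(s), "")[[1]]])), collapse = "")
}

# All (possibly overlapping) occurrences of a fixed string, by repeated
# linear scan advancing one position past each match start.
oracle_all_occurrences <- function(pat, subj) {
  out <- integer()
  from <- 1L
  repeat {
    p <- regexpr(pat, substr(subj, from, nchar(subj)), fixed = TRUE)[1]
    if (p < 0) break
    out <- c(out, from + p - 1L)
    from <- from + p
  }
  out
}

# All exact occurrences of `s` on both strands of a genome (0-based
# half-open forward coordinates).
oracle_map_read <- function(s, genome) {
  out <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    if (nchar(s) > nchar(subj)) next
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") s else oracle_revcomp(s)
      starts1 <- oracle_all_occurrences(pat, subj)
      if (length(starts1) == 0) next
      out[[length(out) + 1]] <- tibble::tibble(
        seq = s, chrom = chrom, start = starts1 - 1L,
        end = starts1 - 1L + nchar(s), strand = strand
      )
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(seq = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character())
  }
}

oracle_priority <- c(
  "known_microRNA", "p21U_RNA", "rRNA", "tRNA", "snoRNA", "snRNA",
  "scRNA", "repeat_RNA", "siRNA", "sense_RNA", "non_hairpin_region", "other"
)

# Category of one read from its alignments by nested interval loops.
oracle_classify_read <- function(aln, annotations, genes) {
  cands <- character()
  feats <- annotations[annotations$feature_class != "coding_gene", ]
  for (k in seq_len(nrow(aln))) {
    a <- aln[k, ]
    rlen <- a$end - a$start
    for (f in seq_len(nrow(feats))) {
      ft <- feats[f, ]
      if (ft$chrom != a$chrom) next
      ov <- min(a$end, ft$end) - max(a$start, ft$start)
      if (ov <= 0) next
      same <- ft$strand == a$strand
      cls <- ft$feature_class
      if (cls == "mirna_hairpin") {
        if (same && ov >= 0.9 * rlen) cands <- c(cands, "known_microRNA")
      } else if (cls == "p21u_locus") {
        if (same && ov >= 0.9 * rlen) cands <- c(cands, "p21U_RNA")
      } else if (cls == "repeat") {
        cands <- c(cands, "repeat_RNA")
      } else if (cls %in% c("rRNA", "tRNA", "snoRNA", "snRNA", "scRNA",
                            "non_hairpin_region")) {
        cands <- c(cands, cls)
      }
    }
    for (gidx in seq_len(nrow(genes))) {
      gn <- genes[gidx, ]
      if (gn$chrom != a$chrom) next
      ex <- gn$exons[[1]]
      for (e in seq_len(nrow(ex))) {
        ov <- min(a$end, ex$end[e]) - max(a$start, ex$start[e])
        if (ov > 0 && a$strand != gn$strand) cands <- c(cands, "siRNA")
      }
      ov <- min(a$end, gn$span_end) - max(a$start, gn$span_start)
      if (ov > 0 && a$strand == gn$strand) cands <- c(cands, "sense_RNA")
    }
  }
  if (length(cands) == 0) return("other")
  oracle_priority[min(match(cands, oracle_priority))]
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Every window of each UTR within `max_mismatch` Hamming distance of the
# reverse complement of the miRNA.
oracle_scan_sites <- function(utr_seq, mirna_seq, max_mismatch = 0) {
  target <- oracle_revcomp(mirna_seq)
  k <- nchar(target)
  hits <- list()
  if (nchar(utr_seq) >= k) {
    for (p in 0:(nchar(utr_seq) - k)) {
      win <- substr(utr_seq, p + 1, p + k)
      mm <- oracle_hamming(win, target)
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1]] <- tibble::tibble(
          start = p, end = p + k, mismatch_count = mm, site_seq = win
        )
      }
    }
  }
  if (length(hits)) dplyr::bind_rows(hits) else {
    tibble::tibble(start = integer(), end = integer(),
                   mismatch_count = integer(), site_seq = character())
  }
}

# Distinct siRNA species with a zero-mismatch antisense window on a
# transcript, by per-window Hamming comparison.
oracle_trans_hits <- function(species_seqs, transcript) {
  hits <- 0L
  for (s in species_seqs) {
    rc <- oracle_revcomp(s)
    k <- nchar(rc)
    found <- FALSE
    if (nchar(transcript) >= k) {
      for (p in 0:(nchar(transcript) - k)) {
        if (oracle_hamming(substr(transcript, p + 1, p + k), rc) == 0) {
          found <- TRUE
          break
        }
      }
    }
    hits <- hits + found
  }
  hits
}
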