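# File interfaces: FASTA / GFF3 / BED / TSV writers and readers, flat
# key=value configs, and input validation.

#' Write a toy world to standard-format files
#'
#' Writes `genome.fa` (FASTA), `genes.gff3` (gene/exon/three_prime_UTR
#' features, 1-based closed coordinates), `features.bed` (BED6, 0-based
#' half-open, name = `class|id`), `mirnas.tsv` and `config.txt` (flat
#' key=value) into `dir`.
#'
#' @param world A `toy_world`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.gff3"),
    features = file.path(dir, "features.bed"),
    mirnas = file.path(dir, "mirnas.tsv"),
    config = file.path(dir, "config.txt")
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(world$genome),
                              paths[["genome"]])
  write_genes_gff3(world$genes, paths[["genes"]])
  write_features_bed(world$annotations, paths[["features"]])
  readr::write_tsv(
    world$mirnas |> select(-dplyr::any_of("exons")),
    paths[["mirnas"]]
  )
  write_flat_config(world$config, paths[["config"]])
  invisible(paths)
}

write_genes_gff3 <- function(genes, path) {
  if (nrow(genes) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    rows[[length(rows) + 1]] <- tibble(
      chrom = g$chrom, start = g$span_start, end = g$span_end,
      strand = g$strand, type = "gene", id = g$gene_id,
      parent = NA_character_,
      extra = sprintf("role=%s;rde1_dependent=%s", g$role,
                      tolower(g$rde1_dependent))
    )
    ex <- g$exons[[1]]
    rows[[length(rows) + 1]] <- tibble(
      chrom = g$chrom, start = ex$start, end = ex$end, strand = g$strand,
      type = "exon", id = sprintf("%s.exon%d", g$gene_id, seq_len(nrow(ex))),
      parent = g$gene_id, extra = NA_character_
    )
    rows[[length(rows) + 1]] <- tibble(
      chrom = g$chrom, start = g$utr3_start, end = g$utr3_end,
      strand = g$strand, type = "three_prime_UTR",
      id = paste0(g$gene_id, ".utr3"), parent = g$gene_id,
      extra = NA_character_
    )
  }
  df <- bind_rows(rows)
  attrs <- paste0(
    "ID=", df$id,
    ifelse(is.na(df$parent), "", paste0(";Parent=", df$parent)),
    ifelse(is.na(df$extra), "", paste0(";", df$extra))
  )
  lines <- sprintf("%s\tagoscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   df$chrom, df$type, df$start + 1L, df$end, df$strand,
                   attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

write_features_bed <- function(annotations, path) {
  feats <- annotations |> filter(.data$feature_class != "coding_gene")
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s", feats$chrom, feats$start,
                   feats$end, paste0(feats$feature_class, "|", feats$id),
                   feats$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read back world files
#'
#' Counterpart of [write_world()]: reads the FASTA genome, the GFF3 gene
#' models (re-deriving spliced transcripts from the genome), the BED6
#' feature annotations and the miRNA table.
#'
#' @param dir Directory written by [write_world()].
#' @return A list with `genome`, `annotations`, `genes`, `mirnas`,
#'   `config`.
#' @export
read_world <- function(dir) {
  genome_set <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  genome <- setNames(as.character(genome_set), names(genome_set))
  gff <- rtracklayer::import(file.path(dir, "genes.gff3"), format = "gff3")
  genes <- gff_to_gene_models(gff, genome)
  bed <- rtracklayer::import(file.path(dir, "features.bed"), format = "bed")
  nm <- stringr::str_split_fixed(bed$name, stringr::fixed("|"), 2)
  annotations <- tibble(
    chrom = as.character(GenomicRanges::seqnames(bed)),
    start = GenomicRanges::start(bed) - 1L,
    end = GenomicRanges::end(bed),
    strand = as.character(GenomicRanges::strand(bed)),
    feature_class = nm[, 1], id = nm[, 2]
  ) |>
    bind_rows(
      genes |>
        dplyr::transmute(
          chrom = .data$chrom, start = .data$span_start,
          end = .data$span_end, strand = .data$strand,
          feature_class = "coding_gene", id = .data$gene_id
        )
    ) |>
    arrange(.data$start)
  mirnas <- readr::read_tsv(file.path(dir, "mirnas.tsv"),
                            show_col_types = FALSE)
  config <- read_flat_config(file.path(dir, "config.txt"))
  list(genome = genome, annotations = annotations, genes = genes,
       mirnas = mirnas, config = config)
}

gff_to_gene_models <- function(gff, genome) {
  df <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gff)),
    start = GenomicRanges::start(gff) - 1L,
    end = GenomicRanges::end(gff),
    strand = as.character(GenomicRanges::strand(gff)),
    type = as.character(gff$type),
    id = gff$ID,
    parent = vapply(gff$Parent, function(p) {
      if (length(p)) p[[1]] else NA_character_
    }, character(1)),
    role = if ("role" %in% names(S4Vectors::mcols(gff))) gff$role else NA,
    rde1_dependent = if ("rde1_dependent" %in% names(S4Vectors::mcols(gff))) {
      gff$rde1_dependent
    } else {
      NA
    }
  )
  gene_rows <- df |> filter(.data$type == "gene")
  purrr::map_dfr(seq_len(nrow(gene_rows)), function(i) {
    g <- gene_rows[i, ]
    ex <- df |>
      filter(.data$type == "exon", .data$parent == g$id) |>
      arrange(.data$start) |>
      select("start", "end")
    utr <- df |> filter(.data$type == "three_prime_UTR", .data$parent == g$id)
    tx <- spliced_transcript(unname(genome[g$chrom]), ex, g$strand)
    tibble(
      gene_id = g$id, chrom = g$chrom, strand = g$strand,
      span_start = g$start, span_end = g$end, exons = list(ex),
      utr3_start = utr$start[1], utr3_end = utr$end[1],
      transcript = tx, tx_len = nchar(tx),
      utr3_tx_start = nchar(tx) - (utr$end[1] - utr$start[1]),
      utr3_tx_end = nchar(tx),
      rde1_dependent = isTRUE(as.logical(g$rde1_dependent)),
      role = as.character(g$role %||% NA)
    )
  })
}

#' Write a read library to FASTA and TSV
#'
#' Writes `<prefix>.fa` (count-annotated headers), `<prefix>.tsv`
#' (sequence, count) and `<prefix>.meta.tsv` (5' chemistry and
#' generator-side source labels, for test oracles).
#'
#' @param reads Library tibble from [simulate_library()].
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of file paths.
#' @export
write_library <- function(reads, prefix) {
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  paths <- c(fa = paste0(prefix, ".fa"), tsv = paste0(prefix, ".tsv"),
             meta = paste0(prefix, ".meta.tsv"))
  headers <- sprintf(">read%06d count=%d five_prime=%s source=%s",
                     seq_len(nrow(reads)), reads$count, reads$five_prime,
                     reads$true_source)
  writeLines(as.vector(rbind(headers, reads$seq)), paths[["fa"]])
  readr::write_tsv(reads |> select("seq", "count"), paths[["tsv"]])
  readr::write_tsv(reads |> select("seq", "five_prime", "true_source"),
                   paths[["meta"]])
  invisible(paths)
}

#' Read a library written by [write_library()]
#'
#' @param prefix Path prefix used when writing.
#' @return The library tibble (`seq`, `count`, `five_prime`,
#'   `true_source`).
#' @export
read_library <- function(prefix) {
  reads <- readr::read_tsv(paste0(prefix, ".tsv"), show_col_types = FALSE,
                           col_types = "ci")
  meta_path <- paste0(prefix, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                            col_types = "ccc")
    reads <- reads |> left_join(meta, by = "seq", multiple = "first")
  }
  reads
}

write_flat_config <- function(config, path) {
  fmt <- function(v) {
    if (!is.null(names(v)) && length(names(v)) == length(v)) {
      paste(sprintf("%s:%s", names(v), as.character(v)), collapse = ",")
    } else {
      paste(as.character(v), collapse = ",")
    }
  }
  keys <- setdiff(names(config), character())
  writeLines(sprintf("%s=%s", keys,
                     vapply(config[keys], fmt, character(1))), path)
  invisible(path)
}

read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- stringr::str_split_fixed(lines, stringr::fixed("="), 2)
  parse_val <- function(s) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    if (all(grepl(":", parts, fixed = TRUE))) {
      sub <- stringr::str_split_fixed(parts, stringr::fixed(":"), 2)
      v <- suppressWarnings(as.numeric(sub[, 2]))
      if (any(is.na(v))) v <- sub[, 2]
      return(setNames(v, sub[, 1]))
    }
    v <- suppressWarnings(as.numeric(parts))
    if (any(is.na(v))) parts else v
  }
  vals <- lapply(kv[, 2], parse_val)
  names(vals) <- kv[, 1]
  defaults <- sim_config()
  known <- intersect(names(vals), names(defaults))
  do.call(sim_config, vals[intersect(known, names(formals(sim_config)))])
}

#' Validate pipeline input files
#'
#' Checks FASTA / GFF3 / BED / read-TSV well-formedness: readable files,
#' DNA alphabet, coordinates within chromosome bounds, non-negative
#' integer counts. Problems are reported as rows, with fatal errors
#' distinguished from warnings; a clean input set yields zero rows.
#'
#' @param genome_fa Path to the genome FASTA.
#' @param gff3,bed,reads_tsv Optional paths to annotation and read
#'   files.
#' @return Tibble of diagnostics: `severity` (`"fatal"`/`"warning"`),
#'   `file`, `message`.
#' @export
validate_inputs <- function(genome_fa, gff3 = NULL, bed = NULL,
                            reads_tsv = NULL) {
  diags <- list()
  note <- function(severity, file, message) {
    diags[[length(diags) + 1]] <<- tibble(severity = severity,
                                          file = basename(file),
                                          message = message)
  }
  chrom_len <- NULL
  if (!file.exists(genome_fa)) {
    note("fatal", genome_fa, "genome FASTA not found")
  } else {
    genome <- tryCatch(
      Biostrings::readDNAStringSet(genome_fa),
      error = function(e) NULL
    )
    if (is.null(genome)) {
      note("fatal", genome_fa, "unreadable FASTA")
    } else {
      chrom_len <- setNames(Biostrings::width(genome),
                            sub("\\s.*$", "", names(genome)))
      freqs <- Biostrings::alphabetFrequency(genome)
      nonacgt <- sum(freqs) - sum(freqs[, c("A", "C", "G", "T")])
      if (nonacgt > 0) {
        note("warning", genome_fa,
             sprintf("%d non-ACGT characters in genome", nonacgt))
      }
    }
  }
  check_ranges <- function(path, chrom, start0, end0, ids) {
    unknown <- !chrom %in% names(chrom_len)
    for (i in which(unknown)) {
      note("fatal", path, sprintf("%s: unknown chromosome %s", ids[i], chrom[i]))
    }
    for (i in which(!unknown)) {
      if (start0[i] < 0 || end0[i] > chrom_len[[chrom[i]]] ||
          start0[i] >= end0[i]) {
        note("fatal", path,
             sprintf("%s: interval [%d, %d) outside %s (length %d)",
                     ids[i], start0[i], end0[i], chrom[i],
                     chrom_len[[chrom[i]]]))
      }
    }
  }
  if (!is.null(gff3)) {
    if (!file.exists(gff3)) {
      note("fatal", gff3, "GFF3 not found")
    } else if (!is.null(chrom_len)) {
      gff <- tryCatch(rtracklayer::import(gff3, format = "gff3"),
                      error = function(e) NULL)
      if (is.null(gff)) {
        note("fatal", gff3, "unparseable GFF3")
      } else {
        check_ranges(gff3, as.character(GenomicRanges::seqnames(gff)),
                     GenomicRanges::start(gff) - 1L,
                     GenomicRanges::end(gff),
                     gff$ID %||% as.character(seq_along(gff)))
      }
    }
  }
  if (!is.null(bed)) {
    if (!file.exists(bed)) {
      note("fatal", bed, "BED not found")
    } else if (!is.null(chrom_len)) {
      b <- tryCatch(rtracklayer::import(bed, format = "bed"),
                    error = function(e) NULL)
      if (is.null(b)) {
        note("fatal", bed, "unparseable BED")
      } else {
        check_ranges(bed, as.character(GenomicRanges::seqnames(b)),
                     GenomicRanges::start(b) - 1L, GenomicRanges::end(b),
                     b$name %||% as.character(seq_along(b)))
      }
    }
  }
  if (!is.null(reads_tsv)) {
    if (!file.exists(reads_tsv)) {
      note("fatal", reads_tsv, "read TSV not found")
    } else {
      rd <- tryCatch(
        readr::read_tsv(reads_tsv, show_col_types = FALSE),
        error = function(e) NULL
      )
      if (is.null(rd) || !all(c("seq", "count") %in% names(rd))) {
        note("fatal", reads_tsv, "read TSV needs `seq` and `count` columns")
      } else {
        if (any(is.na(rd$count)) || any(rd$count < 0) ||
            any(rd$count != floor(rd$count))) {
          note("fatal", reads_tsv, "read counts must be non-negative integers")
        }
        if (any(grepl("[^ACGT]", rd$seq))) {
          note("fatal", reads_tsv, "read sequences contain non-ACGT characters")
        }
      }
    }
  }
  if (length(diags)) bind_rows(diags) else
    tibble(severity = character(), file = character(), message = character())
}
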