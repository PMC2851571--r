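# End-to-end pipeline: simulate -> annotate -> compare -> signature ->
# target scan, with a machine-readable run manifest.

#' Default library panel for a pipeline run
#'
#' The panel mirrors the two experimental designs the analysis chain
#' needs: Argonaute IP libraries (ALG-1, ALG-2, RDE-1; cloning chemistry
#' preserving 5'-triphosphate reads, modelled as TAP-treated) and total
#' RNA libraries for a genotype series, including the matched wild-type
#' TAP+/TAP- pair used for triphosphate-dependence calls.
#'
#' @param depth Total-RNA library depth (default 100,000 reads).
#' @param ip_depth IP library depth (default 10,000 reads; the IP
#'   libraries came from a lower-throughput sequencing effort).
#' @param genotypes Character vector of single null alleles for the
#'   total-RNA genotype series (besides wild type).
#' @param seeds Optional integer seeds, one per library.
#' @return Tibble with a `spec` list-column of [library_spec()]s.
#' @export
default_library_panel <- function(depth = 100000L, ip_depth = 10000L,
                                  genotypes = c("rde-1", "mir-243", "rrf-1",
                                                "MAGO", "alg-1"),
                                  seeds = NULL) {
  labels <- c("ALG-1_IP", "ALG-2_IP", "RDE-1_IP", "N2_TAP", "N2_noTAP",
              paste0(gsub("-", "", genotypes), "_TAP"))
  n <- length(labels)
  seeds <- seeds %||% seq_len(n)
  specs <- c(
    list(
      library_spec("ALG-1_IP", ip_target = "ALG-1", depth = ip_depth,
                   seed = seeds[1]),
      library_spec("ALG-2_IP", ip_target = "ALG-2", depth = ip_depth,
                   seed = seeds[2]),
      library_spec("RDE-1_IP", ip_target = "RDE-1", depth = ip_depth,
                   seed = seeds[3]),
      library_spec("N2_TAP", depth = depth, seed = seeds[4]),
      library_spec("N2_noTAP", tap_treated = FALSE, depth = depth,
                   seed = seeds[5])
    ),
    purrr::map(seq_along(genotypes), function(i) {
      library_spec(paste0(gsub("-", "", genotypes[i]), "_TAP"),
                   geno = genotype(genotypes[i]), depth = depth,
                   seed = seeds[5 + i])
    })
  )
  tibble(label = labels, spec = specs)
}

#' Run the full analysis pipeline
#'
#' Builds the synthetic world, simulates the library panel, annotates
#' every library into the twelve read categories, computes the IP
#' (RDE-1 vs ALG-1 miRNA) and genotype (mutant vs wild-type miRNA and
#' per-locus siRNA) log2 comparisons, scores depleted loci for the four
#' secondary siRNA signatures, scans 3'UTRs for perfectly complementary
#' sites of RDE-1-enriched miRNAs, runs the trans-action hit analysis,
#' and writes every table plus a run manifest under `out_dir`. The
#' summary names the loci satisfying the full evidence chain: depleted
#' in both the scavenger-Argonaute and the trigger-miRNA mutants,
#' secondary-like by signature, and carrying a perfect site for an
#' RDE-1-enriched miRNA.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param seed Master seed; per-library seeds are derived from it.
#' @param panel Library panel (default [default_library_panel()]).
#' @param depth,ip_depth Depths forwarded to the default panel.
#' @return An object of class `agoscan_run` (invisibly a list of all
#'   result tables plus the manifest).
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = config$seed,
                         panel = NULL, depth = 100000L, ip_depth = 10000L) {
  t0 <- Sys.time()
  log_path <- file.path(out_dir, "run.log")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"), msg),
        file = log_path, append = TRUE)
    message(msg)
  }
  stage <- function(name, expr) {
    st <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      logf("stage %s FAILED: %s", name, conditionMessage(e))
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    logf("stage %s done (%.1fs)", name,
         as.numeric(difftime(Sys.time(), st, units = "secs")))
    res
  }

  config$seed <- as.integer(seed)
  lib_seeds <- withr::with_seed(config$seed,
                                sample.int(.Machine$integer.max - 1L, 64L))
  panel <- panel %||% default_library_panel(depth = depth,
                                            ip_depth = ip_depth,
                                            seeds = lib_seeds)
  if (nrow(panel) == 0) abort("Configuration requests zero libraries.")
  for (sub in c("world", "libraries", "calls")) {
    dir.create(file.path(out_dir, sub), showWarnings = FALSE,
               recursive = TRUE)
  }

  world <- stage("simulate-world", build_toy_genome(config))
  world_paths <- write_world(world, file.path(out_dir, "world"))
  index <- build_index(world)

  libs <- stage("simulate-libraries", {
    purrr::map(panel$spec, simulate_library, world = world, config = config)
  })
  names(libs) <- panel$label

  calls <- stage("annotate", {
    purrr::imap(libs, function(reads, label) {
      out <- annotate_library(reads, world, index)
      write_library(reads, file.path(out_dir, "libraries", label))
      readr::write_tsv(
        out |> select(dplyr::any_of(c("seq", "count", "category", "chrom",
                                      "start", "end", "strand", "locus_id",
                                      "n_hits", "mapped"))),
        file.path(out_dir, "calls", paste0(label, ".calls.tsv"))
      )
      out
    })
  })

  compositions <- stage("composition", {
    comp <- purrr::imap(calls, function(x, label) {
      summarize_library(x) |> mutate(library = label, .before = 1)
    })
    tab <- bind_rows(comp)
    readr::write_tsv(tab, file.path(out_dir, "composition.tsv"))
    tab
  })

  # --- species-level miRNA counts per library -------------------------
  mirna_counts <- function(label) {
    calls[[label]] |>
      filter(.data$category == "known_microRNA") |>
      inner_join(world$mirnas |> select("mirna_id", species_seq = "mature"),
                 by = c(seq = "species_seq")) |>
      group_by(species = .data$mirna_id) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      tidyr::complete(species = world$mirnas$mirna_id,
                      fill = list(count = 0))
  }

  lib_total <- function(label) sum(calls[[label]]$count)
  scale_species <- function(counts, label) {
    scale_library(counts, library_total = lib_total(label))
  }
  enrich_ip <- stage("compare-ip", {
    rec <- log2_enrichment(
      scale_species(mirna_counts("RDE-1_IP"), "RDE-1_IP"),
      scale_species(mirna_counts("ALG-1_IP"), "ALG-1_IP")
    )
    readr::write_tsv(rec, file.path(out_dir, "mirna_rde1_vs_alg1.tsv"))
    rec
  })

  genotype_labels <- setdiff(panel$label,
                             c("ALG-1_IP", "ALG-2_IP", "RDE-1_IP",
                               "N2_TAP", "N2_noTAP"))
  comparisons <- stage("compare-genotypes", {
    n2_mir <- scale_species(mirna_counts("N2_TAP"), "N2_TAP")
    n2_loc <- scale_species(
      per_locus_sirna_counts(calls[["N2_TAP"]], world$genes), "N2_TAP"
    )
    purrr::map(setNames(genotype_labels, genotype_labels), function(lb) {
      mir <- log2_enrichment(scale_species(mirna_counts(lb), lb), n2_mir)
      loc <- log2_enrichment(
        scale_species(per_locus_sirna_counts(calls[[lb]], world$genes), lb),
        n2_loc
      )
      readr::write_tsv(mir, file.path(out_dir,
                                      paste0("mirna_", lb, "_vs_N2.tsv")))
      readr::write_tsv(loc, file.path(out_dir,
                                      paste0("sirna_loci_", lb, "_vs_N2.tsv")))
      list(mirna = mir, loci = loc)
    })
  })

  depleted <- stage("call-depleted", {
    dep <- call_depleted_loci(comparisons[["rde1_TAP"]]$loci)
    readr::write_tsv(dep, file.path(out_dir, "depleted_loci.tsv"))
    dep
  })

  signatures <- stage("signature", {
    total_tap <- sum(calls[["N2_TAP"]]$count)
    total_notap <- sum(calls[["N2_noTAP"]]$count)
    cand <- union(depleted$species, world$target_gene_id)
    cand <- cand[!is.na(cand)]
    sig <- purrr::map_dfr(cand, function(gid) {
      gene <- world$genes[world$genes$gene_id == gid, ]
      reads <- locus_reads_from_calls(calls[["N2_TAP"]], gene, world)
      no_tap_reads <- locus_reads_from_calls(calls[["N2_noTAP"]], gene, world)
      scale_to <- 100000
      trig_pos <- if (!is.null(world$trigger_site) &&
                        gid %in% world$trigger_site$gene_id) {
        world$trigger_site$tx_start[world$trigger_site$gene_id == gid]
      } else {
        NA_integer_
      }
      locus_signature(
        reads, gene, world$genome,
        count_tap = sum(reads$count) * scale_to / total_tap,
        count_no_tap = sum(no_tap_reads$count) * scale_to / total_notap,
        trigger_tx_start = trig_pos
      )
    })
    readr::write_tsv(sig, file.path(out_dir, "locus_signatures.tsv"))
    sig
  })

  sites <- stage("target-scan", {
    enriched <- enrich_ip |> filter(.data$log2_ratio > 1)
    mir <- world$mirnas |> filter(.data$mirna_id %in% enriched$species)
    utrs <- world$genes |>
      dplyr::transmute(
        transcript_id = .data$gene_id,
        seq = substr0(.data$transcript, .data$utr3_tx_start,
                      .data$utr3_tx_end)
      )
    st <- scan_sites(utrs, mir, max_mismatch = 0)
    readr::write_tsv(st, file.path(out_dir, "target_sites.tsv"))
    st
  })

  trans_hits <- stage("trans-hits", {
    sec <- signatures |> filter(.data$verdict == "secondary-like")
    if (nrow(sec) == 0) {
      th <- tibble(transcript_id = character(), unique_hits = integer(),
                   multi_hits = integer(), total_hits = integer(),
                   flagged_for_decay = logical())
    } else {
      gid <- sec$locus_id[1]
      gene <- world$genes[world$genes$gene_id == gid, ]
      reads <- locus_reads_from_calls(calls[["N2_TAP"]], gene, world) |>
        left_join(
          calls[["N2_TAP"]] |> select("seq", "n_hits") |> distinct(),
          by = "seq"
        ) |>
        mutate(n_hits = dplyr::coalesce(.data$n_hits, 1L))
      th <- trans_hit_analysis(
        reads,
        world$genes |> select(transcript_id = "gene_id", seq = "transcript")
      )
    }
    readr::write_tsv(th, file.path(out_dir, "trans_hits.tsv"))
    th
  })

  summary <- stage("summarize", {
    dep_in <- function(lb) {
      call_depleted_loci(comparisons[[lb]]$loci)$species
    }
    chain <- Reduce(intersect, list(
      dep_in("rde1_TAP"), dep_in("mir243_TAP"),
      signatures$locus_id[signatures$verdict == "secondary-like"],
      sites$transcript_id[sites$mismatch_count == 0]
    ))
    reduced_under <- function(lb, loci) {
      rec <- comparisons[[lb]]$loci |> filter(.data$species %in% loci)
      setNames(rec$log2_ratio, rec$species)
    }
    s <- list(
      evidence_chain_loci = chain,
      depleted_rde1 = dep_in("rde1_TAP"),
      depleted_mir243 = dep_in("mir243_TAP"),
      secondary_like = signatures$locus_id[
        signatures$verdict == "secondary-like"
      ],
      perfect_site_loci = unique(sites$transcript_id[
        sites$mismatch_count == 0
      ]),
      log2_vs_N2_rrf1 = as.list(reduced_under("rrf1_TAP", chain)),
      log2_vs_N2_MAGO = as.list(reduced_under("MAGO_TAP", chain)),
      log2_vs_N2_alg1 = as.list(reduced_under("alg1_TAP", chain))
    )
    jsonlite::write_json(s, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    s
  })

  manifest <- list(
    tool = "agoscan",
    seed = config$seed,
    config = unclass(config),
    libraries = purrr::map(panel$spec, function(sp) {
      list(label = sp$label, genotype = genotype_label(sp$genotype),
           ip_target = sp$ip_target, tap_treated = sp$tap_treated,
           depth = sp$depth, seed = sp$seed)
    }),
    outputs = local({
      files <- sort(setdiff(
        list.files(out_dir, recursive = TRUE),
        c("run.log", "manifest.json")
      ))
      digests <- unname(tools::md5sum(file.path(out_dir, files)))
      purrr::map2(files, digests, function(f, d) list(file = f, md5 = d))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  logf("pipeline complete in %.1fs",
       as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(
    list(world = world, libraries = libs, calls = calls,
         compositions = compositions, enrich_ip = enrich_ip,
         comparisons = comparisons, depleted = depleted,
         signatures = signatures, sites = sites, trans_hits = trans_hits,
         summary = summary, manifest = manifest, out_dir = out_dir),
    class = "agoscan_run"
  )
}

# Reads attributable to a locus in one annotated library: siRNA-called
# unique mappers on the locus plus unmapped reads matching the locus's
# spliced transcript (junction-spanning secondary siRNAs).
locus_reads_from_calls <- function(calls, gene, world) {
  on_locus <- calls |>
    filter(.data$category == "siRNA", .data$n_hits == 1L,
           .data$locus_id == gene$gene_id)
  un <- calls |> filter(!.data$mapped)
  if (nrow(un)) {
    rc <- reverse_complement(un$seq)
    keep <- vapply(rc, function(p) {
      regexpr(p, gene$transcript, fixed = TRUE)[1] > 0
    }, logical(1))
    un <- un[keep, ]
  }
  bind_rows(on_locus, un) |> select("seq", "count")
}

#' @export
print.agoscan_run <- function(x, ...) {
  cat("<agoscan_run>\n")
  cat(sprintf("  %d libraries, %d depleted loci, %d secondary-like, %d perfect sites\n",
              length(x$libraries), nrow(x$depleted),
              sum(x$signatures$verdict == "secondary-like"),
              sum(x$sites$mismatch_count == 0)))
  cat(sprintf("  evidence-chain loci: %s\n",
              paste(x$summary$evidence_chain_loci, collapse = ", ")))
  cat(sprintf("  outputs: %s\n", x$out_dir))
  invisible(x)
}

#' Tidy the per-locus results of a pipeline run
#'
#' @param x An `agoscan_run`.
#' @param ... Unused.
#' @return The locus signature table with the rde-1-versus-wild-type
#'   log2 ratio joined on.
#' @export
tidy.agoscan_run <- function(x, ...) {
  as_tibble(x$signatures) |>
    left_join(
      x$comparisons[["rde1_TAP"]]$loci |>
        select(locus_id = "species", log2_rde1_vs_N2 = "log2_ratio"),
      by = "locus_id"
    )
}

#' One-row summary of a pipeline run
#'
#' @inheritParams tidy.agoscan_run
#' @export
glance.agoscan_run <- function(x, ...) {
  tibble(
    n_libraries = length(x$libraries),
    n_loci = nrow(x$world$genes),
    n_depleted_rde1 = nrow(x$depleted),
    n_secondary_like = sum(x$signatures$verdict == "secondary-like"),
    n_perfect_sites = sum(x$sites$mismatch_count == 0),
    evidence_chain = paste(x$summary$evidence_chain_loci, collapse = ";")
  )
}
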