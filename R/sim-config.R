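# Simulation configuration and genotype model.

#' Configuration for the synthetic small RNA world
#'
#' Bundles every tunable of the synthetic-data generator: the toy genome
#' layout, Argonaute loading weights, the cellular small RNA pool
#' composition, per-locus secondary siRNA production rates, genotype effect
#' sizes, and the 3' coverage gradient shape.
#'
#' @param genome_size Chromosome length in bases (single toy chromosome).
#' @param chrom_name Chromosome name used in all coordinates and files.
#' @param n_sirna_loci Number of coding genes that produce endogenous
#'   secondary siRNAs. The first `n_rde1_dependent` of them require the
#'   miRNA trigger pathway (RDE-1/miR-243 analog); the rest are
#'   constitutive endo-siRNA loci unaffected by that pathway.
#' @param n_rde1_dependent Number of trigger-dependent siRNA loci (the
#'   first is the perfectly matched miRNA target carrying the planted
#'   3'UTR site; the second stands in for a second strongly affected
#'   locus).
#' @param n_mirna Number of miRNA hairpins. The first hairpin is the
#'   trigger miRNA with a perfectly paired (0-mismatch) precursor stem;
#'   the others carry 1-3 stem mismatches.
#' @param n_p21u,n_scrna,n_snrna,n_snorna,n_trna,n_rrna Numbers of 21U-RNA
#'   loci and structural RNA genes.
#' @param n_repeat_families,repeat_copies Repeat families and identical
#'   copies per family (copies make repeat-derived reads multi-map).
#' @param n_non_hairpin Number of annotated non-hairpin regions.
#' @param w0 Probability that a 0-mismatch precursor stem loads RDE-1.
#' @param w_mm Probability that a >=1-mismatch precursor loads RDE-1.
#' @param alg_purity miRNA purity of ALG-1/ALG-2 immunoprecipitates.
#' @param scavenger_background Per-class read mixture of the RDE-1
#'   immunoprecipitate (named numeric summing to 1; 21U-RNAs get weight 0).
#' @param pool_fractions Expected class fractions of the total cellular
#'   small RNA pool, excluding the siRNA class (which is determined by
#'   `sirna_base_rate` times the number of active loci).
#' @param sirna_base_rate Expected fraction of a total library contributed
#'   by one active siRNA locus in wild type.
#' @param genotype_factors Multiplicative effects of non-null genotypes on
#'   trigger-dependent siRNA production (`rrf-1`, `MAGO`, `alg-1`);
#'   `rde-1` and `mir-243` null alleles abolish production entirely.
#' @param gradient_lambda Shape of the 3' coverage bias: secondary read
#'   start positions are sampled with weight `exp(lambda * x)` where `x`
#'   is the fractional position along the spliced transcript (0 = 5' end).
#' @param read_length Secondary siRNA (and background window) read length.
#' @param mature_length Mature miRNA length.
#' @param seed Integer seed controlling world construction.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_size = 60000L,
                       chrom_name = "chrT",
                       n_sirna_loci = 50L,
                       n_rde1_dependent = 2L,
                       n_mirna = 20L,
                       n_p21u = 30L,
                       n_scrna = 3L,
                       n_snrna = 4L,
                       n_snorna = 6L,
                       n_trna = 8L,
                       n_rrna = 2L,
                       n_repeat_families = 4L,
                       repeat_copies = 2L,
                       n_non_hairpin = 5L,
                       w0 = 0.8,
                       w_mm = 0.1,
                       alg_purity = 0.95,
                       scavenger_background = c(
                         known_microRNA = 0.60, repeat_RNA = 0.15,
                         siRNA = 0.10, sense_RNA = 0.05, other_classes = 0.10
                       ),
                       pool_fractions = c(
                         known_microRNA = 0.40, p21U_RNA = 0.10,
                         tRNA = 0.05, rRNA = 0.05, snoRNA = 0.04,
                         snRNA = 0.03, scRNA = 0.02, repeat_RNA = 0.06,
                         non_hairpin_region = 0.02, sense_RNA = 0.01,
                         other = 0.02
                       ),
                       sirna_base_rate = 0.004,
                       genotype_factors = c(
                         `rrf-1` = 0.05, MAGO = 0.1, `alg-1` = 1.2
                       ),
                       gradient_lambda = 2,
                       read_length = 22L,
                       mature_length = 22L,
                       seed = 101L) {
  cfg <- list(
    genome_size = as.integer(genome_size),
    chrom_name = chrom_name,
    n_sirna_loci = as.integer(n_sirna_loci),
    n_rde1_dependent = as.integer(n_rde1_dependent),
    n_mirna = as.integer(n_mirna),
    n_p21u = as.integer(n_p21u),
    n_scrna = as.integer(n_scrna),
    n_snrna = as.integer(n_snrna),
    n_snorna = as.integer(n_snorna),
    n_trna = as.integer(n_trna),
    n_rrna = as.integer(n_rrna),
    n_repeat_families = as.integer(n_repeat_families),
    repeat_copies = as.integer(repeat_copies),
    n_non_hairpin = as.integer(n_non_hairpin),
    w0 = w0,
    w_mm = w_mm,
    alg_purity = alg_purity,
    scavenger_background = scavenger_background,
    pool_fractions = pool_fractions,
    sirna_base_rate = sirna_base_rate,
    genotype_factors = genotype_factors,
    gradient_lambda = gradient_lambda,
    read_length = as.integer(read_length),
    mature_length = as.integer(mature_length),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$w0, cfg$w_mm, cfg$alg_purity, cfg$sirna_base_rate,
             cfg$scavenger_background, cfg$pool_fractions)
  if (any(probs < 0 | probs > 1)) {
    abort("All probabilities/fractions in a sim_config must lie in [0, 1].")
  }
  if (any(cfg$genotype_factors < 0)) {
    abort("Genotype factors must be >= 0.")
  }
  counts <- unlist(cfg[grepl("^n_", names(cfg))])
  if (any(counts < 0)) abort("Feature counts must be non-negative.")
  if (cfg$n_rde1_dependent > cfg$n_sirna_loci) {
    abort("`n_rde1_dependent` cannot exceed `n_sirna_loci`.")
  }
  if (cfg$genome_size < 1L) abort("`genome_size` must be positive.")
  if (cfg$mature_length < 18L || cfg$mature_length > 26L) {
    abort("`mature_length` must lie in [18, 26].")
  }
  needed <- c("known_microRNA", "repeat_RNA", "siRNA", "sense_RNA",
              "other_classes")
  if (!all(needed %in% names(cfg$scavenger_background))) {
    abort("`scavenger_background` must name all five mixture components.")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %s (%d bp), seed %d\n",
              x$chrom_name, x$genome_size, x$seed))
  cat(sprintf(
    "  features: %d siRNA loci (%d trigger-dependent), %d miRNA hairpins, %d 21U loci\n",
    x$n_sirna_loci, x$n_rde1_dependent, x$n_mirna, x$n_p21u
  ))
  cat(sprintf("  loading: w0 = %.2f, w_mm = %.2f; ALG purity %.2f\n",
              x$w0, x$w_mm, x$alg_purity))
  cat(sprintf("  siRNA base rate %.4f / locus; gradient lambda %.1f\n",
              x$sirna_base_rate, x$gradient_lambda))
  invisible(x)
}

#' Construct a genotype (set of null alleles)
#'
#' Wild type is the empty set; known null alleles are `rde-1`, `alg-1`,
#' `mir-243`, `mir-1`, `rrf-1`, `rrf-2`, `rrf-3` and the multi-Argonaute
#' `MAGO` strain.
#'
#' @param alleles Character vector of null alleles (possibly empty).
#' @return Character vector of class `genotype`.
#' @export
genotype <- function(alleles = character()) {
  alleles <- as.character(alleles)
  alleles <- alleles[alleles != "N2"]
  bad <- setdiff(alleles, KNOWN_ALLELES)
  if (length(bad) > 0) {
    abort(sprintf("Unknown allele(s): %s", paste(bad, collapse = ", ")))
  }
  structure(unique(alleles), class = "genotype")
}

genotype_label <- function(g) {
  if (length(g) == 0) "N2" else paste(unclass(g), collapse = ";")
}

#' Genotype factor for trigger-dependent secondary siRNA production
#'
#' Returns the multiplicative factor `g(genotype)` applied to the expected
#' secondary siRNA output of a trigger-dependent locus: 0 for `rde-1` or
#' `mir-243` nulls (production abolished), otherwise the product of the
#' configured factors for `rrf-1`, `MAGO` and `alg-1`; 1 for wild type and
#' for alleles with no modelled effect (`mir-1`, `rrf-2`, `rrf-3`).
#'
#' @param geno A [genotype()] (or character vector of alleles).
#' @param config A [sim_config()].
#' @return A single non-negative number.
#' @export
genotype_factor <- function(geno, config) {
  geno <- genotype(geno)
  if (any(c("rde-1", "mir-243") %in% geno)) {
    return(0)
  }
  f <- 1
  for (allele in intersect(names(config$genotype_factors), geno)) {
    f <- f * config$genotype_factors[[allele]]
  }
  f
}

#' Specification of one simulated sequencing library
#'
#' @param label Library label (used in file names and reports).
#' @param geno A [genotype()]; wild type by default.
#' @param ip_target Immunoprecipitation antibody: `"none"` (total RNA),
#'   `"RDE-1"`, `"ALG-1"` or `"ALG-2"`.
#' @param tap_treated Whether the RNA was treated with tobacco acid
#'   pyrophosphatase before cloning. Untreated libraries cannot clone
#'   5'-triphosphate (RdRP-made) reads.
#' @param depth Total number of reads drawn (before the TAP cloning rule
#'   removes triphosphate reads from untreated libraries).
#' @param seed Integer seed; identical spec + seed gives an identical
#'   library.
#' @return A list of class `library_spec`.
#' @export
library_spec <- function(label,
                         geno = genotype(),
                         ip_target = c("none", "RDE-1", "ALG-1", "ALG-2"),
                         tap_treated = TRUE,
                         depth = 100000L,
                         seed = 1L) {
  ip_target <- match.arg(ip_target)
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0L) abort("`depth` must be a positive integer.")
  structure(
    list(
      label = label, genotype = genotype(geno), ip_target = ip_target,
      tap_treated = isTRUE(tap_treated), depth = depth,
      seed = as.integer(seed)
    ),
    class = "library_spec"
  )
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf(
    "<library_spec> %s: genotype %s, IP %s, TAP %s, depth %d, seed %d\n",
    x$label, genotype_label(x$genotype), x$ip_target,
    if (x$tap_treated) "+" else "-", x$depth, x$seed
  ))
  invisible(x)
}
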