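# Shared simulation worlds, memoised so test files can reuse them.

.world_cache <- new.env(parent = emptyenv())

# Reduced-scale world for unit tests: same structure as the default
# conditions, fewer loci.
tiny_config <- function(seed = 7, ...) {
  sim_config(
    genome_size = 20000, n_sirna_loci = 8, n_rde1_dependent = 2,
    n_mirna = 6, n_p21u = 6, n_scrna = 1, n_snrna = 2, n_snorna = 2,
    n_trna = 3, n_rrna = 1, n_repeat_families = 2, n_non_hairpin = 2,
    seed = seed, ...
  )
}

# Minimal annotated world fitting in a 2 kb genome (one siRNA-capable
# gene plus its paralog, one hairpin, one 21U locus, one tRNA).
micro_config <- function(seed = 11) {
  sim_config(
    genome_size = 2000, n_sirna_loci = 1, n_rde1_dependent = 1,
    n_mirna = 1, n_p21u = 1, n_scrna = 0, n_snrna = 0, n_snorna = 0,
    n_trna = 1, n_rrna = 0, n_repeat_families = 0, n_non_hairpin = 0,
    seed = seed
  )
}

cached_world <- function(key, config) {
  if (!exists(key, envir = .world_cache)) {
    assign(key, build_toy_genome(config), envir = .world_cache)
  }
  get(key, envir = .world_cache)
}

tiny_world <- function() cached_world("tiny", tiny_config())
default_world <- function() cached_world("default", sim_config())

cached_index <- function(key, world) {
  ikey <- paste0(key, "_index")
  if (!exists(ikey, envir = .world_cache)) {
    assign(ikey, build_index(world), envir = .world_cache)
  }
  get(ikey, envir = .world_cache)
}

tiny_index <- function() cached_index("tiny", tiny_world())
default_index <- function() cached_index("default", default_world())

# Random read set: half sampled from genome windows (either strand),
# half random sequences (mostly unmappable).
random_reads <- function(world, n = 500, seed = 1) {
  withr::with_seed(seed, {
    g <- unname(world$genome[1])
    L <- nchar(g)
    w <- sample(15:30, n, replace = TRUE)
    from_genome <- seq_len(n) <= n / 2
    seqs <- character(n)
    for (i in seq_len(n)) {
      if (from_genome[i]) {
        s0 <- sample.int(L - w[i] + 1L, 1) - 1L
        s <- substr(g, s0 + 1L, s0 + w[i])
        if (runif(1) < 0.5) s <- reverse_complement(s)
        seqs[i] <- s
      } else {
        seqs[i] <- paste(sample(c("A", "C", "G", "T"), w[i],
                                replace = TRUE), collapse = "")
      }
    }
    unique(seqs)
  })
}
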