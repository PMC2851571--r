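# Shared low-level helpers: sequence utilities and validation.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Reverse complement of nucleotide sequences
#'
#' Standard Watson-Crick reverse complement. `U` is treated as `T`, so
#' RNA-alphabet inputs (e.g. northern probe sequences) are handled
#' transparently; the result is always in DNA alphabet.
#'
#' @param x Character vector of sequences over `{A,C,G,T,U}` (case
#'   insensitive).
#' @return Character vector of reverse-complemented sequences, upper case.
#' @examples
#' reverse_complement("ATATCCCGCCGCGATCGTACCG")
#' @export
reverse_complement <- function(x) {
  if (!is.character(x)) {
    abort("`x` must be a character vector of nucleotide sequences.")
  }
  x <- toupper(x)
  bad <- grepl("[^ACGTU]", x)
  if (any(bad)) {
    abort(sprintf(
      "Sequences contain characters outside {A,C,G,T,U}: e.g. %s",
      substr(x[bad][1], 1, 30)
    ))
  }
  x <- chartr("U", "T", x)
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

# Hamming distance between two equal-length strings.
hamming_distance <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Random DNA string(s).
random_dna <- function(n_chars) {
  paste(sample(DNA_ALPHABET, n_chars, replace = TRUE), collapse = "")
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf(
      "%s contains characters outside {A,C,G,T}: e.g. %s",
      what, substr(x[bad][1], 1, 30)
    ))
  }
  invisible(x)
}

# Substring with 0-based half-open coordinates.
substr0 <- function(x, start0, end0) {
  substr(x, start0 + 1L, end0)
}

# The twelve read categories, in classification priority order (highest
# first). Specific, well-defined annotations outrank broad ones; structural
# RNA classes claim their (likely degradation-product) reads before the
# genic siRNA/sense categories.
CATEGORY_PRIORITY <- c(
  "known_microRNA", "p21U_RNA", "rRNA", "tRNA", "snoRNA", "snRNA",
  "scRNA", "repeat_RNA", "siRNA", "sense_RNA", "non_hairpin_region", "other"
)

# Feature classes allowed in annotation tables.
FEATURE_CLASSES <- c(
  "coding_gene", "mirna_hairpin", "p21u_locus", "scRNA", "snRNA", "snoRNA",
  "tRNA", "rRNA", "repeat", "non_hairpin_region"
)

# Null alleles understood by the genotype model.
KNOWN_ALLELES <- c(
  "rde-1", "alg-1", "mir-243", "mir-1", "rrf-1", "rrf-2", "rrf-3", "MAGO"
)
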