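---
title: "Methods: simulating and detecting miRNA-triggered secondary siRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and detecting miRNA-triggered secondary siRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agoscan)
```

# The biological model

In *C. elegans*, small RNA silencing runs through two Argonaute tiers.
Dicer products (miRNAs and other ~22-nt duplex-derived RNAs) carry a 5'
monophosphate and load a primary Argonaute; which one depends on the
structure of the precursor duplex. Precursors whose stems pair with one
to three mismatches are handled as miRNAs by ALG-1/ALG-2, while
perfectly paired stems preferentially load the scavenger Argonaute
RDE-1. When an RDE-1-bound guide finds a perfectly complementary site on
an mRNA — the configuration normally produced only by exogenous dsRNA —
an RNA-dependent RNA polymerase (RRF-1 in the soma) is recruited to the
target and synthesizes secondary siRNAs directly, without Dicer. Those
secondary siRNAs are diagnosable by four signatures:

1. **polarity** — they are strictly antisense to the template mRNA;
2. **5' chemistry** — as direct polymerase products they carry a 5'
   triphosphate, so ligation-based cloning only captures them after
   tobacco acid pyrophosphatase (TAP) treatment;
3. **exon restriction** — the template is the spliced transcript, so the
   reads stay within exons and some span exon–exon junctions (such reads
   have no exact genomic match);
4. **3' coverage bias** — polymerase recruitment at the 3' end yields
   coverage that declines toward the 5' end.

`agoscan` implements this entire chain as testable code: a seeded
generator that realizes the model on a toy genome, and an analysis side
(read classification, library comparison, signature scoring, target
scanning) that must re-discover what the generator planted, without
access to the generator's labels.

# The synthetic world

`build_toy_genome()` lays out non-overlapping features on a single
random chromosome (60 kb by default): 50 coding genes with a fixed
3-exon structure (exons of 150/130/160 nt, 60-nt introns, a 90-nt 3'UTR
in the terminal exon), one additional paralog gene, 20 miRNA hairpins,
30 21U-RNA loci, structural RNA genes (tRNA, rRNA, sn/sno/scRNA), repeat
families laid down as identical copies (so their reads multi-map), and
annotated non-hairpin regions. Three landmarks are planted by
construction:

* the first hairpin is the **trigger miRNA**: its precursor stem pairs
  perfectly (`stem_mismatch_count = 0`); all other hairpins get 1–3
  stem mismatches;
* the first gene (the **target**) carries a 22-nt site in its 3'UTR that
  is the exact reverse complement of the trigger's mature sequence;
* the **paralog** shares exactly one 22-mer with the target's spliced
  transcript (its flanking bases are forced to differ so the shared
  stretch cannot extend), giving the trans-action analysis a
  single-hit transcript.

Construction is verified before the world is returned: every mature
sequence with a mismatched stem must occur exactly once genome-wide
(both strands searched); the trigger's mature necessarily occurs three
times — its own arm, its star arm (a perfect stem *is* the reverse
complement), and the planted site — and the shared 22-mer exactly
twice. A rare random collision triggers a rebuild under a shifted seed.

## Library generation

`simulate_library()` draws exactly `depth` reads from one multinomial
over read sources, so library depth is conserved by construction and a
knocked-out pathway redistributes reads to the remaining classes, as a
fixed-depth sequencing run would. The source weights encode the three
library designs:

* **total RNA** (`ip_target = "none"`): class fractions of the cellular
  pool (40% miRNA, 10% 21U, 20% structural/repeat/background classes,
  and 0.4% per active siRNA locus — 20% in wild type);
* **ALG-1/ALG-2 IP**: 95% miRNA (purity `alg_purity`), with species
  weights proportional to expression times `1 - P(RDE-1)`, i.e.
  mismatched-stem precursors;
* **RDE-1 IP**: the scavenger mixture — 60% miRNA weighted by
  expression times `P(RDE-1)` (`w0 = 0.8` for the perfect stem,
  `w_mm = 0.1` otherwise), 15% repeats, 10% secondary siRNAs, 5% sense
  fragments, 10% across the remaining classes, and **zero** weight for
  21U-RNAs, which do not interact with the scavenger.

miRNA expression levels are a fixed geometric ladder (16-fold range),
shuffled per world, so ratio-versus-abundance plots have a realistic
abundance axis without risking absurdly low-coverage species.

Secondary siRNA reads at a locus are 22-nt windows of the spliced
transcript, reverse-complemented (strictly antisense), emitted as
triphosphate reads. Window starts are sampled with weight
$e^{\lambda x}$ where $x \in [0,1]$ is the fractional transcript
position and $\lambda = 2$; this realizes a smooth 3' bias whose
half-ratio statistic is comfortably positive at a few hundred reads.
The TAP rule is applied last: untreated libraries lose every
triphosphate read (the cloning leak is exactly zero — the package
models full dependence of secondary siRNA cloning on 5' trimming).

## Genotype model

Production at a **trigger-dependent** locus is scaled by
`g(genotype)`: zero for `rde-1` or `mir-243` nulls (the trigger complex
cannot form), 0.05 for `rrf-1` (the dedicated polymerase is gone;
residual activity from other RdRPs), 0.1 for the multi-Argonaute `MAGO`
strain (secondary siRNAs are made but not stabilized), 1.2 for `alg-1`
(the competing Argonaute no longer sequesters the trigger), and 1 for
wild type and for alleles with no modelled effect (`mir-1`, `rrf-2`,
`rrf-3`). The source observations are categorical (northern blots), so
these magnitudes are the package's own calibration, chosen once so that
"abolished", "greatly reduced", "severely affected" and "slightly
elevated" are statistically separable at a 100,000-read desk depth; all
are configurable. The other 48 endo-siRNA loci are modelled as
constitutive: genotype factors do not touch them, which matches the
observation that only two loci respond strongly to scavenger-Argonaute
loss and keeps the depletion analysis' planted truth unambiguous.

# The analysis side

## Mapping and the twelve categories

`map_reads()` reports *every* exact occurrence of a read on either
genome strand (implemented as a hash join of reads against all genome
windows of the queried lengths — exact and complete at toy-genome
scale; the test suite holds it to a brute-force linear-scan oracle).
Inexact alignment is deliberately out of scope: at 60 kb with
error-free reads it buys nothing and would blur the planted truth.

`classify_reads()` assigns each mapped read one of twelve categories by
a fixed priority over all of its alignments:

> known_microRNA > 21U > rRNA > tRNA > snoRNA > snRNA > scRNA >
> repeat > siRNA (antisense to a coding exon) > sense > non-hairpin
> region > other.

Specific, well-curated annotations outrank broad ones, and structural
RNA classes claim their likely degradation products before genic
categories. miRNA and 21U calls additionally require ≥90% of the read
inside the feature on the same strand (isomiR-style end slack without
admitting passers-by). A read is `other` only if no alignment overlaps
anything. Junction-spanning secondary reads have no genomic match at
all: they surface in the unmapped set, are excluded from composition
denominators, and are recovered later by the signature module through
spliced-transcript matching. Multi-mappers are classified by the best
category across hits, but per-locus siRNA counting uses unique mappers
only — multi-mapping siRNA reads cannot be attributed to one locus.

## Library comparison

`scale_library()` rescales counts to a common total (100,000 by
default) with largest-remainder rounding, so whole-library scalings sum
to the target *exactly*. Species subsets (the miRNA table, the siRNA
locus table) are scaled against the full library total via
`library_total`, which is the meaningful normalization when the subset
itself shrinks in a mutant. `log2_enrichment()` adds a pseudocount of
one scaled read before the ratio — zeros are real in this data (a locus
abolished in a mutant) and must stay plottable; the pseudocount choice
only matters in the far-depleted tail where calls are unambiguous
anyway. Depleted loci are called at `log2 ratio <= -2` with a wild-type
floor of 20 scaled reads; both knobs are exposed, and the floor is what
keeps never-expressed loci (the paralog) out of the call set.

## Signature scoring and verdict

The four statistics are computed per locus from the TAP-treated
library's reads: the count-weighted antisense fraction; the TAP
statistic `log2((TAP+ + 1)/(TAP- + 1))` on scaled locus totals; the
exonic fraction (transcript-matching reads, junction reads counted and
reported separately); and the 3' gradient as both a halves log2 ratio
(middle base excluded for odd lengths, so mirrored profiles flip the
sign exactly) and a Spearman correlation of 25-nt window coverage with
window index. The verdict is a pure threshold rule: *secondary-like*
needs antisense ≥ 0.95 AND TAP ≥ 3 (~8-fold) AND exonic ≥ 0.95;
*primary-like* is TAP ≤ 1; anything else is *mixed*, and fewer than 50
reads is *insufficient_data*. The source observations are categorical
("strictly antisense", "fully dependent"), so the numeric cutoffs are
implementation choices made to render the categories testable; they are
parameters, not findings. The fraction of antisense reads 5' of the
trigger site is reported as an auxiliary statistic but never gated on —
with a 3'UTR trigger site nearly the entire transcript is upstream of
it, so the check has little discriminative value here.

## Target scan and trans analysis

`scan_sites()` is a full-length sliding Hamming comparison against the
reverse complement of the mature miRNA — no G:U wobble, no gaps, no
seed-only mode. That is exactly the configuration that licenses RdRP
recruitment in the model; canonical (seed-pairing) target prediction is
out of scope. `trans_hit_analysis()` counts distinct siRNA species with
a perfect antisense window per transcript and flags transcripts at
`min_hits = 2`: a single shared 22-mer — the planted paralog case — is
*not* sufficient evidence for decay. The flag is advisory; no
sufficiency threshold beyond "more than one" is claimed.

# Numerical and design choices

* **Determinism.** Every stochastic step runs under `withr::with_seed`
  with a caller-supplied seed; identical config + spec + seed gives
  byte-identical libraries and pipeline outputs (the run log, which
  records wall-clock stage timings, is the one non-reproducible file).
* **Coordinates.** 0-based half-open everywhere internally; GFF3 is
  written 1-based closed, BED 0-based half-open.
* **Problem sizes.** Unit tests run on a reduced world (20 kb, 8 loci);
  the acceptance-style checks use the default conditions (60 kb, 50
  loci, 100,000-read total libraries, 10,000-read IP libraries). The
  trans-action analysis uses a deep locus read set (expected ~8,000
  reads) because its planted truth — the one species overlapping the
  shared 22-mer — must actually be present in the sample; at ~400 reads
  over ~420 start positions that species is missing from about half of
  the draws.
* **Degenerate inputs.** Empty configurations build bare genomes;
  empty libraries refuse to scale; a zero-coverage locus yields
  `insufficient_data` rather than statistics; UTRs shorter than the
  miRNA scan to zero sites without error.
* **Tie-breaks.** Largest-remainder ties fall to lexicographically
  earlier species; equal-priority classification candidates fall to the
  leftmost alignment. Both are deterministic.

# What passing tests do and do not show

The generator emulates the *structure* of the data — class mixtures,
loading biases, chemistry, genotype dependence, splicing — with
error-free single-end reads, no adapters, no sequencing error, no
quality scores, fixed read length, one isoform per gene, and no
convergent-transcription loci (the mixed sense/antisense dsRNA-core
case is represented in tests only as a fixture for the verdict rule).
Recovering the planted truth therefore demonstrates that the analysis
logic is correct under the stated model; it does not demonstrate
robustness to alignment ambiguity at genome scale, annotation error, or
cloning biases beyond the TAP rule. Those are properties of real
libraries that this package's claims deliberately do not cover.
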