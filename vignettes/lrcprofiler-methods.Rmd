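---
title: "Methods: paralog-aware analysis of LRC Ig-like receptor genes"
author: "lrcprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralog-aware analysis of LRC Ig-like receptor genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcprofiler)
```

# Scope and model

The leukocyte receptor complex (LRC) encodes families of immunoglobulin-like
immune receptors (KIR, LILR and relatives) that expand and contract rapidly
across mammalian lineages. A recently expanded family typically presents as
two or more divergent clades of paralogs: genes between clades are only
about two-thirds identical at the nucleotide level, while paralogs within a
clade can exceed 95% identity. This structure creates two linked analysis
problems that this package addresses end to end:

1. **Functional annotation.** Each gene model must be called inhibitory
   (long cytoplasmic tail carrying immunoreceptor tyrosine-based inhibition
   motifs, ITIMs), activating (short tail plus a basic transmembrane residue
   that can recruit an activating adapter), pseudogene (disabled by a
   premature stop or frameshift), fragment, or ambiguous.
2. **Expression quantification.** Short RNA-seq reads multi-map within a
   clade, so read counting must be tiered: confident at the clade (group)
   level, conservative at the gene level, and region-restricted where only a
   sub-interval of the transcript distinguishes two near-identical genes.

A distance-based phylogenetic module (composite-likelihood distances,
minimum-evolution search, bootstrap) establishes the clade structure, and a
sliding-window recurrence (dot-plot) module compares assemblies to locate
inversions and regions present in only one assembly. Because real loci of
this kind are large and proprietary accessions are not redistributable, the
package ships a fully seeded synthetic-locus and read generator that
reproduces the family's statistical structure with complete ground truth;
every downstream module is validated against that truth.

# The synthetic locus generator

`generate_locus()` builds `n_groups * genes_per_group` receptor genes from a
single random codon template with segments leader (60 nt), two Ig-like
domains (294 nt each), transmembrane segment (TM, 69 nt) and a cytoplasmic
tail of 75 aa (long) or 9 aa (short), plus a terminal stop. Inhibitory
genes receive two ITIM blocks (`VTYAQL`) at tail offsets 11 and 41;
activating genes receive a mid-TM arginine. Identity targets default to
0.67 between groups and (0.90, 0.98) within groups, measured over the
template region shared by all genes (leader + Ig domains + TM, 717 nt by
default); the long and short tails are different segments and cannot be
compared ungapped, so they are excluded from the identity bookkeeping but
diverge at the same per-site rate.

## Identity calibration

Divergence is applied as uniform random substitutions with *exact counts*
rather than per-site coin flips: at 300-900 nt, binomial sampling alone
would spread realized identities by more than the ±0.02 band the generator
promises. Three further choices make the realized identities tight:

* **Protected positions.** The start codon, ITIM codons and the TM
  arginine codon never mutate. The TM is built from xTy codons
  (Leu/Val/Ile/Phe/Met), whose first and third codon positions accept any
  substitution without losing hydrophobicity; only the invariant `T` at
  position 2 is protected. This keeps the hydropathy scan valid for every
  diverged gene while leaving the TM as divergent between clades
  (~0.77 identity) as the rest of the template, so no artificially
  conserved island can seed spurious cross-clade alignments.
* **Disjoint ancestor mutations.** Each group ancestor mutates a private
  set of positions, and gene-level mutations avoid all ancestor positions.
  A cross-group gene pair therefore mismatches at exactly
  `2 * k_anc` ancestor sites plus the same gene-level channel that
  separates within-group pairs, giving the closed form
  `k_anc = C * (intra_mid - inter) / 2` over the comparable region `C`.
  The gene-level per-site rate `e` then follows from the intra-group
  midpoint alone via the uniform-substitution match probability
  `(1 - e)^2 + e^2/3`.
* **Largest-remainder allocation.** Substitution counts are distributed
  over segments proportionally to their mutable-pool sizes, avoiding the
  systematic up-rounding that per-segment `round()` would give small pools.

Across ten seeds the realized cross-group identities fall in
[0.661, 0.678] for a 0.67 target and within-group identities stay inside
their band, as the test suite asserts.

## Pseudogenes and the novel gene pair

`round(pseudogene_fraction * n)` genes are disabled, each by an
independently placed lesion — a premature stop (codon replaced by a random
stop within the first 80% of the CDS) or a 1-2 nt deletion — with positions
drawn without replacement across pseudogenes so that no two share a lesion,
emulating post-expansion disablement. `generate_paired_novel_genes()`
builds the long-tailed/short-tailed receptor pair: membrane-distal Ig
domains differing by an exact number of nucleotides (synonymous
third-position changes where possible, so the domain's protein sequence is
unchanged), membrane-proximal domains differing by an exact count that can
include a glutamine-to-stop CAG>TAG change, and a short-tailed gene whose
TM arginine sits one residue from the extracellular boundary — close enough
that its ability to recruit an activating adapter is uncertain, which the
classifier reflects by calling it ambiguous rather than activating.

## Read simulation

`simulate_reads()` draws each fragment's gene of origin with probability
proportional to `abundance * transcript_length`, a fragment length from
Normal(300, 30) truncated at the read length and the transcript length
(typical short-insert libraries; the real libraries' insert size is not
published, so this is a stand-in, not an inference), a uniform start
position, and independent per-base substitution errors (default 0.5%; also
a stand-in). Paired mates are written as `/1` and `/2` records with fixed
Q30 qualities, and every read's origin, position and error count is
recorded in the truth table. The generator does not model indel errors,
quality-dependent error rates, intron-containing transcripts, recombination
or gene conversion; validation results on synthetic data therefore
demonstrate algorithmic correctness under substitution-only divergence, not
robustness to those additional real-data phenomena.

# Receptor classification

Evidence is gathered identically for every model: standard-code translation
with internal stops reported in CDS coordinates; an ITIM scan of the
cytoplasmic tail for `(I/L/V/S)xYxx(L/V)` with all (overlapping) hits
reported; a Kyte-Doolittle hydropathy scan (window 19 aa, mean threshold
1.6, the best window extended while the added residue is itself hydrophobic
and the window mean stays above threshold) when no TM segment is annotated;
charged residues (R, K, D, E, H) inside the TM with their offset from the
extracellular boundary; and disablement detection (internal stops;
frameshift when the CDS length is not a multiple of 3 or an annotated indel
shifts frame, with downstream stops attributed to the shift).

Calls follow a fixed precedence — fragment (no TM and fewer than half the
template domain kinds), pseudogene (any disablement), inhibitory (long
tail, at least `min_itims` ITIMs), activating (short tail plus a
non-boundary-proximal basic TM residue), else ambiguous — so permuting the
order in which evidence is gathered can never change a call. Defaults worth
knowing: a tail of >= 30 aa counts as long (separating the 75-aa and 9-aa
exemplars with wide margin); one ITIM suffices for an inhibitory call (the
canonical definition; known inhibitory receptors here carry two);
boundary-proximal means within 3 aa of the TM's extracellular end. All are
configurable via `classify_params()`. Histidine is reported among charged
residues but never confers activating potential.

# Paralog-aware read assignment

`align_reads()` is a seed-and-extend local aligner (Rcpp): exact 15-mer
seeds on both strands locate candidate diagonals per reference, each
diagonal cluster is resolved by banded Smith-Waterman (band 5; match +1,
mismatch -1, gap -2), and the best local alignment per read/gene pair is
reported when identity (= matches / alignment length, the convention used
by standard local-search tools) reaches `min_identity` (default 0.90) and
the alignment length reaches `min_aln_len` (default 50). These thresholds
play the role of a stringent E-value cutoff at 100-nt reads; they are
configurable, not claimed equivalent.

`assign_reads()` applies the tiers in one pass:

* reads whose hits span more than one group are flagged `cross_group` and
  excluded from all counts;
* reads with hits in exactly one group count for that group;
* a read is promoted to a specific gene when its best-scoring hit reaches
  `cutoff` identity (default 0.99, chosen because the most similar paralogs
  are ~95% identical: specific, deliberately insensitive) **and** the best
  score leads the runner-up by at least `min_margin` (default 3).

The margin term generalizes "ties demote to the group tier". A score tie is
only the limiting case of an uninformative read: with a 0.5% error rate, a
read can acquire an error exactly at one of the few positions
distinguishing two ~95%-identical paralogs, converting it into a
zero-mismatch copy of the wrong gene that wins by a margin of one
substitution. Such a read is evidence-free at the gene level, and promoting
it would be an arbitrary choice exactly like promoting a tie; requiring a
lead of more than one substitution (3 score units) demotes it instead. The
cost is conservative: a read must cover at least two informative positions
to be gene-assigned, which slightly reduces gene-tier counts and matches
the high-confidence framing of the 99% cutoff.

`region_restricted_count()` applies the same promotion rules among hits
overlapping each gene's annotated unique region (e.g. TM + cytoplasmic
tail) by at least `min_overlap` (default 25 nt, a quarter-read anchor).
One approximation is documented rather than engineered away: the identity
entering the cutoff is the hit's overall identity, not re-computed within
the overlapping window. For the intended use — gene pairs nearly identical
outside the unique region — the two quantities coincide.

`compute_fpkm()` implements fragments per kilobase of transcript per
million sequenced reads, `count * 1e9 / (length_nt * total_reads)`; paired
mates are counted as independent reads throughout, matching a
per-sequenced-read denominator. Group-level FPKM divides by the mean CDS
length of the group's functional members — a necessary convention, since a
group has no single transcript length; it is recorded here because other
choices (e.g. the shortest member) would shift group FPKM by a constant
factor. `summarize_expression()` reports per-sample and pooled counts and
FPKM, the mean and (n-1)-denominator standard deviation of per-sample FPKM
(absent at n = 1), and the unaccounted summary — group totals minus
gene-assigned totals, with the percentage rounded to one decimal.

## How region-restricted recovery is validated

The count ratio of a gene pair under region-restricted counting estimates
the share of *reads overlapping the unique regions*, not the share of all
reads: a read qualifies when it overlaps the region by `min_overlap`, so
the eligible window extends `read_len - 2 * min_overlap` nt beyond the
region and plain region-length normalization is geometrically biased when
the two regions differ in length. The validation therefore compares
restricted counts against the truth-defined overlap share (binomial
standard-error band) and separately shows that whole-CDS gene-tier
counting, which can only see the TM+tail windows when the extracellular
region differs by a single synonymous nucleotide, misses the transcripts'
true read share by an order of magnitude more.

# Phylogenetics

`pairwise_distance()` computes Tamura-Nei-form distances with *pairwise
deletion* (per pair, only sites where both rows are unambiguous bases) and
a *composite* parameterization: base frequencies and the partition of
differences into the two transition classes and transversions are estimated
once from all pairs pooled, then applied to each pair's difference
proportion. With equal base frequencies and no transition bias the formula
reduces to the Jukes-Cantor closed form `-(3/4) ln(1 - 4p/3)`, which the
tests verify to 1e-3 at p = 0.1; this is an approximation to full
maximum-composite-likelihood estimation, documented as such. Saturated
pairs (any logarithm argument <= 0) and pairs with no shared ungapped sites
raise errors naming the pair.

`nj_tree()` produces the neighbor-joining starting tree (via ape), with
negative branch lengths clamped to zero and the deficit moved to the
adjacent branch. `me_search()` hill-climbs over nearest-neighbor
interchanges under the ordinary-least-squares total-branch-length
criterion: all NNI neighbors are scored by an OLS fit of branch lengths to
the distance matrix (path design matrix, QR solve), the best strictly
improving neighbor is accepted (ties broken by sorted newick string, so the
search is deterministic), and the search stops at a local optimum. On
additive matrices of up to six taxa the result matches exhaustive
enumeration of all topologies, as the tests assert. Raw OLS lengths (which
may be negative) drive the search; reported branch lengths are clamped at
zero.

`bootstrap_tree()` resamples alignment columns with replacement, rebuilds
distances and the ME tree per replicate, and reports per-internal-branch
support as the percentage of replicates containing the same bipartition
(canonical split keys make the support invariant to leaf order). Supports
land on the base tree as node labels; displaying only values above 50% is a
rendering choice, not part of the computation. Multiple sequence alignment
itself is out of scope: synthetic sequences contain no indels, so their
true alignment is known (`locus_alignment()` extracts the extracellular
concatenation), and real data are accepted as aligned FASTA produced by an
external aligner.

# Dot-plot assembly comparison

`compute_grid()` slides 200-bp windows (step 50) over both sequences and
records, for every window pair, the fraction of matching positions —
forward and against the reverse complement of the second sequence
(ambiguity characters count as mismatches). The per-window identity
replaces a score-matrix greyscale; it is simpler and sufficient for
segment detection. `detect_segments()` follows diagonal runs of at least
`min_windows` (3) cells at or above `min_identity` (0.8), bridging at most
one sub-threshold cell, and reports inverted segments from the
reverse-channel runs with coordinates mapped back to the forward strand.
Axis intervals covered by no segment are reported as unmatched — the
signature of sequence present in only one assembly. On a 20-kb sequence
with a planted 2-kb inversion and a 2-kb insertion, both features are
recovered with interval error no larger than one window; this scaled-down
setting stands in for chromosome-scale comparisons, which behave
identically per window but are not exercised in the test suite.

# Pipeline, formats and conventions

All coordinates inside the package are 1-based inclusive — the native
convention of R, IRanges and GFF3 — and conversion to 0-based half-open
happens only at the BED boundary. FASTA/FASTQ pass through Biostrings and
GFF3 through rtracklayer; domain features carry a `segment_kind` attribute.
`run_pipeline()` chains simulate, annotate, quantify, phylo and dotplot
under a single validated configuration (`pipeline_config()`, YAML-loadable
via `load_config()`); unknown keys and out-of-range values abort before any
stage runs, seeds are mandatory (no clock seeding), every effective
parameter lands in `run_log.txt`, and identical configuration reproduces
identical outputs byte for byte. A thin command-line front end
(`inst/scripts/lrc-profiler.R`) exposes the stages as subcommands.

# Validation scale and limitations

The test suite exercises the study-scale conditions the package is designed
for: two clades of five genes (inter 0.67, intra up to 0.95), 1e5
paired-end 100-nt reads at 0.5% error for assignment specificity and
abundance recovery; 200 bootstrap replicates for clade support; 20-kb
sequences for rearrangement detection; and 10,000 random tails for the
ITIM-scanner oracle. These sizes keep a full run in a few minutes while
leaving the statistical conclusions unchanged at larger n.

Known limitations: the aligner's gene tier is deliberately insensitive
(near-tie demotion discards single-evidence reads); allelic variation is
not simulated, so the generator cannot probe the cutoff's behaviour under
polymorphism; the composite distance is an approximation to full
maximum-composite-likelihood; the hydropathy TM predictor is a desk-scale
surrogate for HMM-based prediction and is exercised only on synthetic and
curated inputs; and the dot-plot module does not chain segments across
rearrangements or mask repeats.
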