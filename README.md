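# lrcprofiler

Paralog-aware annotation, expression quantification and comparative
analysis of immunoglobulin-like receptor gene families of the leukocyte
receptor complex (LRC).

Recently expanded receptor families (KIR, LILR and relatives) are hard to
analyse for two reasons: paralogs within a clade can be ~95% identical, so
short RNA-seq reads multi-map and naive counting misattributes expression;
and functional state (inhibitory, activating, pseudogene) must be inferred
from sequence features rather than orthology. `lrcprofiler` implements the
full desk-side workflow for such a family, aimed at immunogenetics
researchers annotating new assemblies of these loci:

* **Functional classification** of receptor gene models: translation with
  internal-stop reporting, canonical ITIM scan (`(I/L/V/S)xYxx(L/V)`),
  Kyte–Doolittle transmembrane prediction, charged-TM-residue calls with
  boundary offsets, disablement (premature stop / frameshift) detection and
  the `<family><group><B|A><ordinal>` naming scheme. Calls follow the
  precedence fragment > pseudogene > inhibitory > activating > ambiguous.
* **Paralog-aware read assignment**: a seed-and-extend local aligner
  (Rcpp), tiered counting — clade (group) level for multi-mapping reads,
  gene level only for reads with a unique best hit at ≥ 99% identity and a
  decisive score margin, region-restricted counting over unique TM+tail
  intervals for near-identical gene pairs — and FPKM
  (`count × 10⁹ / (length × total reads)`) per sample and pooled, with the
  unaccounted-read summary.
* **Distance phylogenetics**: Tamura–Nei-form distances with pooled
  (composite) parameters and pairwise deletion, neighbor-joining start
  tree, minimum-evolution NNI search under the OLS total-branch-length
  criterion, column-bootstrap support and clade-monophyly tests.
* **Dot-plot assembly comparison**: 200-bp sliding-window recurrence grids
  (forward + reverse-complement channels), collinear/inverted segment
  detection and unmatched-interval reporting (insertions, assembly gaps).
* **A fully seeded synthetic-locus and read generator** that reproduces the
  family's statistical structure — two clades ~67% identical, paralogs up
  to ~95% identical, long/short-tailed gene pairs differing by single
  nucleotides, independently disabled pseudogenes, paired-end reads with
  substitution errors — with complete ground truth for validation.

See `vignettes/lrcprofiler-methods.Rmd` for the models, parameter defaults
and design decisions.

## Worked example

```r
library(lrcprofiler)

# a two-clade locus: 2 x 5 receptor genes, 30% pseudogenes
spec <- locus_spec(n_groups = 2, genes_per_group = 5,
                   inter_group_identity = 0.67,
                   intra_group_identity_range = c(0.90, 0.95),
                   pseudogene_fraction = 0.3, seed = 42)
locus <- generate_locus(spec)
cls <- classify_locus(locus)
table(cls$call)
#> activating inhibitory pseudogene
#>          3          4          3

# simulate 20,000 paired-end fragments and assign them
abund <- with_seed(43, setNames(rlnorm(10), names(locus$genes)))
sim <- simulate_reads(locus$genes, abund, 20000, error_rate = 0.005, seed = 44)
refs <- reference_set_from_locus(locus)
hits <- align_reads(sim$reads, refs)
asn <- assign_reads(hits, refs, read_ids = names(sim$reads), cutoff = 0.99)
table(asn$tier)
#>  gene group
#> 36393  3607
sum(asn$cross_group)
#> [1] 0

counts <- tally_assignment(asn, refs)
summ <- summarize_expression(list(s1 = counts), refs,
                             totals = c(s1 = length(sim$reads)))
summ$unaccounted
#>   group group_total gene_assigned unaccounted unaccounted_pct
#> 1     1       20758         18902        1856             8.9
#> 2     2       19242         17491        1751             9.1
#> 3   ALL       40000         36393        3607             9.0

# clade structure with bootstrap support
st <- bootstrap_tree(locus_alignment(locus), n_reps = 200, seed = 45)
labels <- setNames(paste0("group", locus$truth$genes$group),
                   locus$truth$genes$id)
test_monophyly(st, labels)
#>    label n_leaves monophyletic
#> 1 group1        5         TRUE
#> 2 group2        3         TRUE
```

Reading the output: every gene's functional call matches the generator's
truth; all 40,000 read records fall inside a single clade (`cross_group`
is 0 — the two clades are distinguishable at ~67% identity); 91% of reads
are confidently assigned to a specific gene at the 99% cutoff and the rest
remain at the clade tier (the unaccounted 9%), and both clades come back
monophyletic (frameshifted pseudogenes are excluded from the extracellular
alignment, hence 3 leaves in group 2). An end-to-end run of all stages
with one configuration is `run_pipeline(pipeline_config(seed = 1), "out/")`;
a command-line front end lives at `inst/scripts/lrc-profiler.R`.

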