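# Synthetic locus and read generator.

test_that("mutate_to_identity hits its identity target exactly", {
  set.seed(1)
  s <- rand_dna(300)
  expect_identical(mutate_to_identity(s, 1.0, seed = 3), s)
  m <- mutate_to_identity(s, 0.67, preserve_frame = FALSE, seed = 1)
  expect_equal(nchar(m), 300L)
  realized <- pairwise_identity(s, m)
  expect_gte(realized, 0.65)
  expect_lte(realized, 0.69)
  expect_error(mutate_to_identity(s, 0), "target_identity")
  expect_error(mutate_to_identity(s, 1.2), "target_identity")
})

test_that("frame-preserving mutation never creates an in-frame stop", {
  set.seed(2)
  for (i in 1:10) {
    s <- paste(lrcprofiler:::random_codons(100), collapse = "")
    m <- mutate_to_identity(s, 0.95, preserve_frame = TRUE, seed = i)
    codons <- substring(m, seq(1, 298, 3), seq(3, 300, 3))
    expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("generate_locus reproduces the requested category structure", {
  spec <- locus_spec(n_groups = 2, genes_per_group = 5,
                     inter_group_identity = 0.67,
                     intra_group_identity_range = c(0.90, 0.98),
                     pseudogene_fraction = 0.4, seed = 7)
  loc <- generate_locus(spec)
  tg <- loc$truth$genes
  expect_equal(nrow(tg), 10L)
  expect_equal(sum(tg$class == "pseudogene"), 4L)
  # every pseudogene carries >= 1 disablement; functional genes carry none
  dis <- loc$truth$disablements
  expect_setequal(dis$gene_id, tg$id[tg$class == "pseudogene"])
  # no two pseudogenes share a disabling change
  expect_false(anyDuplicated(paste(dis$kind, dis$cds_pos)) > 0)
})

test_that("identical spec and seed give identical output", {
  spec <- locus_spec(pseudogene_fraction = 0.2, seed = 11)
  l1 <- generate_locus(spec)
  l2 <- generate_locus(spec)
  expect_identical(l1$locus_seq, l2$locus_seq)
  expect_identical(l1$genes, l2$genes)
  expect_identical(l1$truth, l2$truth)
  d1 <- file.path(tempdir(), "locA")
  d2 <- file.path(tempdir(), "locB")
  write_locus(l1, d1)
  write_locus(l2, d2)
  for (f in c("locus.fasta", "genes.fasta", "locus.gff3", "truth_genes.tsv")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
})

test_that("realized pairwise identities stay within +/-0.02 of the targets", {
  for (sd in c(3, 7)) {
    spec <- locus_spec(inter_group_identity = 0.67,
                       intra_group_identity_range = c(0.90, 0.98),
                       pseudogene_fraction = 0.4,
                       disablement_kinds = "premature_stop", seed = sd)
    loc <- generate_locus(spec)
    m <- locus_identity_matrix(loc)
    grp <- loc$truth$genes$group
    cross <- m[outer(grp, grp, "!=")]
    intra <- m[outer(grp, grp, "==") & upper.tri(m)]
    expect_true(all(cross >= 0.65 & cross <= 0.69))
    expect_true(all(intra >= 0.90 & intra <= 0.98))
  }
})

test_that("impossible identity constraints are rejected", {
  expect_error(locus_spec(inter_group_identity = 0.95,
                          intra_group_identity_range = c(0.90, 0.98)),
               "identity constraints")
  expect_error(locus_spec(pseudogene_fraction = 1.2), "pseudogene_fraction")
})

test_that("functional genes translate end-to-end without internal stops", {
  loc <- generate_locus(locus_spec(pseudogene_fraction = 0.3, seed = 5))
  tg <- loc$truth$genes
  for (i in which(tg$class != "pseudogene")) {
    cds <- loc$genes[[tg$id[i]]]
    model <- gene_model(tg$id[i], data.frame(start = 1L, end = nchar(cds)))
    tr <- translate_cds(model, cds)
    expect_equal(nrow(tr$internal_stops), 0L, info = tg$id[i])
    expect_equal(tr$trailing_nt, 0L)
  }
})

test_that("the novel gene pair differs by the requested counts", {
  pair <- generate_paired_novel_genes(distal_diff_nt = 1, proximal_diff_nt = 13,
                                      introduce_stop = TRUE, seed = 3)
  sa <- strsplit(pair$long$seq, "")[[1]]
  sb <- strsplit(pair$short$seq, "")[[1]]
  d <- pair$distal_region
  p <- pair$proximal_region
  expect_equal(sum(sa[d[1]:d[2]] != sb[d[1]:d[2]]), 1L)
  expect_equal(sum(sa[p[1]:p[2]] != sb[p[1]:p[2]]), 13L)
  # the distal difference is synonymous: identical protein over that domain
  aa <- function(s, iv) {
    as.character(Biostrings::translate(Biostrings::DNAString(
      substr(s, iv[1], iv[2])), no.init.codon = TRUE))
  }
  expect_identical(aa(pair$long$seq, d), aa(pair$short$seq, d))
  # the stop change is CAG>TAG at the recorded position
  expect_identical(substr(pair$long$seq, pair$stop_cds_pos, pair$stop_cds_pos + 2), "CAG")
  expect_identical(substr(pair$short$seq, pair$stop_cds_pos, pair$stop_cds_pos + 2), "TAG")
  # short-tailed gene: translated proximal domain contains a stop
  expect_true(grepl("\\*", aa(pair$short$seq, p)))
  expect_false(grepl("\\*", aa(pair$long$seq, p)))
})

test_that("a zero-difference pair has identical extracellular sequence", {
  pair <- generate_paired_novel_genes(distal_diff_nt = 0, proximal_diff_nt = 0,
                                      introduce_stop = FALSE, seed = 3)
  p_end <- pair$proximal_region[2]
  expect_identical(substr(pair$long$seq, 1, p_end),
                   substr(pair$short$seq, 1, p_end))
})

test_that("novel-pair error cases are rejected", {
  expect_error(generate_paired_novel_genes(distal_diff_nt = 10000),
               "exceed")
})

test_that("simulated reads respect abundances, errors and truth conservation", {
  loc <- generate_locus(locus_spec(seed = 2))
  genes <- loc$genes
  # degenerate abundance: all mass on one gene
  ab <- stats::setNames(c(1, rep(0, length(genes) - 1L)), names(genes))
  sim <- simulate_reads(genes, ab, 200, error_rate = 0, seed = 5)
  expect_true(all(sim$truth$source_gene == names(genes)[1]))
  # error_rate 0: every read is an exact substring of its source transcript
  src <- genes[sim$truth$source_gene]
  fwd_in <- mapply(function(r, s) grepl(r, s, fixed = TRUE), sim$reads, src)
  rev_in <- mapply(function(r, s) grepl(r, s, fixed = TRUE), revcomp(sim$reads), src)
  expect_true(all(fwd_in | rev_in))
  # conservation: n_reads fragments, x2 records when paired, unique ids
  expect_equal(length(sim$reads), 400L)
  expect_equal(nrow(sim$truth), 400L)
  expect_false(anyDuplicated(sim$truth$read_id) > 0)
  # determinism
  sim2 <- simulate_reads(genes, ab, 200, error_rate = 0, seed = 5)
  expect_identical(sim$reads, sim2$reads)
  expect_error(simulate_reads(genes, ab * 0, 100, seed = 1), "abundances")
  expect_error(simulate_reads(genes, ab, 100, error_rate = 0.7, seed = 1),
               "error_rate")
})

test_that("read origins follow abundance x length weights", {
  loc <- generate_locus(locus_spec(seed = 2))
  genes <- loc$genes
  set.seed(4)
  ab <- stats::setNames(stats::runif(length(genes), 0.5, 2), names(genes))
  sim <- simulate_reads(genes, ab, 50000, paired = FALSE, error_rate = 0.005,
                        seed = 17)
  w <- ab * nchar(genes)
  obs <- table(factor(sim$truth$source_gene, levels = names(genes)))
  gof <- stats::chisq.test(as.integer(obs), p = w / sum(w))
  expect_gt(gof$p.value, 0.001)
})
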