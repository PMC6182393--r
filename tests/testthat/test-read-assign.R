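# Tiered read assignment, FPKM and expression summaries.

fake_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(read_id = r[[1]], gene_id = r[[2]], strand = "+",
               score = r[[3]], matches = r[[4]], aln_len = r[[5]],
               identity = r[[4]] / r[[5]],
               read_start = 1L, read_end = r[[5]],
               ref_start = r[[6]], ref_end = r[[6]] + r[[5]] - 1L,
               stringsAsFactors = FALSE)
  }))
}

two_group_refs <- function() {
  set.seed(3)
  reference_set(c("A1", "A2", "B1"), c("A", "A", "B"),
                c(rand_dna(900), rand_dna(900), rand_dna(900)))
}

test_that("group tier collapses within-group multi-mapping and flags cross-group", {
  refs <- two_group_refs()
  hits <- fake_hits(
    list("r1", "A1", 100, 100, 100, 1),   # within-group multi-map
    list("r1", "A2", 96, 98, 100, 1),
    list("r2", "A1", 100, 100, 100, 1),   # cross-group
    list("r2", "B1", 95, 97, 100, 1)
  )
  asn <- assign_reads(hits, refs, read_ids = c("r1", "r2", "r3"))
  expect_equal(asn$tier, c("gene", "unassigned", "unassigned"))
  expect_equal(asn$cross_group, c(FALSE, TRUE, FALSE))
  gc <- group_counts(asn)
  expect_equal(gc$counts, c(A = 1L))
  expect_equal(gc$cross_group, "r2")
  expect_equal(gc$unassigned, 1L)
})

test_that("gene tier needs a unique best score at >= cutoff identity", {
  refs <- two_group_refs()
  # clear winner at identity 1.00 vs 0.95
  asn <- assign_reads(fake_hits(list("r1", "A1", 100, 100, 100, 1),
                                list("r1", "A2", 90, 95, 100, 1)), refs)
  expect_equal(asn$tier, "gene")
  expect_equal(asn$unit, "A1")
  # below cutoff: group level only
  asn2 <- assign_reads(fake_hits(list("r1", "A1", 96, 98, 100, 1)), refs)
  expect_equal(asn2$tier, "group")
  expect_equal(asn2$unit, "A")
  # exact score tie: demoted
  asn3 <- assign_reads(fake_hits(list("r1", "A1", 100, 100, 100, 1),
                                 list("r1", "A2", 100, 100, 100, 1)), refs)
  expect_equal(asn3$tier, "group")
  # near-tie within the score margin: demoted rather than guessed
  asn4 <- assign_reads(fake_hits(list("r1", "A1", 100, 100, 100, 1),
                                 list("r1", "A2", 98, 99, 100, 1)), refs)
  expect_equal(asn4$tier, "group")
  expect_error(assign_reads(fake_hits(list("r1", "A1", 1, 1, 1, 1)), refs,
                            cutoff = 1.5), "cutoff")
})

test_that("raising the cutoff never increases a per-gene count", {
  loc <- generate_locus(locus_spec(seed = 4))
  refs <- reference_set_from_locus(loc)
  ab <- stats::setNames(rep(1, nrow(refs)), refs$id)
  sim <- simulate_reads(loc$genes, ab, 3000, error_rate = 0.005, seed = 9)
  hits <- align_reads(sim$reads, refs)
  prev <- NULL
  for (cutoff in c(0.95, 0.97, 0.99, 1.0)) {
    counts <- gene_counts(assign_reads(hits, refs, cutoff = cutoff), refs)
    if (!is.null(prev)) expect_true(all(counts <= prev))
    prev <- counts
  }
})

test_that("assignment tiers are conserved", {
  loc <- generate_locus(locus_spec(seed = 4))
  refs <- reference_set_from_locus(loc)
  ab <- stats::setNames(rep(1, nrow(refs)), refs$id)
  sim <- simulate_reads(loc$genes, ab, 3000, error_rate = 0.005, seed = 10)
  hits <- align_reads(sim$reads, refs)
  asn <- assign_reads(hits, refs, read_ids = names(sim$reads))
  n_gene <- sum(asn$tier == "gene")
  n_group <- sum(asn$tier %in% c("gene", "group"))
  n_hit <- length(unique(hits$read_id))
  expect_lte(n_gene, n_group)
  expect_lte(n_group, n_hit)
  expect_lte(n_hit, length(sim$reads))
})

test_that("region-restricted counting honours overlap and uniqueness", {
  set.seed(5)
  seqs <- c(rand_dna(500), rand_dna(500))
  ur <- data.frame(gene_id = c("A1", "A2"), start = c(401L, 401L),
                   end = c(500L, 500L))
  refs <- reference_set(c("A1", "A2"), c("A", "A"), seqs, unique_regions = ur)
  # read fully inside the unique region
  h1 <- fake_hits(list("r1", "A1", 100, 100, 100, 401))
  expect_equal(region_restricted_count(h1, refs)$counts, c(A1 = 1L, A2 = 0L))
  # read entirely within the shared region: zero overlap, excluded
  h2 <- fake_hits(list("r2", "A1", 100, 100, 100, 1))
  expect_equal(sum(region_restricted_count(h2, refs)$counts), 0L)
  # overlap of min_overlap - 1: excluded at the threshold boundary
  h3 <- fake_hits(list("r3", "A1", 100, 100, 100, 401 - 76))  # overlap 24
  expect_equal(sum(region_restricted_count(h3, refs, min_overlap = 25)$counts), 0L)
  h4 <- fake_hits(list("r4", "A1", 100, 100, 100, 401 - 75))  # overlap 25
  expect_equal(region_restricted_count(h4, refs, min_overlap = 25)$counts[["A1"]], 1L)
  # configuration error when no gene carries a region
  refs2 <- reference_set(c("A1", "A2"), c("A", "A"), seqs)
  expect_error(region_restricted_count(h1, refs2), "unique region")
})

test_that("FPKM follows count * 1e9 / (length * total)", {
  expect_equal(compute_fpkm(1000, 1000, 1e6), 1000)
  expect_equal(compute_fpkm(0, 500, 1e6), 0)
  expect_equal(compute_fpkm(1000, 1000, 2e6), 500)
  expect_error(compute_fpkm(1, 0, 1e6), "length_nt")
  expect_error(compute_fpkm(1, 100, 0), "total_reads")
  # scale invariance
  f1 <- compute_fpkm(137, 942, 1e6)
  f2 <- compute_fpkm(137 * 7, 942, 7e6)
  expect_equal(f1, f2, tolerance = 1e-9)
})

test_that("expression summaries pool counts and track per-sample spread", {
  set.seed(6)
  refs <- reference_set(c("A1", "A2", "B1"), c("A", "A", "B"),
                        c(rand_dna(900), rand_dna(960), rand_dna(900)))
  counts <- list(
    s1 = data.frame(unit = c("A1", "A2", "B1", "A", "B"),
                    unit_type = c("gene", "gene", "gene", "group", "group"),
                    count = c(10L, 5L, 2L, 20L, 4L)),
    s2 = data.frame(unit = c("A1", "A2", "B1", "A", "B"),
                    unit_type = c("gene", "gene", "gene", "group", "group"),
                    count = c(8L, 7L, 1L, 18L, 2L))
  )
  summ <- summarize_expression(counts, refs, totals = c(s1 = 1e6, s2 = 2e6))
  tab <- summ$table
  pooled <- tab[tab$sample == "POOLED", ]
  expect_equal(pooled$count[pooled$unit == "A"], 38L)
  expect_equal(pooled$count[pooled$unit == "A1"], 18L)
  # pooled FPKM uses the pooled total
  expect_equal(pooled$fpkm[pooled$unit == "A1"],
               compute_fpkm(18, 900, 3e6))
  # group length = mean functional member CDS length
  expect_equal(pooled$fpkm[pooled$unit == "A"],
               compute_fpkm(38, mean(c(900, 960)), 3e6))
  # sd over per-sample FPKM with n-1 denominator
  st <- summ$stats
  f <- tab[tab$unit == "A1" & tab$sample != "POOLED", "fpkm"]
  expect_equal(st$sd_fpkm[st$unit == "A1"], stats::sd(f))
  # single sample: sd reported as absent
  summ1 <- summarize_expression(counts["s1"], refs, totals = c(s1 = 1e6))
  expect_true(is.na(summ1$stats$sd_fpkm[1]))
  # unaccounted arithmetic
  un <- summ$unaccounted
  all_row <- un[un$group == "ALL", ]
  expect_equal(all_row$group_total, 44L)
  expect_equal(all_row$unaccounted, 44L - 33L)
})

test_that("read-count arithmetic reproduces printed-total bookkeeping", {
  s <- unaccounted_summary(c(72195, 135081), 123990)
  expect_equal(s$combined_total, 207276)
  expect_equal(s$unaccounted, 83286)
  expect_equal(s$unaccounted_pct, 40.2)
})

test_that("splice-junction support distinguishes inclusion from exclusion", {
  set.seed(13)
  up <- rand_dna(300)
  seg <- rand_dna(153)
  down <- rand_dna(300)
  tx_skip <- paste0(up, down)
  tx_incl <- paste0(up, seg, down)
  sim_skip <- simulate_reads(c(skip = tx_skip), c(skip = 1), 300,
                             paired = FALSE, error_rate = 0, seed = 2)
  sim_incl <- simulate_reads(c(incl = tx_incl), c(incl = 1), 300,
                             paired = FALSE, error_rate = 0, seed = 3)
  res_skip <- splice_junction_support(sim_skip$reads, up, seg, down)
  expect_gt(res_skip$exclusion, 0)
  expect_equal(res_skip$inclusion, 0)
  res_incl <- splice_junction_support(sim_incl$reads, up, seg, down)
  expect_gt(res_incl$inclusion, 0)
  expect_equal(res_incl$exclusion, 0)
  # reads far from any junction: all three counts zero
  far <- c(far1 = substr(up, 1, 100))
  res_far <- splice_junction_support(far, up, seg, down)
  expect_equal(res_far$exclusion + res_far$inclusion + res_far$segment_specific, 0)
  expect_error(splice_junction_support(far, up, seg, down, flank = 80),
               "flank")
})
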