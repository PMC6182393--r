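# Composite distances, minimum-evolution search, bootstrap and monophyly.

test_that("pairwise distances are symmetric with zero diagonal and honour pairwise deletion", {
  aln <- aligned_set(c(x = "ACGTACGTAC", y = "ACGTACGTAC", z = "AC-TACGTAT"))
  d <- pairwise_distance(aln)
  expect_true(isSymmetric(d$d))
  expect_equal(unname(diag(d$d)), rep(0, 3))
  expect_equal(d$d["x", "y"], 0)
  expect_equal(d$usable["x", "z"], 9L)  # gapped site excluded
  # rows identical except at sites where one has gaps: distance 0
  aln2 <- aligned_set(c(x = "ACGTACGTAC", y = "AC-TAC-TAC", z = "ACGTACGTAT"))
  expect_equal(pairwise_distance(aln2)$d["x", "y"], 0)
  # a pair with no shared ungapped sites is an error naming the pair
  aln3 <- aligned_set(c(x = "AC----", y = "--GT--", z = "ACGTAC"))
  expect_error(pairwise_distance(aln3), "x and y")
})

test_that("composite distance reduces to Jukes-Cantor at p = 0.1 without bias", {
  set.seed(2)
  L <- 6000
  a <- rand_dna(L)
  b <- mutate_to_identity(a, 0.9, seed = 4)
  c3 <- mutate_to_identity(a, 0.7, seed = 5)
  d <- pairwise_distance(aligned_set(c(s1 = a, s2 = b, s3 = c3)))
  jc <- -0.75 * log(1 - 4 * 0.1 / 3)
  expect_lt(abs(d$d["s1", "s2"] - jc), 1e-3)
})

test_that("neighbor joining recovers additive trees and clamps negatives", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,d:1):1);")
  dm <- cophenetic(tr)
  nj0 <- nj_tree(dm)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj0)), 0,
               ignore_attr = TRUE)
  expect_true(all(nj0$edge.length >= 0))
  # equidistant 3 taxa: equal branch lengths
  dm3 <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(dm3) <- 0
  t3 <- nj_tree(dm3)
  expect_equal(unname(t3$edge.length), rep(0.5, 3))
  # two tight pairs are neighbors
  dm4 <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(dm4) <- 0
  dm4["a", "b"] <- dm4["b", "a"] <- 0.01
  dm4["c", "d"] <- dm4["d", "c"] <- 0.01
  t4 <- nj_tree(dm4)
  truth <- ape::unroot(ape::read.tree(text = "((a,b),(c,d));"))
  expect_equal(ape::dist.topo(t4, truth), 0, ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("ME search minimizes OLS length and matches exhaustive search", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,d:1):1);")
  dm <- cophenetic(tr)
  # start at the optimum: returned unchanged
  me0 <- me_search(nj_tree(dm), dm)
  expect_equal(ape::dist.topo(me0, ape::unroot(tr)), 0, ignore_attr = TRUE)
  # deliberately wrong start topology: truth recovered
  wrong <- ape::unroot(ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);"))
  me1 <- me_search(wrong, dm)
  expect_equal(ape::dist.topo(me1, ape::unroot(tr)), 0, ignore_attr = TRUE)
  # exhaustive oracle over all 105 six-taxon topologies, OLS refit via lm()
  set.seed(9)
  tr6 <- ape::rtree(6)
  tr6$edge.length <- stats::runif(nrow(tr6$edge), 0.1, 1)
  dm6 <- cophenetic(tr6)
  me6 <- me_search(nj_tree(dm6), dm6)
  allt <- phangorn::allTrees(6, rooted = FALSE, tip.label = tr6$tip.label)
  tot <- vapply(seq_along(allt), function(i) {
    ols_tree_length(allt[[i]], dm6)$total
  }, numeric(1))
  best <- allt[[which.min(tot)]]
  expect_equal(ape::dist.topo(me6, best), 0, ignore_attr = TRUE)
  expect_equal(attr(me6, "ols_total"), min(tot), tolerance = 1e-9)
  # monotone acceptance on a random matrix
  set.seed(10)
  r <- matrix(stats::runif(25), 5, 5)
  r <- (r + t(r)) / 2
  diag(r) <- 0
  dimnames(r) <- list(letters[1:5], letters[1:5])
  start <- nj_tree(r)
  out <- me_search(start, r)
  expect_lte(attr(out, "ols_total"), ols_tree_length(start, r)$total + 1e-12)
})

test_that("OLS branch lengths reproduce additive distances exactly", {
  tr <- ape::read.tree(text = "((a:1,b:2):1,(c:1.5,d:1):1);")
  dm <- cophenetic(tr)
  fit <- ols_tree_length(ape::unroot(tr), dm)
  expect_equal(fit$total, sum(tr$edge.length), tolerance = 1e-9)
  # independent check: lm() on the path design of the quartet
  # d(a,b) = ea + eb etc.; for an additive matrix residuals are zero
  expect_equal(unname(sort(fit$lengths)), sort(c(1, 2, 1.5, 1, 2)),
               tolerance = 1e-9)
})

test_that("bootstrap supports behave at the edges and under permutation", {
  loc <- generate_locus(locus_spec(genes_per_group = 3, seed = 7))
  aln <- locus_alignment(loc)
  # n_reps = 1: supports are 0 or 100
  st1 <- bootstrap_tree(aln, n_reps = 1, seed = 2)
  expect_true(all(st1$support$percent %in% c(0, 100)))
  # duplicate taxon rows form a cherry at support 100
  seqs <- unclass(aln)[1:4]
  seqs <- c(seqs, dup1 = unname(seqs[1]))
  names(seqs)[5] <- "dup1"
  st2 <- bootstrap_tree(aligned_set(seqs), n_reps = 25, seed = 3)
  k <- split_key(c(names(seqs)[1], "dup1"), st2$tree$tip.label)
  expect_equal(st2$support$percent[st2$support$split == k], 100)
  # leaf-order permutation leaves supports invariant
  st <- bootstrap_tree(aln, n_reps = 25, seed = 5)
  perm <- unclass(aln)[rev(seq_along(aln))]
  stp <- bootstrap_tree(aligned_set(perm), n_reps = 25, seed = 5)
  s1 <- st$support[order(st$support$split), ]
  s2 <- stp$support[order(stp$support$split), ]
  expect_equal(s1$split, s2$split)
  expect_equal(s1$percent, s2$percent)
})

test_that("monophyly verdicts match the tree's bipartitions", {
  t1 <- ape::read.tree(text = "((a1,a2),(b1,b2));")
  labs <- c(a1 = "a", a2 = "a", b1 = "b", b2 = "b")
  m1 <- test_monophyly(t1, labs)
  expect_true(all(m1$monophyletic))
  t2 <- ape::read.tree(text = "((a1,b1),(a2,b2));")
  m2 <- test_monophyly(t2, labs)
  expect_false(any(m2$monophyletic))
  expect_error(test_monophyly(t1, labs[1:3]), "labeled")
  # cross-check against ape on a larger random tree
  set.seed(6)
  tr <- ape::rtree(12)
  labels <- stats::setNames(sample(c("x", "y"), 12, TRUE), tr$tip.label)
  mine <- test_monophyly(tr, labels)
  for (lb in mine$label) {
    tips <- names(labels)[labels == lb]
    expect_equal(mine$monophyletic[mine$label == lb],
                 ape::is.monophyletic(tr, tips, reroot = TRUE),
                 info = lb)
  }
})

test_that("the synthetic two-group locus yields two monophyletic clades", {
  loc <- generate_locus(locus_spec(genes_per_group = 4, seed = 7))
  aln <- locus_alignment(loc)
  st <- bootstrap_tree(aln, n_reps = 50, seed = 5)
  labels <- stats::setNames(paste0("g", loc$truth$genes$group),
                            loc$truth$genes$id)
  mono <- test_monophyly(st, labels)
  expect_true(all(mono$monophyletic))
})
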