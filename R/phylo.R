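# Distance-based phylogenetics for receptor gene families.
#
# Pairwise nucleotide distances use a composite-likelihood realization of
# the Tamura-Nei (TN93) model: base frequencies and the partition of
# differences into the two transition classes and transversions are
# estimated once from all sequence pairs pooled, then applied per pair with
# pairwise deletion of gapped sites. Trees are built by neighbor joining
# followed by a minimum-evolution hill-climb over nearest-neighbor
# interchanges under the OLS total-branch-length criterion, with
# column-resampling bootstrap support.

#' Validate an aligned sequence set
#'
#' @param seqs Named character vector of equal-length aligned nucleotide
#'   rows; `-` is the gap character.
#' @return The input, invisibly classed as `aligned_set`.
#' @export
aligned_set <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(seqs) < 3L) stop("need at least 3 sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("aligned rows must have equal length", call. = FALSE)
  }
  structure(seqs, class = "aligned_set")
}

.aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(toupper(unclass(aln)), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Composite-likelihood pairwise distances with pairwise deletion
#'
#' For each pair, sites where either row is not an unambiguous base are
#' excluded (pairwise deletion). Distances follow the Tamura-Nei form with
#' base frequencies and the transition/transversion partition estimated
#' once from all pairs pooled and applied per pair; with equal frequencies
#' and no transition bias the distance reduces to the Jukes-Cantor closed
#' form `-(3/4) log(1 - 4p/3)`.
#'
#' @param aln An [aligned_set()] (or named character vector).
#' @param model `"tn93_composite"` (default) or `"jc"`.
#' @return List of class `distance_result`: `d` (symmetric matrix, zero
#'   diagonal), `usable` (per-pair comparable-site counts), `pi` (pooled
#'   base frequencies).
#' @export
pairwise_distance <- function(aln, model = c("tn93_composite", "jc")) {
  model <- match.arg(model)
  if (!inherits(aln, "aligned_set")) aln <- aligned_set(aln)
  M <- .aln_matrix(aln)
  n <- nrow(M)
  L <- ncol(M)
  valid <- matrix(M %in% BASES, n, L)

  counts <- table(factor(M[valid], levels = BASES))
  pi <- as.numeric(counts) / sum(counts)
  names(pi) <- BASES

  usable <- matrix(0L, n, n, dimnames = list(rownames(M), rownames(M)))
  p_mat <- matrix(0, n, n)
  P1m <- matrix(0, n, n)  # A<->G proportion
  P2m <- matrix(0, n, n)  # C<->T proportion
  Qm <- matrix(0, n, n)   # transversion proportion
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      u <- sum(ok)
      if (u == 0L) {
        stop(sprintf("no comparable ungapped sites between %s and %s",
                     rownames(M)[i], rownames(M)[j]), call. = FALSE)
      }
      a <- M[i, ok]
      b <- M[j, ok]
      diff <- a != b
      ts1 <- sum((a == "A" & b == "G") | (a == "G" & b == "A"))
      ts2 <- sum((a == "C" & b == "T") | (a == "T" & b == "C"))
      tv <- sum(diff) - ts1 - ts2
      usable[i, j] <- usable[j, i] <- u
      p_mat[i, j] <- p_mat[j, i] <- sum(diff) / u
      P1m[i, j] <- P1m[j, i] <- ts1 / u
      P2m[i, j] <- P2m[j, i] <- ts2 / u
      Qm[i, j] <- Qm[j, i] <- tv / u
    }
  }

  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  if (model == "jc") {
    arg <- 1 - 4 * p_mat / 3
    if (any(arg <= 0 & upper.tri(arg))) {
      stop("saturated pair: Jukes-Cantor distance undefined", call. = FALSE)
    }
    d <- -3 / 4 * log(arg)
    diag(d) <- 0
    dimnames(d) <- dimnames(usable)
    return(structure(list(d = d, usable = usable, pi = pi, model = model),
                     class = "distance_result"))
  }

  # pooled (composite) partition of differences into the two transition
  # classes and transversions
  ut <- upper.tri(p_mat)
  tot <- sum(P1m[ut]) + sum(P2m[ut]) + sum(Qm[ut])
  if (tot > 0) {
    f1 <- sum(P1m[ut]) / tot
    f2 <- sum(P2m[ut]) / tot
  } else {
    f1 <- f2 <- 1 / 6  # no differences anywhere; partition is irrelevant
  }
  fQ <- 1 - f1 - f2

  piR <- pi["A"] + pi["G"]
  piY <- pi["C"] + pi["T"]
  k1 <- 2 * pi["A"] * pi["G"] / piR
  k2 <- 2 * pi["T"] * pi["C"] / piY
  k3 <- 2 * (piR * piY - pi["A"] * pi["G"] * piY / piR -
               pi["T"] * pi["C"] * piR / piY)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      p <- p_mat[i, j]
      if (p == 0) next
      P1 <- p * f1
      P2 <- p * f2
      Q <- p * fQ
      w1 <- 1 - P1 / k1 - Q / (2 * piR)
      w2 <- 1 - P2 / k2 - Q / (2 * piY)
      w3 <- 1 - Q / (2 * piR * piY)
      if (min(w1, w2, w3) <= 0) {
        stop(sprintf("saturated pair %s / %s: composite distance undefined",
                     rownames(M)[i], rownames(M)[j]), call. = FALSE)
      }
      d[i, j] <- d[j, i] <-
        as.numeric(-k1 * log(w1) - k2 * log(w2) - k3 * log(w3))
    }
  }
  structure(list(d = d, usable = usable, pi = pi, model = model,
                 transition_fractions = c(AG = f1, CT = f2)),
            class = "distance_result")
}

.as_dist_matrix <- function(d) {
  if (inherits(d, "distance_result")) d <- d$d
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  d
}

#' Neighbor-joining starting tree
#'
#' Saitou-Nei neighbor joining; negative branch lengths are set to zero with
#' the deficit transferred to the adjacent (parent-side) branch.
#'
#' @param d A `distance_result` or symmetric matrix.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  dm <- .as_dist_matrix(d)
  tree <- ape::nj(stats::as.dist(dm))
  .clamp_negative_branches(tree)
}

.clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    e <- neg[1L]
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    parent <- tree$edge[e, 1L]
    up <- which(tree$edge[, 2L] == parent)
    if (length(up) == 1L) {
      tree$edge.length[up] <- tree$edge.length[up] + deficit
      if (tree$edge.length[up] < 0) tree$edge.length[up] <- 0
    }
  }
  tree
}

# OLS branch lengths for a fixed topology: solve the path design system
# d(i,j) ~ sum of branch lengths on the path between i and j.
.ols_fit <- function(tree, dm) {
  tips <- tree$tip.label
  n <- length(tips)
  ne <- nrow(tree$edge)
  # edge sets on the path from each node to the root of the edge table
  nn <- max(tree$edge)
  path_up <- vector("list", nn)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  path_up[[root]] <- integer(0)
  # children ordered so parents are resolved first
  ord <- order(tree$edge[, 1L])  # parents numbered root-first in phylo
  repeat {
    done <- TRUE
    for (e in seq_len(ne)) {
      child <- tree$edge[e, 2L]
      par <- tree$edge[e, 1L]
      if (is.null(path_up[[child]]) && !is.null(path_up[[par]])) {
        path_up[[child]] <- c(path_up[[par]], e)
        done <- FALSE
      }
    }
    if (done) break
  }
  pairs <- utils::combn(n, 2L)
  np <- ncol(pairs)
  X <- matrix(0, np, ne)
  y <- numeric(np)
  for (p in seq_len(np)) {
    i <- pairs[1L, p]
    j <- pairs[2L, p]
    pi_ <- path_up[[i]]
    pj <- path_up[[j]]
    sym <- c(setdiff(pi_, pj), setdiff(pj, pi_))
    X[p, sym] <- 1
    y[p] <- dm[tips[i], tips[j]]
  }
  beta <- qr.coef(qr(X), y)
  beta[is.na(beta)] <- 0
  list(lengths = beta, total = sum(beta))
}

#' OLS minimum-evolution tree length
#'
#' @param tree A `phylo` topology.
#' @param d A `distance_result` or symmetric matrix.
#' @return List `lengths` (raw OLS branch lengths, may be negative) and
#'   `total` (their sum, the ME criterion).
#' @export
ols_tree_length <- function(tree, d) {
  dm <- .as_dist_matrix(d)
  .ols_fit(ape::unroot(tree), dm)
}

#' Minimum-evolution search by nearest-neighbor interchange
#'
#' Steepest-descent hill-climb: all NNI neighbors of the current tree are
#' scored by OLS total branch length and the best strictly improving
#' neighbor is accepted (ties broken by sorted newick string), until a local
#' optimum is reached. Deterministic for a given start tree.
#'
#' @param tree Starting `phylo` tree (e.g. from [nj_tree()]).
#' @param d A `distance_result` or symmetric matrix.
#' @return A `phylo` tree with OLS branch lengths (clamped at 0 for
#'   reporting; the raw criterion value is attribute `"ols_total"`).
#' @export
me_search <- function(tree, d) {
  dm <- .as_dist_matrix(d)
  cur <- ape::unroot(tree)
  cur_fit <- .ols_fit(cur, dm)
  if (length(cur$tip.label) >= 4L) {
    repeat {
      nbrs <- phangorn::nni(cur)
      # multiPhylo stores tip labels compressed; [[ ]] restores them
      nbrs <- lapply(seq_along(nbrs), function(i) nbrs[[i]])
      best_tree <- NULL
      best_total <- cur_fit$total
      best_key <- ""
      for (nb in nbrs) {
        fit <- .ols_fit(nb, dm)
        key <- ape::write.tree(.sorted_topology(nb))
        if (fit$total < best_total - 1e-12 ||
            (!is.null(best_tree) && abs(fit$total - best_total) <= 1e-12 &&
               key < best_key)) {
          best_tree <- nb
          best_total <- fit$total
          best_key <- key
        }
      }
      if (is.null(best_tree)) break
      cur <- best_tree
      cur_fit <- .ols_fit(cur, dm)
    }
  }
  cur$edge.length <- pmax(cur_fit$lengths, 0)
  attr(cur, "ols_total") <- cur_fit$total
  attr(cur, "ols_lengths") <- cur_fit$lengths
  cur
}

.sorted_topology <- function(tree) {
  tree$edge.length <- NULL
  ape::rotateConstr(tree, sort(tree$tip.label))
}

# Canonical bipartition keys of the unrooted tree's internal edges: each
# split is represented by the sorted tip set on the side NOT containing the
# alphabetically first taxon.
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n <- length(tips)
  anchor <- sort(tips)[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- character(0)
  for (cl in pp) {
    side <- labs[cl]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (anchor %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap a minimum-evolution tree
#'
#' Resamples alignment columns with replacement, rebuilds composite
#' distances, the NJ start tree and the ME tree for each replicate, and
#' reports for each internal branch of the full-data tree the percentage of
#' replicates containing the same bipartition.
#'
#' @param aln An [aligned_set()].
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed; replicates are deterministic given the seed.
#' @param model Distance model, see [pairwise_distance()].
#' @return An object of class `supported_tree`: list with `tree` (`phylo`
#'   with support percentages as internal node labels), `support` (data
#'   frame split/percent) and `n_reps`.
#' @export
bootstrap_tree <- function(aln, n_reps = 1000L, seed = 1L,
                           model = "tn93_composite") {
  if (!inherits(aln, "aligned_set")) aln <- aligned_set(aln)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  M <- .aln_matrix(aln)
  base_tree <- me_search(nj_tree(pairwise_distance(aln, model)),
                         pairwise_distance(aln, model))
  base_splits <- tree_splits(base_tree)
  counts <- stats::setNames(numeric(length(base_splits)), base_splits)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      rep_aln <- aligned_set(stats::setNames(
        apply(M[, cols, drop = FALSE], 1L, paste, collapse = ""),
        rownames(M)
      ))
      rep_tree <- tryCatch(
        me_search(nj_tree(pairwise_distance(rep_aln, model)),
                  pairwise_distance(rep_aln, model)),
        error = function(e) NULL
      )
      if (is.null(rep_tree)) next
      hit <- base_splits %in% tree_splits(rep_tree)
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- 100 * counts / n_reps
  tree <- .attach_support(base_tree, support)
  structure(list(tree = tree, n_reps = n_reps,
                 support = data.frame(split = names(support),
                                      percent = as.numeric(support),
                                      stringsAsFactors = FALSE)),
            class = "supported_tree")
}

# node labels on internal nodes whose edge corresponds to each split
.attach_support <- function(tree, support) {
  tree <- ape::unroot(tree)
  tips <- tree$tip.label
  n <- length(tips)
  anchor <- sort(tips)[1L]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  node_lab <- rep("", tree$Nnode)
  for (idx in seq_along(pp)) {
    side <- labs[pp[[idx]]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    key_side <- if (anchor %in% side) setdiff(tips, side) else side
    key <- paste(sort(key_side), collapse = "|")
    if (key %in% names(support)) {
      node_lab[idx] <- format(round(support[[key]], 1L), trim = TRUE)
    }
  }
  tree$node.label <- node_lab
  tree
}

#' Test monophyly of labeled leaf sets
#'
#' A label is monophyletic when some bipartition of the unrooted tree
#' contains exactly that label's leaves (labels of size 1 or n are trivially
#' monophyletic).
#'
#' @param tree A `phylo` tree (a `supported_tree` is also accepted).
#' @param labels Named character vector mapping every leaf to a label.
#' @return Data frame `label`, `n_leaves`, `monophyletic`.
#' @export
test_monophyly <- function(tree, labels) {
  if (inherits(tree, "supported_tree")) tree <- tree$tree
  tips <- tree$tip.label
  if (!all(tips %in% names(labels))) {
    stop("every leaf must be labeled", call. = FALSE)
  }
  labels <- labels[tips]
  anchor <- sort(tips)[1L]
  splits <- tree_splits(tree)
  out <- lapply(unique(labels), function(lb) {
    set <- tips[labels == lb]
    mono <- if (length(set) <= 1L || length(set) >= length(tips) - 1L) {
      TRUE
    } else {
      key_side <- if (anchor %in% set) setdiff(tips, set) else set
      paste(sort(key_side), collapse = "|") %in% splits
    }
    data.frame(label = lb, n_leaves = length(set), monophyletic = mono,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Extract the extracellular alignment of a synthetic locus
#'
#' Synthetic genes are generated without indels, so the concatenated
#' leader + Ig-domain region is a true alignment across genes.
#'
#' @param locus A `synthetic_locus`.
#' @param segments Domain kinds to concatenate (default leader + Ig).
#' @return An [aligned_set()].
#' @export
locus_alignment <- function(locus, segments = c("leader", "ig_domain")) {
  stopifnot(inherits(locus, "synthetic_locus"))
  td <- locus$truth$domains
  fs <- locus$truth$disablements
  drop <- fs$gene_id[fs$kind == "frameshift"]
  ids <- setdiff(locus$truth$genes$id, drop)
  seqs <- vapply(ids, function(id) {
    dd <- td[td$gene_id == id & td$kind %in% segments, , drop = FALSE]
    paste(substring(locus$genes[[id]], dd$cds_start, dd$cds_end), collapse = "")
  }, character(1L))
  aligned_set(seqs)
}

#' Write a supported tree as newick
#'
#' Branch lengths come from the OLS fit; bootstrap percentages appear as
#' internal node labels.
#'
#' @param st A `supported_tree` (or `phylo`).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_supported_newick <- function(st, path) {
  tree <- if (inherits(st, "supported_tree")) st$tree else st
  ape::write.tree(tree, file = path)
  invisible(path)
}
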