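# Synthetic receptor-locus generator.
#
# Emulates the statistical structure of a two-clade Ig-like receptor
# expansion: groups of paralogs that are highly similar within a group but
# only ~two-thirds identical between groups, a long-tailed/short-tailed gene
# dichotomy, pseudogenes disabled by independent mutations, and paired-end
# reads drawn from per-gene abundances with substitution errors. All output
# carries full ground truth so downstream classification, read assignment
# and phylogenetics can be validated exactly.

#' Default receptor domain template
#'
#' Segment layout of a two-Ig-domain receptor: a 60-nt leader, two 294-nt
#' Ig-like domains, a 69-nt transmembrane segment and a cytoplasmic tail
#' (225 nt, i.e. the 75-aa long variant; the short variant is 9 aa).
#'
#' @return A data frame with columns `kind` and `length_nt`.
#' @export
default_domain_template <- function() {
  data.frame(
    kind = c("leader", "ig_domain", "ig_domain", "tm", "cyt_tail"),
    length_nt = c(60L, 294L, 294L, 69L, 225L),
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic receptor locus
#'
#' @param n_groups Number of divergent gene groups (clades).
#' @param genes_per_group Genes per group.
#' @param inter_group_identity Target pairwise nucleotide identity between
#'   genes of different groups (measured over the template region shared by
#'   all genes: leader + Ig domains + TM).
#' @param intra_group_identity_range Length-2 numeric, the (lo, hi) band for
#'   pairwise identity within a group.
#' @param domain_template Data frame of segment kinds and lengths; Ig-domain
#'   and TM lengths must be positive multiples of 3.
#' @param tail_variants Named integer vector `c(long =, short =)` giving the
#'   cytoplasmic-tail lengths in amino acids.
#' @param pseudogene_fraction Fraction of genes to disable.
#' @param disablement_kinds Subset of `c("premature_stop", "frameshift")`.
#' @param seed Integer seed; the same spec and seed reproduce the locus
#'   byte-identically.
#' @return An object of class `locus_spec`.
#' @export
locus_spec <- function(n_groups = 2L,
                       genes_per_group = 5L,
                       inter_group_identity = 0.67,
                       intra_group_identity_range = c(0.90, 0.98),
                       domain_template = default_domain_template(),
                       tail_variants = c(long = 75L, short = 9L),
                       pseudogene_fraction = 0,
                       disablement_kinds = c("premature_stop", "frameshift"),
                       seed = 1L) {
  stopifnot(n_groups >= 1L, genes_per_group >= 1L)
  lo <- intra_group_identity_range[1L]
  hi <- intra_group_identity_range[2L]
  if (!(inter_group_identity > 0 && inter_group_identity < lo &&
        lo <= hi && hi <= 1)) {
    stop("identity constraints must satisfy 0 < inter < intra_lo <= intra_hi <= 1",
         call. = FALSE)
  }
  if (pseudogene_fraction < 0 || pseudogene_fraction > 1) {
    stop("pseudogene_fraction must lie in [0, 1]", call. = FALSE)
  }
  disablement_kinds <- match.arg(disablement_kinds,
                                 c("premature_stop", "frameshift"),
                                 several.ok = TRUE)
  stopifnot(is.data.frame(domain_template),
            all(c("kind", "length_nt") %in% names(domain_template)))
  kinds <- domain_template$kind
  if (sum(kinds == "tm") != 1L || sum(kinds == "cyt_tail") != 1L ||
      sum(kinds == "ig_domain") < 1L) {
    stop("domain template needs >= 1 ig_domain, exactly one tm and one cyt_tail",
         call. = FALSE)
  }
  codon_kinds <- kinds %in% c("ig_domain", "tm")
  if (any(domain_template$length_nt[codon_kinds] %% 3L != 0L) ||
      any(domain_template$length_nt <= 0L)) {
    stop("ig_domain and tm segment lengths must be positive multiples of 3",
         call. = FALSE)
  }
  if (domain_template$length_nt[kinds == "leader"] %% 3L != 0L) {
    stop("leader length must be a multiple of 3", call. = FALSE)
  }
  stopifnot(all(c("long", "short") %in% names(tail_variants)))
  structure(
    list(
      n_groups = as.integer(n_groups),
      genes_per_group = as.integer(genes_per_group),
      inter_group_identity = inter_group_identity,
      intra_group_identity_range = c(lo, hi),
      domain_template = domain_template,
      tail_variants = as.integer(tail_variants[c("long", "short")]),
      pseudogene_fraction = pseudogene_fraction,
      disablement_kinds = disablement_kinds,
      seed = as.integer(seed)
    ),
    class = "locus_spec"
  )
}

#' Mutate a sequence to a target ungapped identity
#'
#' Substitutes exactly `round((1 - target_identity) * nchar(seq))` positions,
#' each to a uniformly drawn alternative base, so the realized identity is
#' deterministic given the length. With `preserve_frame` no substitution
#' creates a stop codon in the reading frame starting at position 1.
#'
#' @param seq Nucleotide string.
#' @param target_identity Fraction in (0, 1].
#' @param preserve_frame Avoid creating in-frame stop codons.
#' @param seed Integer seed.
#' @return A mutated string of the same length.
#' @export
mutate_to_identity <- function(seq, target_identity, preserve_frame = FALSE,
                               seed = 1L) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L) {
    stop("`seq` must be a single non-empty string", call. = FALSE)
  }
  if (target_identity <= 0 || target_identity > 1) {
    stop("target_identity must lie in (0, 1]", call. = FALSE)
  }
  L <- nchar(seq)
  k <- round((1 - target_identity) * L)
  if (k == 0L) return(seq)
  with_seed(seed, {
    chars <- seq_chars(seq)
    pool <- seq_len(L)
    if (preserve_frame) pool <- pool[pool <= (L %/% 3L) * 3L]
    chars_seq(mutate_exact(chars, pool, k, frame_guard = preserve_frame))
  })
}

# ---- internal template machinery -------------------------------------------

ITIM_BLOCK <- "GTGACCTATGCCCAGCTG"  # VTYAQL: (I/L/V/S)xYxx(L/V)
# xTy codons code only Leu/Val/Ile/Phe/Met (all hydrophobic), so a TM built
# from them tolerates substitutions at codon positions 1 and 3 without ever
# losing hydrophobicity; position 2 (always T) is the only protected one.
TM_CODONS <- c("ATA", "ATC", "ATG", "ATT", "CTA", "CTC", "CTG", "CTT",
               "GTA", "GTC", "GTG", "GTT", "TTA", "TTC", "TTG", "TTT")

# Build the root gene parts as character vectors, one element per nt.
# Also returns, per part, the pool of mutable positions (relative, 1-based).
.build_root_parts <- function(spec, itim_aa_starts = c(11L, 41L)) {
  tpl <- spec$domain_template
  parts <- list()
  pools <- list()
  ig_i <- 0L
  for (r in seq_len(nrow(tpl))) {
    kind <- tpl$kind[r]
    len <- tpl$length_nt[r]
    if (kind == "leader") {
      s <- c(seq_chars("ATG"), seq_chars(chars_seq(random_codons(len / 3L - 1L))))
      parts$leader <- s
      pools$leader <- 4L:len
    } else if (kind == "ig_domain") {
      ig_i <- ig_i + 1L
      nm <- paste0("ig", ig_i)
      cods <- random_codons(len / 3L)
      if (ig_i == 2L) cods[len / 6L] <- "CAG"  # guaranteed Gln for CAG>TAG edits
      parts[[nm]] <- seq_chars(chars_seq(cods))
      pools[[nm]] <- seq_len(len)
    } else if (kind == "tm") {
      n_cod <- len / 3L
      cods <- sample(TM_CODONS, n_cod, replace = TRUE)
      # the mid-TM codon is fixed to CTG (Leu) so the activating-gene
      # arginine edit (CTG>CGG) costs a single nucleotide
      arg_slot <- n_cod %/% 2L
      cods[arg_slot] <- "CTG"
      parts$tm <- seq_chars(chars_seq(cods))
      pools$tm <- setdiff(seq_len(len)[-seq(2L, len, by = 3L)],
                          (arg_slot * 3L - 2L):(arg_slot * 3L))
      tm_arg_codon <- arg_slot
    }
  }
  long_aa <- spec$tail_variants[1L]
  short_aa <- spec$tail_variants[2L]
  tail_long <- random_codons(long_aa)
  it_starts <- itim_aa_starts[itim_aa_starts + 5L <= long_aa]
  protected_nt <- integer(0)
  for (s in it_starts) {
    tail_long[s:(s + 5L)] <- substring(ITIM_BLOCK,
                                       seq(1L, 16L, by = 3L),
                                       seq(3L, 18L, by = 3L))
    protected_nt <- c(protected_nt, ((s - 1L) * 3L + 1L):((s + 5L) * 3L))
  }
  parts$tail_long <- seq_chars(chars_seq(tail_long))
  pools$tail_long <- setdiff(seq_len(long_aa * 3L), protected_nt)
  parts$tail_short <- seq_chars(chars_seq(random_codons(short_aa)))
  pools$tail_short <- seq_len(short_aa * 3L)
  list(parts = parts, pools = pools, itim_aa_starts = it_starts,
       tm_arg_codon = tm_arg_codon)
}

# distribute k_total substitutions over parts proportionally to their
# mutable-pool sizes (largest-remainder rounding, deterministic)
.allocate_counts <- function(pools, k_total) {
  sizes <- lengths(pools)
  raw <- k_total * sizes / sum(sizes)
  k <- floor(raw)
  rem <- k_total - sum(k)
  if (rem > 0L) {
    o <- order(raw - k, decreasing = TRUE)
    k[o[seq_len(rem)]] <- k[o[seq_len(rem)]] + 1L
  }
  stats::setNames(as.integer(k), names(pools))
}

# Parts making up the comparable (shared) template region, in order.
.common_part_names <- function(parts) {
  setdiff(names(parts), c("tail_long", "tail_short"))
}

# Solve (1-e)^2 + e^2/3 = x for the smaller root e.
.solve_channel_rate <- function(x) {
  disc <- 4 - (16 / 3) * (1 - x)
  if (disc < 0) {
    stop("impossible identity constraints: target below the uniform-substitution floor",
         call. = FALSE)
  }
  (2 - sqrt(disc)) / (8 / 3)
}

# Divergence calibration over the comparable region (protected positions
# never mutate and always match). Group ancestors receive mutually disjoint
# mutation sets and gene-level mutations avoid every ancestor-mutated
# position, so a cross-group pair mismatches at exactly 2 * k_anc ancestor
# sites plus the same gene-level channel that separates within-group pairs.
# Hence k_anc = C * (intra_mid - inter) / 2 and the gene-level per-site rate
# e follows from the intra-group target alone, with variance reduced to the
# small gene-gene coincidence terms.
.divergence_rates <- function(spec, parts, pools) {
  common <- .common_part_names(parts)
  C_len <- sum(lengths(parts[common]))
  m_C <- sum(lengths(pools[common]))
  m_t <- mean(spec$intra_group_identity_range)
  q_t <- spec$inter_group_identity
  k_anc <- round(C_len * (m_t - q_t) / 2)
  if (k_anc < 1) {
    stop("impossible identity constraints: inter-group target not below intra-group",
         call. = FALSE)
  }
  m_gene <- m_C - spec$n_groups * k_anc  # mutable sites left for gene-level
  if (m_gene <= 0) {
    stop("impossible identity constraints: too many groups for this divergence",
         call. = FALSE)
  }
  X1 <- 1 - C_len * (1 - m_t) / m_gene
  if (X1 <= 0.25) {
    stop("impossible identity constraints: intra-group target unreachable",
         call. = FALSE)
  }
  e <- .solve_channel_rate(X1)
  list(e = e, k_anc = k_anc, anc_rate = k_anc / m_C)
}

.mutate_parts <- function(parts, pools, rate, jitter = 1) {
  ks <- .allocate_counts(pools[names(parts)],
                         round(rate * jitter * sum(lengths(pools[names(parts)]))))
  for (nm in names(parts)) {
    parts[[nm]] <- mutate_exact(parts[[nm]], pools[[nm]], ks[[nm]],
                                frame_guard = TRUE)
  }
  parts
}

# Ancestor divergence with mutation sets disjoint from previous ancestors'
# (tracked per part in `used`, an environment of position vectors). The
# comparable-region parts receive exactly `k_anc` substitutions; tails are
# mutated at the equivalent per-site rate.
.mutate_ancestor <- function(parts, pools, k_anc, anc_rate, used) {
  common <- .common_part_names(parts)
  tails <- setdiff(names(parts), common)
  ks <- c(.allocate_counts(pools[common], k_anc),
          .allocate_counts(pools[tails],
                           round(anc_rate * sum(lengths(pools[tails])))))
  for (nm in names(parts)) {
    k <- ks[[nm]]
    if (k == 0L) next
    avail <- setdiff(pools[[nm]], used[[nm]])
    pos <- if (k >= length(avail)) avail else sample(avail, k)
    used[[nm]] <- c(used[[nm]], pos)
    chars <- parts[[nm]]
    for (p in pos) {
      alts <- sample(setdiff(BASES, chars[p]))
      ok <- !vapply(alts, function(b) .makes_stop(chars, p, b), logical(1L))
      chars[p] <- alts[ok][1L]
    }
    parts[[nm]] <- chars
  }
  parts
}

#' Generate a synthetic receptor locus with full ground truth
#'
#' Produces a locus sequence carrying `n_groups * genes_per_group` receptor
#' genes whose pairwise identities match the spec's inter- and intra-group
#' targets, assigns each gene a true functional class (inhibitory genes carry
#' long tails with two ITIMs; activating genes carry short tails and a
#' mid-TM arginine), disables `round(pseudogene_fraction * n)` genes each by
#' an independently placed mutation, and emits GFF3-style gene models plus a
#' truth table.
#'
#' @param spec A [locus_spec()].
#' @return An object of class `synthetic_locus`: list with `locus_name`,
#'   `locus_seq`, `genes` (named CDS strings), `gff` (feature data frame),
#'   `truth` (gene, domain and disablement tables) and the input `spec`.
#' @export
generate_locus <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  with_seed(spec$seed, .generate_locus_impl(spec))
}

.generate_locus_impl <- function(spec) {
  root <- .build_root_parts(spec)
  rates <- .divergence_rates(spec, root$parts, root$pools)
  n_genes <- spec$n_groups * spec$genes_per_group

  # true classes: round(pf * n) pseudogenes placed by a seeded draw,
  # remaining functional genes alternate inhibitory / activating
  n_pg <- round(spec$pseudogene_fraction * n_genes)
  pg_idx <- if (n_pg > 0L) sort(sample(n_genes, n_pg)) else integer(0)
  classes <- character(n_genes)
  flip <- TRUE
  for (i in seq_len(n_genes)) {
    if (i %in% pg_idx) {
      classes[i] <- "pseudogene"
    } else {
      classes[i] <- if (flip) "inhibitory" else "activating"
      flip <- !flip
    }
  }
  # pseudogene scaffolds alternate tails too (short-tailed ones get the TM Arg)
  scaffold <- ifelse(classes == "inhibitory", "long",
                     ifelse(classes == "activating", "short",
                            rep_len(c("short", "long"), n_genes)))

  tm_arg_codon <- root$tm_arg_codon  # mid-TM codon index (1-based)

  genes <- character(0)
  gene_rows <- list()
  domain_rows <- list()
  disable_rows <- list()
  used_disablements <- character(0)
  gi <- 0L
  ord_counts <- new.env(parent = emptyenv())

  anc_used <- new.env(parent = emptyenv())
  for (nm in names(root$parts)) anc_used[[nm]] <- integer(0)
  ancestors <- lapply(seq_len(spec$n_groups), function(g) {
    .mutate_ancestor(root$parts, root$pools, rates$k_anc, rates$anc_rate,
                     anc_used)
  })
  # gene-level mutations avoid every ancestor-mutated position
  gene_pools <- root$pools
  for (nm in names(gene_pools)) {
    gene_pools[[nm]] <- setdiff(gene_pools[[nm]], anc_used[[nm]])
  }
  for (g in seq_len(spec$n_groups)) {
    anc <- ancestors[[g]]
    for (j in seq_len(spec$genes_per_group)) {
      gi <- gi + 1L
      id <- sprintf("G%d_%02d", g, j)
      jit <- stats::runif(1L, 0.95, 1.05)
      gp <- .mutate_parts(anc, gene_pools, rates$e, jitter = jit)
      tail_kind <- scaffold[gi]
      tail_part <- if (tail_kind == "long") gp$tail_long else gp$tail_short
      if (tail_kind == "short") {
        # activating configuration: basic residue mid-TM (CTG > CGG, Arg)
        tm <- gp$tm
        tm[((tm_arg_codon - 1L) * 3L + 1L):(tm_arg_codon * 3L)] <- seq_chars("CGG")
        gp$tm <- tm
      }
      common <- .common_part_names(gp)
      seg_chars <- c(gp[common], list(cyt_tail = tail_part))
      cds <- c(unlist(seg_chars, use.names = FALSE), seq_chars("TAA"))

      # domain coordinates on the CDS (1-based inclusive), before disablement
      seg_kinds <- c(vapply(common, function(nm) {
        if (nm == "leader") "leader" else if (nm == "tm") "tm" else "ig_domain"
      }, character(1L)), "cyt_tail")
      seg_len <- vapply(seg_chars, length, integer(1L))
      seg_end <- cumsum(seg_len)
      seg_start <- seg_end - seg_len + 1L

      dis <- NULL
      if (classes[gi] == "pseudogene") {
        res <- .apply_disablement(cds, spec$disablement_kinds, used_disablements)
        cds <- res$cds
        dis <- res$row
        used_disablements <- c(used_disablements, res$key)
        if (res$row$kind == "frameshift") {
          shift <- res$row$detail_n
          after <- seg_start > res$row$cds_pos
          seg_start[after] <- seg_start[after] - shift
          seg_end[seg_end >= res$row$cds_pos] <-
            seg_end[seg_end >= res$row$cds_pos] - shift
        }
      }

      genes[id] <- chars_seq(cds)
      gene_rows[[gi]] <- data.frame(
        id = id, group = g, class = classes[gi], tail_kind = tail_kind,
        cds_len = length(cds), stringsAsFactors = FALSE
      )
      domain_rows[[gi]] <- data.frame(
        gene_id = id, kind = seg_kinds, cds_start = seg_start,
        cds_end = seg_end, stringsAsFactors = FALSE
      )
      if (!is.null(dis)) {
        dis$gene_id <- id
        disable_rows[[length(disable_rows) + 1L]] <- dis
      }
    }
  }

  truth_genes <- do.call(rbind, gene_rows)
  truth_domains <- do.call(rbind, domain_rows)
  truth_dis <- if (length(disable_rows)) do.call(rbind, disable_rows) else
    data.frame(kind = character(0), cds_pos = integer(0), detail = character(0),
               detail_n = integer(0), gene_id = character(0),
               stringsAsFactors = FALSE)

  # assembled names under the family naming scheme (functional genes only)
  truth_genes$assigned_name <- NA_character_
  for (i in seq_len(nrow(truth_genes))) {
    cl <- truth_genes$class[i]
    if (cl %in% c("inhibitory", "activating")) {
      truth_genes$assigned_name[i] <-
        assign_gene_name("SYNLILR", truth_genes$group[i], cl, ordinal = i)
    }
  }

  # lay genes on a locus with random intergenic spacers
  spacer_len <- sample(300:600, n_genes + 1L, replace = TRUE)
  locus_chunks <- character(0)
  pos <- 0L
  truth_genes$locus_start <- NA_integer_
  truth_genes$locus_end <- NA_integer_
  for (i in seq_len(n_genes)) {
    sp <- chars_seq(sample(BASES, spacer_len[i], replace = TRUE))
    locus_chunks <- c(locus_chunks, sp)
    pos <- pos + spacer_len[i]
    cds <- genes[[truth_genes$id[i]]]
    locus_chunks <- c(locus_chunks, cds)
    truth_genes$locus_start[i] <- pos + 1L
    truth_genes$locus_end[i] <- pos + nchar(cds)
    pos <- pos + nchar(cds)
  }
  locus_chunks <- c(locus_chunks,
                    chars_seq(sample(BASES, spacer_len[n_genes + 1L], replace = TRUE)))
  locus_seq <- paste(locus_chunks, collapse = "")

  truth_domains$locus_start <-
    truth_domains$cds_start +
    truth_genes$locus_start[match(truth_domains$gene_id, truth_genes$id)] - 1L
  truth_domains$locus_end <-
    truth_domains$cds_end +
    truth_genes$locus_start[match(truth_domains$gene_id, truth_genes$id)] - 1L

  locus <- structure(
    list(
      spec = spec,
      locus_name = "synthetic_locus",
      locus_seq = locus_seq,
      genes = genes,
      truth = list(genes = truth_genes, domains = truth_domains,
                   disablements = truth_dis),
      gff = NULL
    ),
    class = "synthetic_locus"
  )
  locus$gff <- .locus_gff(locus)
  locus
}

# Disable a CDS by a premature stop or a 1-2 nt deletion, drawn within the
# first 80% and guaranteed distinct (kind + homologous position) from every
# previously used disablement, so that no two pseudogenes share a lesion.
.apply_disablement <- function(cds, kinds, used) {
  n_cod <- length(cds) %/% 3L
  repeat {
    kind <- if (length(kinds) == 1L) kinds else sample(kinds, 1L)
    if (kind == "premature_stop") {
      cod <- sample(2L:floor(0.8 * n_cod), 1L)
      key <- paste0("stop@", cod * 3L - 2L)
      if (key %in% used) next
      old <- chars_seq(cds[(cod * 3L - 2L):(cod * 3L)])
      new <- sample(STOP_CODONS, 1L)
      cds[(cod * 3L - 2L):(cod * 3L)] <- seq_chars(new)
      row <- data.frame(kind = "premature_stop", cds_pos = cod * 3L - 2L,
                        detail = paste0(old, ">", new), detail_n = 0L,
                        stringsAsFactors = FALSE)
      return(list(cds = cds, row = row, key = key))
    } else {
      del <- sample(1:2, 1L)
      pos <- sample(4L:floor(0.8 * length(cds)), 1L)
      key <- paste0("fs@", pos)
      if (key %in% used) next
      cds <- cds[-(pos:(pos + del - 1L))]
      row <- data.frame(kind = "frameshift", cds_pos = pos,
                        detail = paste0("del", del), detail_n = del,
                        stringsAsFactors = FALSE)
      return(list(cds = cds, row = row, key = key))
    }
  }
}

# GFF3-style feature table (1-based inclusive coordinates, + strand)
.locus_gff <- function(locus) {
  tg <- locus$truth$genes
  td <- locus$truth$domains
  rows <- list()
  for (i in seq_len(nrow(tg))) {
    id <- tg$id[i]
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = locus$locus_name, source = "lrcprofiler",
      type = c("gene", "mRNA", "CDS"),
      start = tg$locus_start[i], end = tg$locus_end[i],
      score = NA_real_, strand = "+", phase = c(NA, NA, 0L),
      ID = c(id, paste0(id, ".t1"), paste0(id, ".t1.cds")),
      Parent = c(NA, id, paste0(id, ".t1")),
      segment_kind = NA_character_, gene_id = id,
      stringsAsFactors = FALSE
    )
    dd <- td[td$gene_id == id, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = locus$locus_name, source = "lrcprofiler", type = "domain",
      start = dd$locus_start, end = dd$locus_end,
      score = NA_real_, strand = "+", phase = NA_integer_,
      ID = paste0(id, ".dom", seq_len(nrow(dd))),
      Parent = paste0(id, ".t1"), segment_kind = dd$kind, gene_id = id,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Pairwise identity matrix over the shared template region
#'
#' Identities are measured ungapped over the leader + Ig domains + TM, the
#' region present in every gene regardless of tail variant. Pairs involving
#' a frameshifted gene (whose template coordinates are no longer alignable
#' without gaps) are returned as `NA`.
#'
#' @param locus A `synthetic_locus`.
#' @return A symmetric numeric matrix with gene ids as dimnames.
#' @export
locus_identity_matrix <- function(locus) {
  stopifnot(inherits(locus, "synthetic_locus"))
  tg <- locus$truth$genes
  td <- locus$truth$domains
  fs <- locus$truth$disablements
  fs_genes <- fs$gene_id[fs$kind == "frameshift"]
  extract <- function(id) {
    dd <- td[td$gene_id == id & td$kind != "cyt_tail", , drop = FALSE]
    paste(substring(locus$genes[[id]], dd$cds_start, dd$cds_end), collapse = "")
  }
  seqs <- vapply(tg$id, extract, character(1L))
  n <- length(seqs)
  m <- matrix(NA_real_, n, n, dimnames = list(tg$id, tg$id))
  diag(m) <- 1
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (tg$id[i] %in% fs_genes || tg$id[j] %in% fs_genes) next
      m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]])
    }
  }
  m
}

#' Generate a long-tailed/short-tailed novel gene pair
#'
#' Builds two paralogous gene models from one template: the long-tailed gene
#' has a 75-aa (by default) cytoplasmic tail with two ITIMs and an uncharged
#' TM; the short-tailed gene has a short tail and an arginine unusually close
#' to the TM's extracellular boundary. Their membrane-distal Ig domains
#' differ by exactly `distal_diff_nt` nucleotides (synonymous where
#' possible), their membrane-proximal domains by exactly `proximal_diff_nt`,
#' one of which is a CAG>TAG glutamine-to-stop change when `introduce_stop`.
#'
#' @param base_spec A [locus_spec()] providing template dimensions and seed.
#' @param distal_diff_nt Substitutions in the membrane-distal Ig domain.
#' @param proximal_diff_nt Substitutions in the membrane-proximal Ig domain.
#' @param introduce_stop Make one proximal difference a CAG>TAG stop.
#' @param seed Integer seed.
#' @return List with elements `long` and `short`, each containing `id`,
#'   `seq` (CDS string), `domains` (CDS-relative coordinates) and
#'   `tail_kind`; plus `distal_region`/`proximal_region` coordinates shared
#'   by the pair.
#' @export
generate_paired_novel_genes <- function(base_spec = locus_spec(),
                                        distal_diff_nt = 1L,
                                        proximal_diff_nt = 13L,
                                        introduce_stop = TRUE,
                                        seed = 1L) {
  stopifnot(inherits(base_spec, "locus_spec"))
  with_seed(seed, {
    root <- .build_root_parts(base_spec)
    p <- root$parts
    ig1_len <- length(p$ig1)
    ig2_len <- length(p$ig2)
    if (distal_diff_nt > ig1_len || proximal_diff_nt > ig2_len) {
      stop("difference counts exceed domain lengths", call. = FALSE)
    }
    if (introduce_stop && proximal_diff_nt < 1L) {
      stop("introduce_stop requires proximal_diff_nt >= 1", call. = FALSE)
    }

    q <- p
    # distal differences: synonymous third-position changes in 4-fold codons
    if (distal_diff_nt > 0L) {
      four_fold <- c("CT", "GT", "GC", "CC", "AC", "TC", "GG", "CG")
      cods <- matrix(p$ig1, nrow = 3L)
      lead2 <- apply(cods[1:2, , drop = FALSE], 2L, paste, collapse = "")
      cand <- which(lead2 %in% four_fold)
      syn <- sample(cand, min(distal_diff_nt, length(cand)))
      for (ci in syn) {
        pos <- ci * 3L
        q$ig1[pos] <- sample(setdiff(BASES, q$ig1[pos]), 1L)
      }
      extra <- distal_diff_nt - length(syn)
      if (extra > 0L) {
        pool <- setdiff(seq_len(ig1_len), as.vector(outer(1:3, (syn - 1L) * 3L, "+")))
        q$ig1 <- mutate_exact(q$ig1, pool, extra, frame_guard = TRUE)
      }
    }
    # proximal differences, optionally including the CAG>TAG stop
    n_left <- proximal_diff_nt
    stop_pos <- NA_integer_
    if (introduce_stop && n_left > 0L) {
      cods <- matrix(q$ig2, nrow = 3L)
      cag <- which(apply(cods, 2L, paste, collapse = "") == "CAG")
      if (length(cag) == 0L) stop("template proximal domain lacks a CAG codon",
                                  call. = FALSE)
      ci <- cag[1L]
      q$ig2[(ci - 1L) * 3L + 1L] <- "T"
      stop_pos <- (ci - 1L) * 3L + 1L
      n_left <- n_left - 1L
    }
    if (n_left > 0L) {
      pool <- setdiff(seq_len(ig2_len),
                      if (is.na(stop_pos)) integer(0) else stop_pos:(stop_pos + 2L))
      q$ig2 <- mutate_exact(q$ig2, pool, n_left, frame_guard = TRUE)
    }
    # short-tailed gene: boundary-proximal TM arginine (codon 2 of the TM)
    q$tm[4:6] <- seq_chars("CGT")

    assemble <- function(parts, tail_kind) {
      common <- .common_part_names(parts)
      tail_part <- if (tail_kind == "long") parts$tail_long else parts$tail_short
      segs <- c(parts[common], list(cyt_tail = tail_part))
      kinds <- c(vapply(common, function(nm) {
        if (nm == "leader") "leader" else if (nm == "tm") "tm" else "ig_domain"
      }, character(1L)), "cyt_tail")
      seg_len <- vapply(segs, length, integer(1L))
      seg_end <- cumsum(seg_len)
      list(
        seq = paste0(chars_seq(unlist(segs, use.names = FALSE)), "TAA", collapse = ""),
        domains = data.frame(kind = kinds, cds_start = seg_end - seg_len + 1L,
                             cds_end = seg_end, stringsAsFactors = FALSE)
      )
    }
    a <- assemble(p, "long")
    b <- assemble(q, "short")
    ig_rows <- which(a$domains$kind == "ig_domain")
    structure(list(
      long = list(id = "novel_long", seq = a$seq, domains = a$domains,
                  tail_kind = "long"),
      short = list(id = "novel_short", seq = b$seq, domains = b$domains,
                   tail_kind = "short"),
      distal_region = c(a$domains$cds_start[ig_rows[1L]],
                        a$domains$cds_end[ig_rows[1L]]),
      proximal_region = c(a$domains$cds_start[ig_rows[2L]],
                          a$domains$cds_end[ig_rows[2L]]),
      stop_cds_pos = if (is.na(stop_pos)) NA_integer_ else
        stop_pos + a$domains$cds_end[ig_rows[1L]]
    ), class = "novel_gene_pair")
  })
}

#' Simulate paired-end reads from transcript sequences
#'
#' Reads originate from a gene with probability proportional to
#' `abundance * transcript_length`, with uniform fragment start positions,
#' normal fragment lengths (mean 300, sd 30, truncated at the read length and
#' the transcript length) and independent per-base substitution errors.
#'
#' @param genes Named character vector of transcript (spliced CDS) sequences.
#' @param abundances Named non-negative weights, same names as `genes`.
#' @param n_reads Number of fragments to simulate.
#' @param read_len Read length in nt (default 100).
#' @param paired Emit read pairs (2 x `read_len`).
#' @param error_rate Per-base substitution error rate in `[0, 0.5)`.
#' @param seed Integer seed.
#' @param fragment_mean,fragment_sd Fragment-length distribution parameters.
#' @return An object of class `read_sim`: list with `reads` (named character
#'   vector), `qual` (fixed Q30 strings), `truth` (data frame read_id,
#'   source_gene, position, n_errors) and the simulation parameters.
#' @export
simulate_reads <- function(genes, abundances, n_reads, read_len = 100L,
                           paired = TRUE, error_rate = 0.005, seed = 1L,
                           fragment_mean = 300, fragment_sd = 30) {
  stopifnot(is.character(genes), length(genes) >= 1L, !is.null(names(genes)))
  if (n_reads <= 0L) stop("n_reads must be positive", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.5) {
    stop("error_rate must lie in [0, 0.5)", call. = FALSE)
  }
  if (is.null(names(abundances))) names(abundances) <- names(genes)
  abundances <- abundances[names(genes)]
  if (any(is.na(abundances)) || any(abundances < 0) || sum(abundances) <= 0) {
    stop("abundances must be non-negative with a positive sum", call. = FALSE)
  }
  lens <- nchar(genes)
  w <- abundances * lens
  with_seed(seed, {
    origin <- sample(names(genes), n_reads, replace = TRUE, prob = w / sum(w))
    L <- lens[origin]
    fl <- pmin(pmax(round(stats::rnorm(n_reads, fragment_mean, fragment_sd)),
                    read_len), L)
    start <- floor(stats::runif(n_reads) * (L - fl + 1)) + 1L
    r1 <- substr(genes[origin], start, pmin(start + read_len - 1L, start + fl - 1L))
    ids <- sprintf("read%07d", seq_len(n_reads))
    if (paired) {
      s2 <- start + fl - read_len
      s2 <- pmax(s2, start)
      r2 <- revcomp(substr(genes[origin], s2, start + fl - 1L))
      reads <- c(r1, r2)
      names(reads) <- c(paste0(ids, "/1"), paste0(ids, "/2"))
      pos <- c(start, s2)
      src <- c(origin, origin)
    } else {
      reads <- r1
      names(reads) <- ids
      pos <- start
      src <- origin
    }
    # substitution errors
    n_err <- stats::rbinom(length(reads), nchar(reads), error_rate)
    which_err <- which(n_err > 0L)
    for (i in which_err) {
      ch <- seq_chars(reads[[i]])
      at <- sample(length(ch), n_err[i])
      for (pp in at) ch[pp] <- sample(setdiff(BASES, ch[pp]), 1L)
      reads[[i]] <- chars_seq(ch)
    }
    truth <- data.frame(
      read_id = names(reads), source_gene = unname(src),
      position = unname(pos), n_errors = unname(n_err),
      stringsAsFactors = FALSE
    )
    structure(list(
      reads = reads,
      qual = stats::setNames(strrep("?", nchar(reads)), names(reads)),
      truth = truth, n_fragments = n_reads, read_len = read_len,
      paired = paired, error_rate = error_rate, seed = seed
    ), class = "read_sim")
  })
}
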