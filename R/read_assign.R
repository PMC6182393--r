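# Paralog-aware read assignment and FPKM quantification.
#
# Reads aligned to a set of near-identical paralogs are assigned in tiers:
# a read whose hits all fall in one gene group counts for that group; within
# single-group reads, a unique best-scoring hit at >= 99% identity (default)
# promotes the read to the gene tier; score ties always demote to the group
# tier rather than picking arbitrarily. Genes with annotated unique regions
# (e.g. TM + cytoplasmic tail) can additionally be quantified from reads
# overlapping those regions only.

#' Build a reference set for read assignment
#'
#' @param ids Gene identifiers.
#' @param groups Group (clade) label per gene.
#' @param seqs Named or unnamed CDS sequences, parallel to `ids`.
#' @param unique_regions Optional data frame `gene_id`, `start`, `end`
#'   (1-based inclusive CDS coordinates) marking each gene's unique region.
#' @param functional Optional logical vector, marks genes whose lengths enter
#'   the group-level FPKM denominator (default all).
#' @return An object of class `reference_set` (a data frame).
#' @export
reference_set <- function(ids, groups, seqs, unique_regions = NULL,
                          functional = NULL) {
  stopifnot(length(ids) == length(groups), length(ids) == length(seqs))
  if (anyDuplicated(ids)) stop("gene ids must be unique", call. = FALSE)
  rs <- data.frame(id = as.character(ids), group = as.character(groups),
                   seq = unname(as.character(seqs)),
                   length = nchar(seqs),
                   unique_start = NA_integer_, unique_end = NA_integer_,
                   functional = if (is.null(functional)) TRUE else functional,
                   stringsAsFactors = FALSE)
  if (!is.null(unique_regions)) {
    i <- match(unique_regions$gene_id, rs$id)
    if (anyNA(i)) stop("unique_regions name unknown gene ids", call. = FALSE)
    bad <- unique_regions$start < 1L | unique_regions$end > rs$length[i] |
      unique_regions$start > unique_regions$end
    if (any(bad)) stop("unique regions must lie within their CDS", call. = FALSE)
    rs$unique_start[i] <- unique_regions$start
    rs$unique_end[i] <- unique_regions$end
  }
  class(rs) <- c("reference_set", "data.frame")
  rs
}

#' Reference set from a synthetic locus
#'
#' @param locus A `synthetic_locus`.
#' @param unique_region `"none"` or `"tm_tail"` (marks TM + cytoplasmic tail
#'   + terminal stop as each gene's unique region).
#' @return A [reference_set()].
#' @export
reference_set_from_locus <- function(locus, unique_region = c("none", "tm_tail")) {
  unique_region <- match.arg(unique_region)
  tg <- locus$truth$genes
  ur <- NULL
  if (unique_region == "tm_tail") {
    td <- locus$truth$domains
    tm <- td[td$kind == "tm", c("gene_id", "cds_start")]
    ur <- data.frame(gene_id = tm$gene_id, start = tm$cds_start,
                     end = tg$cds_len[match(tm$gene_id, tg$id)])
  }
  reference_set(tg$id, tg$group, locus$genes[tg$id], unique_regions = ur,
                functional = tg$class != "pseudogene")
}

#' Align reads to a paralogous reference set
#'
#' Seed-and-extend local alignment: exact k-mer seeds on both strands,
#' followed by banded Smith-Waterman resolution (match +1, mismatch -1,
#' gap -2 by default). For each read, all references with a local alignment
#' of identity >= `min_identity` (matches / alignment length) and length >=
#' `min_aln_len` are reported, each with its best-scoring alignment.
#'
#' @param reads Named character vector of read sequences (or a `read_sim`).
#' @param refs A [reference_set()].
#' @param min_identity Minimum identity to report a hit (default 0.90).
#' @param min_aln_len Minimum alignment length (default 50).
#' @param k Seed length (default 15).
#' @param band Half-width of the banded extension (default 5).
#' @param match,mismatch,gap Alignment scores.
#' @return Data frame of hits: `read_id`, `gene_id`, `strand`, `score`,
#'   `matches`, `aln_len`, `identity`, read and reference intervals
#'   (1-based inclusive).
#' @export
align_reads <- function(reads, refs, min_identity = 0.90, min_aln_len = 50L,
                        k = 15L, band = 5L, match = 1L, mismatch = -1L,
                        gap = -2L) {
  if (inherits(reads, "read_sim")) reads <- reads$reads
  if (!is.character(reads) || length(reads) == 0L || is.null(names(reads))) {
    stop("`reads` must be a non-empty named character vector", call. = FALSE)
  }
  if (!inherits(refs, "reference_set") || nrow(refs) == 0L) {
    stop("`refs` must be a non-empty reference_set", call. = FALSE)
  }
  seqs <- stats::setNames(refs$seq, refs$id)
  align_reads_cpp(reads, seqs, as.integer(k), min_identity,
                  as.integer(min_aln_len), as.integer(band),
                  as.integer(match), as.integer(mismatch), as.integer(gap))
}

#' Tiered assignment of aligned reads
#'
#' Applies the group tier ([group logic][assign_reads]) and gene tier in one
#' pass: reads whose hits span more than one group are flagged `cross_group`
#' and excluded from all counts; reads with hits in exactly one group count
#' for that group, and are promoted to a specific gene when a unique
#' highest-scoring hit reaches `cutoff` identity (ties demote to the group
#' tier); reads without hits are `unassigned`.
#'
#' @param hits Data frame from [align_reads()].
#' @param refs A [reference_set()].
#' @param read_ids Optional character vector of all read ids, so that reads
#'   without any hit appear as `unassigned`.
#' @param cutoff Gene-tier identity cutoff in (0, 1], default 0.99.
#' @param min_margin Minimum score lead of the best hit over the runner-up
#'   for gene-tier promotion (default 3, i.e. more than one substitution of
#'   evidence); exact ties and near-ties demote to the group tier.
#' @return Data frame with one row per read: `read_id`, `tier`
#'   (`gene`/`group`/`unassigned`), `unit` (gene id, group label or `NA`),
#'   `group`, `cross_group`.
#' @export
assign_reads <- function(hits, refs, read_ids = NULL, cutoff = 0.99,
                         min_margin = 3L) {
  if (cutoff <= 0 || cutoff > 1) {
    stop("cutoff must lie in (0, 1]", call. = FALSE)
  }
  stopifnot(inherits(refs, "reference_set"))
  ht <- data.table::as.data.table(hits)
  ht[, grp := refs$group[match(gene_id, refs$id)]]
  per_read <- ht[, {
    ng <- data.table::uniqueN(grp)
    if (ng > 1L) {
      list(tier = "cross", unit = NA_character_, group = NA_character_)
    } else {
      top <- which.max(score)
      margin <- if (.N == 1L) Inf else score[top] - max(score[-top])
      if (margin >= min_margin && identity[top] >= cutoff) {
        list(tier = "gene", unit = gene_id[top], group = grp[1L])
      } else {
        list(tier = "group", unit = grp[1L], group = grp[1L])
      }
    }
  }, by = read_id]
  out <- data.frame(read_id = per_read$read_id, tier = per_read$tier,
                    unit = per_read$unit, group = per_read$group,
                    cross_group = per_read$tier == "cross",
                    stringsAsFactors = FALSE)
  out$tier[out$tier == "cross"] <- "unassigned"
  out$unit[out$tier == "unassigned"] <- NA_character_
  if (!is.null(read_ids)) {
    missing <- setdiff(read_ids, out$read_id)
    if (length(missing)) {
      out <- rbind(out, data.frame(read_id = missing, tier = "unassigned",
                                   unit = NA_character_, group = NA_character_,
                                   cross_group = FALSE, stringsAsFactors = FALSE))
    }
    out <- out[match(read_ids, out$read_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Per-group read counts with cross-group exclusion
#'
#' @param assignment Data frame from [assign_reads()].
#' @return List with `counts` (named integer vector per group, gene-tier
#'   reads included in their group), `cross_group` (read ids flagged) and
#'   `unassigned` (count).
#' @export
group_counts <- function(assignment) {
  ok <- !is.na(assignment$group)
  counts <- table(assignment$group[ok])
  list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    cross_group = assignment$read_id[assignment$cross_group],
    unassigned = sum(assignment$tier == "unassigned" & !assignment$cross_group)
  )
}

#' Per-gene read counts at the gene tier
#'
#' @param assignment Data frame from [assign_reads()].
#' @param refs A [reference_set()]; genes without gene-tier reads report 0.
#' @return Named integer vector over all reference genes.
#' @export
gene_counts <- function(assignment, refs) {
  g <- assignment$unit[assignment$tier == "gene"]
  counts <- stats::setNames(integer(nrow(refs)), refs$id)
  t <- table(g)
  counts[names(t)] <- as.integer(t)
  counts
}

#' Region-restricted gene counts
#'
#' Counts a read for a gene only when its best hit on that gene overlaps the
#' gene's annotated unique region by at least `min_overlap` reference
#' positions, and the gene-tier rules (unique best score, identity >=
#' `cutoff`) hold among the region-overlapping hits.
#'
#' @param hits Data frame from [align_reads()].
#' @param refs A [reference_set()] whose counted genes carry unique regions.
#' @param min_overlap Minimum overlap in reference nt (default 25).
#' @param cutoff Identity cutoff (default 0.99).
#' @param min_margin Score margin for promotion, as in [assign_reads()].
#' @return List with `counts` (named integer vector over the unique-region
#'   genes) and `assignment` (read_id -> gene data frame).
#' @export
region_restricted_count <- function(hits, refs, min_overlap = 25L,
                                    cutoff = 0.99, min_margin = 3L) {
  stopifnot(inherits(refs, "reference_set"))
  ur <- refs[!is.na(refs$unique_start), , drop = FALSE]
  if (nrow(ur) == 0L) {
    stop("no gene in the reference set has a unique region", call. = FALSE)
  }
  ht <- data.table::as.data.table(hits)
  ht <- ht[gene_id %in% ur$id]
  i <- match(ht$gene_id, ur$id)
  ov <- pmin(ht$ref_end, ur$unique_end[i]) - pmax(ht$ref_start, ur$unique_start[i]) + 1L
  ht <- ht[!is.na(ov) & ov >= min_overlap]
  counts <- stats::setNames(integer(nrow(ur)), ur$id)
  if (nrow(ht) == 0L) {
    return(list(counts = counts,
                assignment = data.frame(read_id = character(0),
                                        gene_id = character(0))))
  }
  per_read <- ht[, {
    top <- which.max(score)
    margin <- if (.N == 1L) Inf else score[top] - max(score[-top])
    if (margin >= min_margin && identity[top] >= cutoff) {
      list(gene = gene_id[top])
    } else {
      list(gene = NA_character_)
    }
  }, by = read_id]
  per_read <- per_read[!is.na(gene)]
  t <- table(per_read$gene)
  counts[names(t)] <- as.integer(t)
  list(counts = counts,
       assignment = data.frame(read_id = per_read$read_id,
                               gene_id = per_read$gene,
                               stringsAsFactors = FALSE))
}

#' Fragments per kilobase of transcript per million sequenced reads
#'
#' `FPKM = count * 1e9 / (length_nt * total_reads)`; a zero count gives 0.
#'
#' @param count Read count(s), non-negative.
#' @param length_nt Transcript length(s) in nt, positive.
#' @param total_reads Total sequenced reads in the sample, positive.
#' @return Numeric FPKM value(s).
#' @export
compute_fpkm <- function(count, length_nt, total_reads) {
  if (any(length_nt <= 0)) stop("length_nt must be positive", call. = FALSE)
  if (any(total_reads <= 0)) stop("total_reads must be positive", call. = FALSE)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  count * 1e9 / (length_nt * total_reads)
}

#' Tally an assignment into unit-level counts
#'
#' @param assignment Data frame from [assign_reads()].
#' @param refs A [reference_set()].
#' @return Data frame `unit`, `unit_type` (`gene`/`group`), `count`; group
#'   counts include gene-tier reads of that group.
#' @export
tally_assignment <- function(assignment, refs) {
  gc <- gene_counts(assignment, refs)
  grp <- group_counts(assignment)$counts
  all_groups <- sort(unique(refs$group))
  grp_full <- stats::setNames(integer(length(all_groups)), all_groups)
  grp_full[names(grp)] <- grp
  rbind(
    data.frame(unit = names(gc), unit_type = "gene", count = as.integer(gc),
               stringsAsFactors = FALSE),
    data.frame(unit = names(grp_full), unit_type = "group",
               count = as.integer(grp_full), stringsAsFactors = FALSE)
  )
}

#' Summarize expression across samples
#'
#' Computes per-sample and pooled counts and FPKM for every gene and group,
#' the mean and (n-1)-denominator standard deviation of per-sample FPKM, and
#' the unaccounted summary (group totals minus gene-assigned totals, with
#' the percentage rounded to 1 decimal). Group FPKM uses the mean CDS length
#' of the group's functional members as the transcript length.
#'
#' @param sample_counts Named list (one element per sample) of count data
#'   frames as returned by [tally_assignment()].
#' @param refs A [reference_set()].
#' @param totals Named numeric vector of total sequenced reads per sample.
#' @return An object of class `expression_summary`: list with `table`
#'   (unit, unit_type, sample, count, fpkm; includes `POOLED` rows),
#'   `stats` (per-unit mean/sd of per-sample FPKM) and `unaccounted`.
#' @export
summarize_expression <- function(sample_counts, refs, totals) {
  stopifnot(inherits(refs, "reference_set"), length(sample_counts) >= 1L)
  samples <- names(sample_counts)
  if (is.null(samples) || anyNA(match(samples, names(totals)))) {
    stop("sample_counts and totals must share sample names", call. = FALSE)
  }
  groups <- sort(unique(refs$group))
  glen <- vapply(groups, function(g) {
    memb <- refs[refs$group == g & refs$functional, , drop = FALSE]
    if (nrow(memb) == 0L) memb <- refs[refs$group == g, , drop = FALSE]
    mean(memb$length)
  }, numeric(1L))
  unit_len <- c(stats::setNames(refs$length, refs$id), stats::setNames(glen, groups))

  rows <- lapply(samples, function(s) {
    cnt <- sample_counts[[s]]
    data.frame(unit = cnt$unit, unit_type = cnt$unit_type, sample = s,
               count = cnt$count,
               fpkm = compute_fpkm(cnt$count, unit_len[cnt$unit], totals[[s]]),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  pooled <- stats::aggregate(count ~ unit + unit_type, data = tab, FUN = sum)
  pooled$sample <- "POOLED"
  pooled$fpkm <- compute_fpkm(pooled$count, unit_len[pooled$unit], sum(totals[samples]))
  tab <- rbind(tab, pooled[, c("unit", "unit_type", "sample", "count", "fpkm")])

  per_sample <- tab[tab$sample != "POOLED", , drop = FALSE]
  stats_df <- do.call(rbind, lapply(split(per_sample, per_sample$unit), function(d) {
    data.frame(unit = d$unit[1L], unit_type = d$unit_type[1L],
               mean_fpkm = mean(d$fpkm),
               sd_fpkm = if (nrow(d) > 1L) stats::sd(d$fpkm) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(stats_df) <- NULL

  pooled_units <- stats::setNames(pooled$count, pooled$unit)
  gene_by_group <- tapply(
    pooled_units[refs$id],
    refs$group,
    sum
  )
  unacc <- data.frame(
    group = groups,
    group_total = as.integer(pooled_units[groups]),
    gene_assigned = as.integer(gene_by_group[groups]),
    stringsAsFactors = FALSE
  )
  overall <- data.frame(group = "ALL",
                        group_total = sum(unacc$group_total),
                        gene_assigned = sum(unacc$gene_assigned),
                        stringsAsFactors = FALSE)
  unacc <- rbind(unacc, overall)
  unacc$unaccounted <- unacc$group_total - unacc$gene_assigned
  unacc$unaccounted_pct <- round(100 * unacc$unaccounted / unacc$group_total, 1L)

  structure(list(table = tab, stats = stats_df, unaccounted = unacc),
            class = "expression_summary")
}

#' Read-count arithmetic over printed group and gene totals
#'
#' Convenience for the unaccounted-read summary when only aggregate counts
#' are available: combined total over groups, reads not accounted for at the
#' gene tier, and the unaccounted percentage rounded to 1 decimal.
#'
#' @param group_totals Numeric vector of group-level read totals.
#' @param gene_assigned_total Total reads assigned at the gene tier.
#' @return List `combined_total`, `unaccounted`, `unaccounted_pct`.
#' @export
unaccounted_summary <- function(group_totals, gene_assigned_total) {
  total <- sum(group_totals)
  un <- total - gene_assigned_total
  list(combined_total = total, unaccounted = un,
       unaccounted_pct = round(100 * un / total, 1L))
}

#' Splice-junction support for an internal candidate segment
#'
#' Given the transcript context around a candidate internal segment (e.g. a
#' degenerate internal Ig-domain fragment), counts reads that support its
#' exclusion (reads spanning the upstream/downstream junction with at least
#' `flank` nt on each side and no candidate sequence), its inclusion (reads
#' spanning either candidate boundary with `flank` nt on each side), and
#' reads specific to the segment itself. Both read strands are searched.
#'
#' @param reads Named character vector of read sequences.
#' @param upstream,candidate,downstream Sequence of the upstream exon, the
#'   candidate internal segment and the downstream exon.
#' @param flank Required anchor length on each side of a junction (default
#'   20); must not exceed half the shortest read.
#' @param max_mismatch Mismatches tolerated in junction matching (default 0).
#' @return List `exclusion`, `inclusion`, `segment_specific` (counts) plus
#'   `reads` (ids per category).
#' @export
splice_junction_support <- function(reads, upstream, candidate, downstream,
                                    flank = 20L, max_mismatch = 0L) {
  stopifnot(is.character(reads), !is.null(names(reads)))
  if (flank > min(nchar(reads)) / 2) {
    stop("flank exceeds half the read length", call. = FALSE)
  }
  take_tail <- function(s, n) substring(s, nchar(s) - n + 1L, nchar(s))
  take_head <- function(s, n) substring(s, 1L, n)
  junc_excl <- paste0(take_tail(upstream, flank), take_head(downstream, flank))
  junc_in5 <- paste0(take_tail(upstream, flank), take_head(candidate, flank))
  junc_in3 <- paste0(take_tail(candidate, flank), take_head(downstream, flank))

  subj <- Biostrings::DNAStringSet(c(reads, revcomp(reads)))
  hits_in <- function(pattern) {
    n <- length(reads)
    cnt <- Biostrings::vcountPattern(pattern, subj, max.mismatch = max_mismatch)
    which(cnt[seq_len(n)] + cnt[n + seq_len(n)] > 0L)
  }
  excl <- hits_in(junc_excl)
  incl <- sort(union(hits_in(junc_in5), hits_in(junc_in3)))
  # segment-specific: the read maps inside the candidate segment only
  seg <- Biostrings::DNAString(candidate)
  seg_specific <- integer(0)
  if (nchar(candidate) >= min(nchar(reads))) {
    in_seg <- vapply(seq_along(reads), function(i) {
      r <- reads[[i]]
      sum(Biostrings::countPattern(r, seg, max.mismatch = max_mismatch),
          Biostrings::countPattern(revcomp(r), seg,
                                   max.mismatch = max_mismatch)) > 0L
    }, logical(1L))
    seg_specific <- setdiff(which(in_seg), union(excl, incl))
  }
  list(
    exclusion = length(excl), inclusion = length(incl),
    segment_specific = length(seg_specific),
    reads = list(exclusion = names(reads)[excl],
                 inclusion = names(reads)[incl],
                 segment_specific = names(reads)[seg_specific])
  )
}
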