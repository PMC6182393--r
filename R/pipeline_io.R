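# Shared format I/O, configuration and the end-to-end pipeline.
#
# Sequence formats go through Biostrings, annotation through
# rtracklayer/GenomicRanges. Package-internal coordinates are 1-based
# inclusive (the native R/GFF3 convention); BED output converts to 0-based
# half-open at the boundary. Every stochastic stage takes an explicit seed.

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_fasta <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path),
                error = function(e) stop(sprintf("FASTA parse error in %s: %s",
                                                 path, conditionMessage(e)),
                                         call. = FALSE))
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line width (default 70).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (Phred+33 qualities).
#' @return List with `seq` and `qual`, both named character vectors.
#' @export
read_fastq <- function(path) {
  parsed <- tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    list(seqs = as.character(x),
         quals = as.character(S4Vectors::mcols(x)$qualities),
         ids = sub("\\s.*$", "", names(x)))
  }, error = function(e) {
    stop(sprintf("FASTQ parse error in %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  seqs <- parsed$seqs
  quals <- parsed$quals
  ids <- parsed$ids
  if (any(nchar(seqs) != nchar(quals))) {
    bad <- which(nchar(seqs) != nchar(quals))[1L]
    stop(sprintf("FASTQ parse error in %s: sequence/quality length mismatch at record %d",
                 path, bad), call. = FALSE)
  }
  list(seq = stats::setNames(seqs, ids), qual = stats::setNames(quals, ids))
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param seqs Named character vector of reads.
#' @param path Output file.
#' @param qual Optional named character vector of quality strings; defaults
#'   to fixed Q30 (`?`).
#' @return The path, invisibly.
#' @export
write_fastq <- function(seqs, path, qual = NULL) {
  if (is.null(qual)) qual <- strrep("?", nchar(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(unname(qual))
  )
  invisible(path)
}

#' Parse a GFF3 file
#'
#' @param path GFF3 file.
#' @return Data frame with columns `seqid`, `source`, `type`, `start`,
#'   `end`, `score`, `strand`, `phase` plus any attribute columns (`ID`,
#'   `Parent`, `segment_kind`, ...). Coordinates 1-based inclusive.
#' @export
parse_gff3 <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop(sprintf("GFF3 parse error in %s: %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    source = as.character(S4Vectors::mcols(gr)$source),
    type = as.character(S4Vectors::mcols(gr)$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    score = S4Vectors::mcols(gr)$score,
    strand = as.character(GenomicRanges::strand(gr)),
    phase = as.integer(S4Vectors::mcols(gr)$phase),
    stringsAsFactors = FALSE
  )
  extra <- S4Vectors::mcols(gr)
  extra <- extra[, setdiff(colnames(extra), c("source", "type", "score", "phase")),
                 drop = FALSE]
  for (nm in colnames(extra)) {
    v <- extra[[nm]]
    if (methods::is(v, "CharacterList") || is.list(v)) {
      v <- vapply(v, function(e) if (length(e)) paste(e, collapse = ",") else
        NA_character_, character(1L))
    }
    df[[nm]] <- v
  }
  df
}

#' Write a GFF3 feature table
#'
#' @param gff Data frame as produced by the generator or [parse_gff3()].
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_gff3 <- function(gff, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = gff$seqid,
    ranges = IRanges::IRanges(start = gff$start, end = gff$end),
    strand = ifelse(is.na(gff$strand), "*", gff$strand)
  )
  S4Vectors::mcols(gr)$source <- gff$source
  S4Vectors::mcols(gr)$type <- gff$type
  S4Vectors::mcols(gr)$score <- gff$score
  S4Vectors::mcols(gr)$phase <- gff$phase
  for (nm in setdiff(names(gff), c("seqid", "source", "type", "start", "end",
                                   "score", "strand", "phase"))) {
    S4Vectors::mcols(gr)[[nm]] <- gff[[nm]]
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write simulated reads and their origin truth
#'
#' @param sim A `read_sim` from [simulate_reads()].
#' @param dir Output directory.
#' @param prefix File-name prefix (default `"reads"`).
#' @return Character vector of written paths, invisibly.
#' @export
write_reads <- function(sim, dir, prefix = "reads") {
  stopifnot(inherits(sim, "read_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (sim$paired) {
    is1 <- grepl("/1$", names(sim$reads))
    p1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
    p2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
    write_fastq(sim$reads[is1], p1, sim$qual[is1])
    write_fastq(sim$reads[!is1], p2, sim$qual[!is1])
    paths <- c(paths, p1, p2)
  } else {
    p <- file.path(dir, paste0(prefix, ".fastq"))
    write_fastq(sim$reads, p, sim$qual)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, paste0(prefix, "_truth.tsv"))
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, tp))
}

#' Write a synthetic locus to disk
#'
#' Emits the locus FASTA, the per-gene CDS FASTA, the GFF3 annotation and
#' the truth tables (TSV). The generation seed is recorded in the FASTA
#' headers.
#'
#' @param locus A `synthetic_locus`.
#' @param dir Output directory.
#' @return Named character vector of paths, invisibly.
#' @export
write_locus <- function(locus, dir) {
  stopifnot(inherits(locus, "synthetic_locus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  locus_fa <- file.path(dir, "locus.fasta")
  seqs <- stats::setNames(locus$locus_seq,
                          sprintf("%s seed=%d", locus$locus_name, locus$spec$seed))
  write_fasta(seqs, locus_fa)
  genes_fa <- file.path(dir, "genes.fasta")
  write_fasta(locus$genes, genes_fa)
  gff_path <- file.path(dir, "locus.gff3")
  write_gff3(locus$gff, gff_path)
  truth_genes <- file.path(dir, "truth_genes.tsv")
  utils::write.table(locus$truth$genes, truth_genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_dis <- file.path(dir, "truth_disablements.tsv")
  utils::write.table(locus$truth$disablements, truth_dis, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(locus = locus_fa, genes = genes_fa, gff = gff_path,
              genes_truth = truth_genes, disablements = truth_dis))
}

# ---- configuration ---------------------------------------------------------

.default_config <- function() {
  list(
    seed = 1L,
    stages = list(simulate = TRUE, annotate = TRUE, quantify = TRUE,
                  phylo = TRUE, dotplot = TRUE),
    simulate = list(
      n_groups = 2L, genes_per_group = 5L, inter_group_identity = 0.67,
      intra_identity_lo = 0.90, intra_identity_hi = 0.98,
      pseudogene_fraction = 0.2, n_reads = 20000L, read_len = 100L,
      paired = TRUE, error_rate = 0.005, n_samples = 3L
    ),
    annotate = list(long_tail_min_aa = 30L, min_itims = 1L,
                    proximal_max = 3L, tm_window = 19L, tm_threshold = 1.6),
    quantify = list(min_identity = 0.90, min_aln_len = 50L, cutoff = 0.99,
                    min_overlap = 25L),
    phylo = list(bootstrap = 200L, model = "tn93_composite"),
    dotplot = list(window = 200L, step = 50L, min_identity = 0.8,
                   min_windows = 3L)
  )
}

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected; parameters outside their documented ranges
#' abort before any stage runs. The seed is mandatory: stochastic stages
#' never fall back to clock seeding.
#'
#' @param ... Overrides merged over the defaults, e.g.
#'   `pipeline_config(seed = 7, quantify = list(cutoff = 0.99))`.
#' @return A validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .default_config()
  over <- list(...)
  merge_block <- function(base, upd, path) {
    unknown <- setdiff(names(upd), names(base))
    if (length(unknown)) {
      stop(sprintf("unknown configuration key(s): %s",
                   paste(paste0(path, unknown), collapse = ", ")), call. = FALSE)
    }
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        base[[nm]] <- merge_block(base[[nm]], upd[[nm]], paste0(path, nm, "."))
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  cfg <- merge_block(cfg, over, "")
  .validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with the same structure as [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
load_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.validate_config <- function(cfg) {
  in_range <- function(x, lo, hi, name, open_lo = FALSE, open_hi = FALSE) {
    ok <- if (open_lo) x > lo else x >= lo
    ok <- ok && if (open_hi) x < hi else x <= hi
    if (!ok) stop(sprintf("configuration value out of range: %s = %s", name, x),
                  call. = FALSE)
  }
  in_range(cfg$quantify$cutoff, 0, 1, "quantify.cutoff", open_lo = TRUE)
  in_range(cfg$quantify$min_identity, 0, 1, "quantify.min_identity")
  in_range(cfg$simulate$error_rate, 0, 0.5, "simulate.error_rate", open_hi = TRUE)
  in_range(cfg$simulate$pseudogene_fraction, 0, 1, "simulate.pseudogene_fraction")
  in_range(cfg$simulate$inter_group_identity, 0, 1, "simulate.inter_group_identity",
           open_lo = TRUE)
  in_range(cfg$dotplot$min_identity, 0, 1, "dotplot.min_identity")
  if (cfg$phylo$bootstrap < 1L) stop("phylo.bootstrap must be >= 1", call. = FALSE)
  if (!is.numeric(cfg$seed)) stop("a numeric seed is mandatory", call. = FALSE)
  invisible(TRUE)
}

# ---- end-to-end pipeline ---------------------------------------------------

#' Run the full analysis pipeline on a synthetic locus
#'
#' Chains simulate, annotate, quantify, phylo and dotplot according to
#' the stage toggles. Every output file and every effective parameter is
#' recorded in `run_log.txt`; identical configuration and seed reproduce
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c("# lrcprofiler run log",
                 paste0("seed: ", config$seed),
                 paste0("config: ", .flatten_config(config)))
  results <- list()
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }

  locus <- NULL
  sims <- NULL
  if (isTRUE(config$stages$simulate)) {
    res <- tryCatch({
      sc <- config$simulate
      spec <- locus_spec(
        n_groups = sc$n_groups, genes_per_group = sc$genes_per_group,
        inter_group_identity = sc$inter_group_identity,
        intra_group_identity_range = c(sc$intra_identity_lo, sc$intra_identity_hi),
        pseudogene_fraction = sc$pseudogene_fraction,
        seed = config$seed
      )
      locus <- generate_locus(spec)
      paths <- write_locus(locus, file.path(out_dir, "simulate"))
      abund <- with_seed(config$seed + 1L,
                         stats::setNames(stats::rlnorm(length(locus$genes)),
                                         names(locus$genes)))
      sims <- lapply(seq_len(sc$n_samples), function(s) {
        sim <- simulate_reads(locus$genes, abund, sc$n_reads,
                              read_len = sc$read_len, paired = sc$paired,
                              error_rate = sc$error_rate,
                              seed = config$seed + 100L + s)
        write_reads(sim, file.path(out_dir, "simulate"),
                    prefix = sprintf("sample%02d", s))
        sim
      })
      names(sims) <- sprintf("sample%02d", seq_len(sc$n_samples))
      list(locus = locus, sims = sims, paths = paths, abundances = abund)
    }, error = function(e) fail("simulate", e))
    locus <- res$locus
    sims <- res$sims
    results$simulate <- res
    log_lines <- c(log_lines, "stage simulate: ok",
                   paste0("  genes: ", length(locus$genes)),
                   paste0("  samples: ", length(sims)))
  }

  if (isTRUE(config$stages$annotate)) {
    if (is.null(locus)) stop("annotate requires the simulate stage", call. = FALSE)
    res <- tryCatch({
      ac <- config$annotate
      cls <- classify_locus(locus, classify_params(
        long_tail_min_aa = ac$long_tail_min_aa, min_itims = ac$min_itims,
        proximal_max = ac$proximal_max, tm_window = ac$tm_window,
        tm_threshold = ac$tm_threshold
      ))
      dir.create(file.path(out_dir, "annotate"), showWarnings = FALSE)
      p <- file.path(out_dir, "annotate", "classification.tsv")
      utils::write.table(cls, p, sep = "\t", quote = FALSE, row.names = FALSE)
      gff <- locus$gff
      gff$receptor_class <- cls$call[match(gff$gene_id, cls$gene_id)]
      write_gff3(gff, file.path(out_dir, "annotate", "annotated.gff3"))
      cls
    }, error = function(e) fail("annotate", e))
    results$annotate <- res
    log_lines <- c(log_lines, "stage annotate: ok",
                   paste0("  calls: ", paste(names(table(res$call)),
                                             table(res$call), sep = "=",
                                             collapse = " ")))
  }

  if (isTRUE(config$stages$quantify)) {
    if (is.null(sims)) stop("quantify requires the simulate stage", call. = FALSE)
    res <- tryCatch({
      qc <- config$quantify
      refs <- reference_set_from_locus(locus)
      counts <- lapply(sims, function(sim) {
        hits <- align_reads(sim$reads, refs, min_identity = qc$min_identity,
                            min_aln_len = qc$min_aln_len)
        tally_assignment(assign_reads(hits, refs, read_ids = names(sim$reads),
                                      cutoff = qc$cutoff), refs)
      })
      totals <- vapply(sims, function(sim) length(sim$reads), numeric(1L))
      summ <- summarize_expression(counts, refs, totals)
      dir.create(file.path(out_dir, "quantify"), showWarnings = FALSE)
      utils::write.table(summ$table,
                         file.path(out_dir, "quantify", "expression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(summ$unaccounted,
                         file.path(out_dir, "quantify", "unaccounted.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summ
    }, error = function(e) fail("quantify", e))
    results$quantify <- res
    log_lines <- c(log_lines, "stage quantify: ok")
  }

  if (isTRUE(config$stages$phylo)) {
    if (is.null(locus)) stop("phylo requires the simulate stage", call. = FALSE)
    res <- tryCatch({
      aln <- locus_alignment(locus)
      st <- bootstrap_tree(aln, n_reps = config$phylo$bootstrap,
                           seed = config$seed, model = config$phylo$model)
      dir.create(file.path(out_dir, "phylo"), showWarnings = FALSE)
      write_supported_newick(st, file.path(out_dir, "phylo", "me_tree.nwk"))
      dd <- pairwise_distance(aln, config$phylo$model)
      utils::write.table(dd$d, file.path(out_dir, "phylo", "distances.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      labels <- stats::setNames(
        paste0("group", locus$truth$genes$group), locus$truth$genes$id
      )[names(unclass(aln))]
      mono <- test_monophyly(st, labels)
      utils::write.table(mono, file.path(out_dir, "phylo", "monophyly.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(tree = st, monophyly = mono)
    }, error = function(e) fail("phylo", e))
    results$phylo <- res
    log_lines <- c(log_lines, "stage phylo: ok")
  }

  if (isTRUE(config$stages$dotplot)) {
    if (is.null(locus)) stop("dotplot requires the simulate stage", call. = FALSE)
    res <- tryCatch({
      dc <- config$dotplot
      # compare the locus against a rearranged copy: one inverted block and
      # one insertion, placed deterministically from the seed
      alt <- with_seed(config$seed + 2L, {
        s <- locus$locus_seq
        L <- nchar(s)
        inv_len <- min(2000L, L %/% 10L)
        inv_s <- L %/% 4L
        ins_len <- min(2000L, L %/% 10L)
        ins_at <- (3L * L) %/% 4L
        block <- revcomp(substr(s, inv_s, inv_s + inv_len - 1L))
        s2 <- paste0(substr(s, 1L, inv_s - 1L), block,
                     substr(s, inv_s + inv_len, L))
        paste0(substr(s2, 1L, ins_at),
               chars_seq(sample(BASES, ins_len, replace = TRUE)),
               substr(s2, ins_at + 1L, nchar(s2)))
      })
      grid <- compute_grid(locus$locus_seq, alt, window = dc$window,
                           step = dc$step)
      report <- detect_segments(grid, min_identity = dc$min_identity,
                                min_windows = dc$min_windows)
      dir.create(file.path(out_dir, "dotplot"), showWarnings = FALSE)
      utils::write.table(report$segments,
                         file.path(out_dir, "dotplot", "segments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_unmatched_bed(report, c("assembly_a", "assembly_b"),
                          file.path(out_dir, "dotplot", "unmatched.bed"))
      report
    }, error = function(e) fail("dotplot", e))
    results$dotplot <- res
    log_lines <- c(log_lines, "stage dotplot: ok")
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

.flatten_config <- function(cfg) {
  flat <- unlist(cfg)
  paste(names(flat), flat, sep = "=", collapse = " ")
}
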