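# Functional classification of Ig-like receptor gene models.
#
# Evidence gathered per gene: standard-code translation with internal-stop
# reporting, ITIM motif scan of the cytoplasmic tail, Kyte-Doolittle
# hydropathy TM prediction, charged TM residues with their offset from the
# extracellular boundary, and disablement (premature stop / frameshift)
# detection. Calls follow a fixed precedence:
# fragment > pseudogene > inhibitory > activating > ambiguous.

#' Construct a receptor gene model
#'
#' @param id Gene identifier.
#' @param cds_segments Data frame (or 2-column matrix) of `start`, `end`
#'   genomic intervals, 1-based inclusive, ordered 5' to 3' in coding
#'   orientation.
#' @param strand `"+"` or `"-"`.
#' @param domain_segments Optional data frame with columns `kind`
#'   (`leader`, `ig_domain`, `tm`, `cyt_tail`) and CDS-relative `cds_start`,
#'   `cds_end`.
#' @param source_sequence_id Name of the sequence the coordinates refer to.
#' @param indels Optional data frame of annotated indels with columns
#'   `cds_pos` and `shift` (net frame shift in nt).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(id, cds_segments, strand = "+",
                       domain_segments = NULL, source_sequence_id = NA_character_,
                       indels = NULL) {
  cds_segments <- as.data.frame(cds_segments)
  names(cds_segments)[1:2] <- c("start", "end")
  stopifnot(all(cds_segments$end >= cds_segments$start), strand %in% c("+", "-"))
  if (!is.null(domain_segments)) {
    domain_segments <- as.data.frame(domain_segments)
    stopifnot(all(c("kind", "cds_start", "cds_end") %in% names(domain_segments)))
    o <- order(domain_segments$cds_start)
    domain_segments <- domain_segments[o, , drop = FALSE]
    if (any(domain_segments$cds_start[-1L] <=
            domain_segments$cds_end[-nrow(domain_segments)])) {
      stop("domain segments must be non-overlapping and ordered", call. = FALSE)
    }
  }
  structure(list(id = id, strand = strand, cds_segments = cds_segments,
                 domain_segments = domain_segments,
                 source_sequence_id = source_sequence_id, indels = indels),
            class = "gene_model")
}

# concatenated CDS nucleotide sequence in coding orientation
.model_cds <- function(model, sequence) {
  parts <- substring(sequence, model$cds_segments$start, model$cds_segments$end)
  cds <- paste(parts, collapse = "")
  if (model$strand == "-") cds <- revcomp(cds)
  cds
}

#' Translate a gene model's CDS
#'
#' Standard genetic code, frame from the first annotated CDS base. Internal
#' stop codons are reported with their CDS coordinates; a terminal stop is
#' not counted as internal. A trailing partial codon (CDS length not a
#' multiple of 3) is dropped from the translation and reported.
#'
#' @param model A [gene_model()].
#' @param sequence The source sequence (single string) named by the model.
#' @return List with `protein` (string; internal stops as `*`),
#'   `internal_stops` (data frame `codon`, `cds_pos`) and `trailing_nt`.
#' @export
translate_cds <- function(model, sequence) {
  cds <- .model_cds(model, sequence)
  if (nchar(cds) < 3L) stop("CDS length must be >= 3", call. = FALSE)
  trailing <- nchar(cds) %% 3L
  usable <- nchar(cds) - trailing
  codons <- substring(cds, seq(1L, usable - 2L, by = 3L), seq(3L, usable, by = 3L))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, usable)),
    no.init.codon = TRUE
  ))
  is_stop <- codons %in% STOP_CODONS
  n_cod <- length(codons)
  internal <- which(is_stop & seq_along(codons) < n_cod)
  # a stop in the final codon position is terminal, not internal
  list(
    protein = aa,
    internal_stops = data.frame(codon = internal,
                                cds_pos = (internal - 1L) * 3L + 1L),
    trailing_nt = trailing
  )
}

#' Scan a cytoplasmic tail for ITIM motifs
#'
#' Reports every window matching the canonical immunoreceptor tyrosine-based
#' inhibition motif (I/L/V/S)xYxx(L/V); overlapping hits are all reported.
#'
#' @param tail Protein sequence (string); may be empty.
#' @return Data frame with `start` (1-based position of the motif's first
#'   residue) and `window` (the 6-aa match).
#' @export
scan_itim <- function(tail) {
  n <- nchar(tail)
  if (n < 6L) {
    return(data.frame(start = integer(0), window = character(0)))
  }
  ch <- seq_chars(tail)
  i <- seq_len(n - 5L)
  hit <- ch[i] %in% c("I", "L", "V", "S") & ch[i + 2L] == "Y" &
    ch[i + 5L] %in% c("L", "V")
  starts <- i[hit]
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0), window = character(0)))
  }
  data.frame(start = starts,
             window = substring(tail, starts, starts + 5L),
             stringsAsFactors = FALSE)
}

#' Predict a transmembrane segment by Kyte-Doolittle hydropathy
#'
#' Slides a window (default 19 aa) over the protein; if any window's mean
#' hydropathy exceeds `threshold`, the best-scoring window is extended
#' outwards one residue at a time while the added residue is itself
#' hydrophobic (positive index) and the extended window's mean stays above
#' the threshold.
#'
#' @param protein Protein string (no internal stops expected; `*` and `X`
#'   score as strongly hydrophilic).
#' @param window Window length in aa (default 19).
#' @param threshold Mean-hydropathy threshold (default 1.6).
#' @return Integer vector `c(start, end)` (1-based inclusive) or `NULL` when
#'   no window qualifies or the protein is shorter than the window.
#' @export
predict_tm <- function(protein, window = 19L, threshold = 1.6) {
  n <- nchar(protein)
  if (n < window) return(NULL)
  h <- KD_HYDROPATHY[seq_chars(protein)]
  h[is.na(h)] <- -4.5
  cs <- c(0, cumsum(h))
  means <- (cs[(window + 1L):(n + 1L)] - cs[seq_len(n - window + 1L)]) / window
  if (max(means) <= threshold) return(NULL)
  best <- which.max(means)
  s <- best
  e <- best + window - 1L
  repeat {
    if (s > 1L && h[s - 1L] > 0 &&
        (cs[e + 1L] - cs[s - 1L]) / (e - s + 2L) > threshold) {
      s <- s - 1L
    } else if (e < n && h[e + 1L] > 0 &&
               (cs[e + 2L] - cs[s]) / (e - s + 2L) > threshold) {
      e <- e + 1L
    } else {
      break
    }
  }
  c(start = s, end = e)
}

#' Charged residues within a transmembrane interval
#'
#' Reports every R, K, D, E or H inside the TM, with its offset from the
#' extracellular boundary (the TM start, offset 0) and whether it lies
#' unusually close to that boundary (offset <= `proximal_max`).
#'
#' @param protein Protein string.
#' @param tm_interval `c(start, end)` from [predict_tm()] or an annotation.
#' @param proximal_max Boundary-proximity threshold in aa (default 3).
#' @return Data frame `residue`, `offset`, `boundary_proximal`.
#' @export
find_charged_tm_residues <- function(protein, tm_interval, proximal_max = 3L) {
  stopifnot(length(tm_interval) == 2L,
            tm_interval[1L] >= 1L, tm_interval[2L] <= nchar(protein))
  tm <- substring(protein, tm_interval[1L], tm_interval[2L])
  ch <- seq_chars(tm)
  at <- which(ch %in% c("R", "K", "D", "E", "H"))
  data.frame(
    residue = ch[at],
    offset = at - 1L,
    boundary_proximal = (at - 1L) <= proximal_max,
    stringsAsFactors = FALSE
  )
}

#' Detect disabling mutations in a gene model
#'
#' Premature stops are internal stop codons; a frameshift is called when the
#' total CDS length is not a multiple of 3 or an annotated indel shifts the
#' frame. Stops downstream of a detected frameshift are attributed to the
#' shift and not reported separately.
#'
#' @param model A [gene_model()].
#' @param sequence Source sequence string.
#' @return Data frame `kind` (`premature_stop`/`frameshift`), `cds_pos`.
#' @export
detect_disablement <- function(model, sequence) {
  tr <- translate_cds(model, sequence)
  out <- data.frame(kind = character(0), cds_pos = integer(0),
                    stringsAsFactors = FALSE)
  fs_pos <- NA_integer_
  if (!is.null(model$indels) && nrow(model$indels) > 0L) {
    sh <- model$indels[model$indels$shift %% 3L != 0L, , drop = FALSE]
    if (nrow(sh) > 0L) fs_pos <- min(sh$cds_pos)
  }
  if (is.na(fs_pos) && tr$trailing_nt != 0L) {
    cds_len <- sum(model$cds_segments$end - model$cds_segments$start + 1L)
    fs_pos <- cds_len
  }
  stops <- tr$internal_stops
  if (!is.na(fs_pos)) {
    stops <- stops[stops$cds_pos < fs_pos, , drop = FALSE]
  }
  if (nrow(stops) > 0L) {
    out <- rbind(out, data.frame(kind = "premature_stop", cds_pos = stops$cds_pos,
                                 stringsAsFactors = FALSE))
  }
  if (!is.na(fs_pos)) {
    out <- rbind(out, data.frame(kind = "frameshift", cds_pos = fs_pos,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Shared-disablement matrix between pseudogenes
#'
#' Entry (i, j) counts disablements identical in kind and homologous CDS
#' position between pseudogenes i and j; the diagonal holds each gene's own
#' disablement count. Off-diagonal zeros support independent (post-expansion)
#' disablement.
#'
#' @param classifications List of `receptor_classification` objects, at
#'   least two of which must be pseudogenes.
#' @return Symmetric integer matrix with gene ids as dimnames.
#' @export
compare_disablements <- function(classifications) {
  calls <- vapply(classifications, function(x) x$call, character(1L))
  pg <- classifications[calls == "pseudogene"]
  if (length(pg) < 2L) {
    stop("need at least two pseudogene classifications", call. = FALSE)
  }
  ids <- vapply(pg, function(x) x$gene_id, character(1L))
  keysets <- lapply(pg, function(x) {
    d <- x$disablements
    paste(d$kind, d$cds_pos, sep = "@")
  })
  n <- length(pg)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- length(intersect(keysets[[i]], keysets[[j]]))
    }
  }
  diag(m) <- lengths(keysets)
  m
}

#' Classification parameters
#'
#' @param long_tail_min_aa Tail length (aa) at or above which a tail is
#'   "long" (default 30; separates the 75-aa and 9-aa exemplars widely).
#' @param min_itims ITIM hits required for an inhibitory call (default 1).
#' @param proximal_max Boundary-proximity threshold for TM charges.
#' @param tm_window,tm_threshold Hydropathy-scan parameters.
#' @return A parameter list.
#' @export
classify_params <- function(long_tail_min_aa = 30L, min_itims = 1L,
                            proximal_max = 3L, tm_window = 19L,
                            tm_threshold = 1.6) {
  list(long_tail_min_aa = long_tail_min_aa, min_itims = min_itims,
       proximal_max = proximal_max, tm_window = tm_window,
       tm_threshold = tm_threshold)
}

#' Classify a receptor gene model
#'
#' Gathers all evidence (translation, disablements, TM, charged TM residues,
#' tail kind, ITIMs) and applies the precedence
#' fragment > pseudogene > inhibitory > activating > ambiguous:
#' a fragment lacks a TM and most template domain kinds; any disablement
#' makes a pseudogene; a long tail with at least `min_itims` ITIMs is
#' inhibitory; a short tail with a basic (R/K) TM residue away from the
#' extracellular boundary is activating; anything else (including a
#' boundary-proximal arginine as sole evidence) is ambiguous.
#'
#' @param model A [gene_model()].
#' @param sequence Source sequence string.
#' @param params A [classify_params()] list.
#' @return An object of class `receptor_classification`.
#' @export
classify_receptor <- function(model, sequence, params = classify_params()) {
  tr <- translate_cds(model, sequence)
  protein <- tr$protein
  # drop the terminal stop from the working protein
  protein_nostop <- sub("\\*$", "", protein)
  disablements <- detect_disablement(model, sequence)

  dom <- model$domain_segments
  kinds_present <- if (!is.null(dom)) unique(dom$kind) else character(0)
  tm_annot <- NULL
  if (!is.null(dom) && "tm" %in% dom$kind) {
    r <- dom[dom$kind == "tm", , drop = FALSE][1L, ]
    tm_annot <- c(start = (r$cds_start - 1L) %/% 3L + 1L,
                  end = (r$cds_end - 1L) %/% 3L + 1L)
  }
  tm_pred <- predict_tm(protein_nostop, params$tm_window, params$tm_threshold)
  tm <- if (!is.null(tm_annot)) tm_annot else tm_pred
  has_tm <- !is.null(tm)

  charged <- if (has_tm) {
    tm_clip <- c(max(1L, tm[1L]), min(nchar(protein_nostop), tm[2L]))
    find_charged_tm_residues(protein_nostop, tm_clip, params$proximal_max)
  } else {
    data.frame(residue = character(0), offset = integer(0),
               boundary_proximal = logical(0))
  }

  # cytoplasmic tail: annotated segment if available, else after the TM
  tail <- ""
  if (!is.null(dom) && "cyt_tail" %in% dom$kind) {
    r <- dom[dom$kind == "cyt_tail", , drop = FALSE][1L, ]
    aa_s <- (r$cds_start - 1L) %/% 3L + 1L
    aa_e <- min((r$cds_end - 1L) %/% 3L + 1L, nchar(protein_nostop))
    if (aa_s <= nchar(protein_nostop)) tail <- substring(protein_nostop, aa_s, aa_e)
  } else if (has_tm && tm[2L] < nchar(protein_nostop)) {
    tail <- substring(protein_nostop, tm[2L] + 1L, nchar(protein_nostop))
  }
  tail_kind <- if (nchar(tail) == 0L) "absent"
  else if (nchar(tail) >= params$long_tail_min_aa) "long" else "short"
  itims <- scan_itim(tail)

  n_template_kinds <- 4L  # leader, ig_domain, tm, cyt_tail
  is_fragment <- !has_tm && length(kinds_present) < n_template_kinds / 2

  call <- if (is_fragment) {
    "fragment"
  } else if (nrow(disablements) > 0L) {
    "pseudogene"
  } else if (tail_kind == "long" && nrow(itims) >= params$min_itims) {
    "inhibitory"
  } else if (tail_kind == "short" &&
             any(charged$residue %in% c("R", "K") & !charged$boundary_proximal)) {
    "activating"
  } else {
    "ambiguous"
  }

  structure(list(
    gene_id = model$id, call = call, itim_hits = itims,
    tm_interval = tm, charged_tm_residues = charged,
    disablements = disablements, tail_kind = tail_kind,
    protein = protein
  ), class = "receptor_classification")
}

#' @export
print.receptor_classification <- function(x, ...) {
  cat(sprintf("<receptor_classification> %s: %s (tail %s, %d ITIM, %d disablement)\n",
              x$gene_id, x$call, x$tail_kind, nrow(x$itim_hits),
              nrow(x$disablements)))
  invisible(x)
}

#' Compose a gene name under the family naming scheme
#'
#' Names follow `<family><group><B|A><ordinal>`: "B" for inhibitory, "A" for
#' activating, the ordinal being the gene's discovery index. Only inhibitory
#' and activating receptors are named.
#'
#' @param family Family prefix, e.g. `"LILR"`.
#' @param group Group (clade) number.
#' @param call `"inhibitory"` or `"activating"`.
#' @param ordinal Positive discovery index.
#' @return The composed name, e.g. `"LILR2B10"`.
#' @export
assign_gene_name <- function(family, group, call, ordinal) {
  if (!call %in% c("inhibitory", "activating")) {
    stop("only inhibitory and activating receptors are named under the A/B scheme",
         call. = FALSE)
  }
  if (ordinal < 1L) stop("ordinal must be >= 1", call. = FALSE)
  paste0(family, group, if (call == "inhibitory") "B" else "A", ordinal)
}

#' Classify every gene of a synthetic locus
#'
#' Builds a [gene_model()] for each gene from the locus truth annotation and
#' classifies it against its CDS sequence.
#'
#' @param locus A `synthetic_locus` from [generate_locus()].
#' @param params A [classify_params()] list.
#' @return Data frame with `gene_id`, `call`, `true_class`, `n_itims`,
#'   `tail_kind`, `n_disablements`, plus the list of full classification
#'   objects as attribute `"classifications"`.
#' @export
classify_locus <- function(locus, params = classify_params()) {
  stopifnot(inherits(locus, "synthetic_locus"))
  tg <- locus$truth$genes
  td <- locus$truth$domains
  cls <- lapply(seq_len(nrow(tg)), function(i) {
    id <- tg$id[i]
    dd <- td[td$gene_id == id, c("kind", "cds_start", "cds_end")]
    cds <- locus$genes[[id]]
    model <- gene_model(id, data.frame(start = 1L, end = nchar(cds)),
                        strand = "+", domain_segments = dd,
                        source_sequence_id = id)
    classify_receptor(model, cds, params)
  })
  out <- data.frame(
    gene_id = tg$id,
    call = vapply(cls, function(x) x$call, character(1L)),
    true_class = tg$class,
    n_itims = vapply(cls, function(x) nrow(x$itim_hits), integer(1L)),
    tail_kind = vapply(cls, function(x) x$tail_kind, character(1L)),
    n_disablements = vapply(cls, function(x) nrow(x$disablements), integer(1L)),
    stringsAsFactors = FALSE
  )
  attr(out, "classifications") <- cls
  out
}

#' Build gene models from a GFF3 feature table
#'
#' Groups features by their `gene_id` attribute: `CDS` rows become the
#' model's CDS segments and `domain` rows (attribute `segment_kind`) are
#' mapped from genomic to CDS-relative coordinates.
#'
#' @param gff Data frame from [parse_gff3()] with a `gene_id` column.
#' @return Named list of [gene_model()] objects.
#' @export
gene_models_from_gff <- function(gff) {
  stopifnot(is.data.frame(gff), "gene_id" %in% names(gff))
  gff <- gff[!is.na(gff$gene_id), , drop = FALSE]
  ids <- unique(gff$gene_id[gff$type %in% c("gene", "CDS")])
  models <- lapply(ids, function(id) {
    rows <- gff[gff$gene_id == id, , drop = FALSE]
    cds <- rows[rows$type == "CDS", , drop = FALSE]
    if (nrow(cds) == 0L) return(NULL)
    strand <- cds$strand[1L]
    cds <- cds[order(cds$start), , drop = FALSE]
    # genomic -> CDS coordinate map (coding orientation)
    seg_len <- cds$end - cds$start + 1L
    cum <- cumsum(c(0L, seg_len))
    total <- sum(seg_len)
    to_cds <- function(gpos) {
      i <- which(gpos >= cds$start & gpos <= cds$end)[1L]
      if (is.na(i)) return(NA_integer_)
      off <- cum[i] + (gpos - cds$start[i]) + 1L
      if (strand == "-") total - off + 1L else off
    }
    dom <- rows[rows$type == "domain", , drop = FALSE]
    dom_df <- NULL
    if (nrow(dom) > 0L && "segment_kind" %in% names(dom)) {
      a <- vapply(dom$start, to_cds, integer(1L))
      b <- vapply(dom$end, to_cds, integer(1L))
      dom_df <- data.frame(kind = dom$segment_kind,
                           cds_start = pmin(a, b), cds_end = pmax(a, b),
                           stringsAsFactors = FALSE)
      dom_df <- dom_df[!is.na(dom_df$cds_start), , drop = FALSE]
      if (nrow(dom_df) == 0L) dom_df <- NULL
    }
    gene_model(id, cds[, c("start", "end")], strand = strand,
               domain_segments = dom_df,
               source_sequence_id = cds$seqid[1L])
  })
  names(models) <- ids
  models[!vapply(models, is.null, logical(1L))]
}

#' Classify every gene of a GFF3 + FASTA annotation
#'
#' @param gff_path GFF3 file with `gene_id` and `segment_kind` attributes.
#' @param fasta_path FASTA with the sequences the GFF refers to.
#' @param params A [classify_params()] list.
#' @return Data frame of calls with the classification objects attached as
#'   attribute `"classifications"`.
#' @export
classify_gff <- function(gff_path, fasta_path, params = classify_params()) {
  gff <- parse_gff3(gff_path)
  seqs <- read_fasta(fasta_path)
  models <- gene_models_from_gff(gff)
  cls <- lapply(models, function(m) {
    if (!m$source_sequence_id %in% names(seqs)) {
      stop(sprintf("sequence %s not present in FASTA", m$source_sequence_id),
           call. = FALSE)
    }
    classify_receptor(m, seqs[[m$source_sequence_id]], params)
  })
  data.frame(
    gene_id = names(models),
    call = vapply(cls, function(x) x$call, character(1L)),
    n_itims = vapply(cls, function(x) nrow(x$itim_hits), integer(1L)),
    tail_kind = vapply(cls, function(x) x$tail_kind, character(1L)),
    n_disablements = vapply(cls, function(x) nrow(x$disablements), integer(1L)),
    row.names = NULL, stringsAsFactors = FALSE
  ) -> out
  attr(out, "classifications") <- cls
  out
}
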