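# Sliding-window recurrence (dot-plot) comparison of long sequences.
#
# The grid holds per-window-pair identity fractions for a forward channel
# (A windows vs B windows) and a reverse channel (A windows vs windows of
# the reverse complement of B), so collinear segments appear as diagonal
# runs in the forward channel and inversions as diagonal runs in the
# reverse channel. Segment detection follows diagonal runs above an
# identity threshold and reports intervals uncovered by any segment as
# unmatched (insertions / region absent from the other assembly).

#' Compute a sliding-window recurrence grid
#'
#' Cell (i, j) is the fraction of matching positions between window i of
#' `seq_a` and window j of `seq_b` (forward channel) or of the reverse
#' complement of `seq_b` (reverse channel). Ambiguity characters count as
#' mismatches. Windows start every `step` nt.
#'
#' @param seq_a,seq_b Nucleotide strings, both at least `window` long.
#' @param window Window size in nt (default 200).
#' @param step Window step in nt (default 50).
#' @return An object of class `recurrence_grid`: list with matrices `fwd`
#'   and `rev`, `window`, `step`, `len_a`, `len_b`.
#' @export
compute_grid <- function(seq_a, seq_b, window = 200L, step = 50L) {
  la <- nchar(seq_a)
  lb <- nchar(seq_b)
  if (la < window || lb < window) {
    stop("both sequences must be at least one window long", call. = FALSE)
  }
  fwd <- .window_identity(seq_a, seq_b, window, step)
  rev <- .window_identity(seq_a, revcomp(seq_b), window, step)
  structure(list(fwd = fwd, rev = rev, window = as.integer(window),
                 step = as.integer(step), len_a = la, len_b = lb),
            class = "recurrence_grid")
}

# identity matrix between all windows of a and all windows of b via one-hot
# cross-products (BLAS does the window-pair match counting)
.window_identity <- function(a, b, window, step) {
  ai <- match(seq_chars(a), BASES)
  bi <- match(seq_chars(b), BASES)
  sa <- seq(1L, length(ai) - window + 1L, by = step)
  sb <- seq(1L, length(bi) - window + 1L, by = step)
  idx_a <- outer(sa, 0L:(window - 1L), "+")
  idx_b <- outer(sb, 0L:(window - 1L), "+")
  Aw <- matrix(ai[idx_a], nrow = length(sa))
  Bw <- matrix(bi[idx_b], nrow = length(sb))
  m <- matrix(0, length(sa), length(sb))
  for (base in 1:4) {
    A1 <- (Aw == base) * 1
    B1 <- (Bw == base) * 1
    A1[is.na(A1)] <- 0
    B1[is.na(B1)] <- 0
    m <- m + A1 %*% t(B1)
  }
  m / window
}

#' Detect collinear and inverted segments in a recurrence grid
#'
#' Maximal diagonal runs of at least `min_windows` cells at or above
#' `min_identity` become segments (forward channel: collinear; reverse
#' channel: inverted, with coordinates mapped back to the forward strand of
#' sequence B). Up to `bridge` consecutive sub-threshold cells inside a run
#' are tolerated. Axis intervals covered by no segment are reported as
#' unmatched.
#'
#' @param grid A [compute_grid()] result.
#' @param min_identity Per-window identity threshold (default 0.8).
#' @param min_windows Minimum qualifying windows per segment (default 3).
#' @param bridge Sub-threshold cells bridged inside a run (default 1).
#' @param min_unmatched Minimum length (nt) for reporting an unmatched
#'   interval; defaults to the window size.
#' @return An object of class `segment_report`: list with `segments`
#'   (a_start, a_end, b_start, b_end, orientation, mean_identity,
#'   n_windows) and `unmatched_a` / `unmatched_b` interval data frames.
#'   All coordinates 1-based inclusive.
#' @export
detect_segments <- function(grid, min_identity = 0.8, min_windows = 3L,
                            bridge = 1L, min_unmatched = NULL) {
  stopifnot(inherits(grid, "recurrence_grid"))
  if (is.null(min_unmatched)) min_unmatched <- grid$window
  w <- grid$window
  st <- grid$step
  segs <- list()

  collect <- function(mat, channel) {
    na <- nrow(mat)
    nb <- ncol(mat)
    for (off in (-(na - 1L)):(nb - 1L)) {
      i0 <- max(1L, 1L - off)
      i1 <- min(na, nb - off)
      if (i1 - i0 + 1L < min_windows) next
      cells <- mat[cbind(i0:i1, (i0:i1) + off)]
      for (run in .threshold_runs(cells >= min_identity, min_windows, bridge)) {
        ia <- i0 + run[1L] - 1L
        ib <- i0 + run[2L] - 1L
        segs[[length(segs) + 1L]] <<- list(
          channel = channel, i_start = ia, i_end = ib, offset = off,
          mean_identity = mean(cells[run[1L]:run[2L]])
        )
      }
    }
  }
  collect(grid$fwd, "forward")
  collect(grid$rev, "inverted")

  if (length(segs) == 0L) {
    segments <- data.frame(a_start = integer(0), a_end = integer(0),
                           b_start = integer(0), b_end = integer(0),
                           orientation = character(0),
                           mean_identity = numeric(0), n_windows = integer(0))
  } else {
    segments <- do.call(rbind, lapply(segs, function(s) {
      a_start <- (s$i_start - 1L) * st + 1L
      a_end <- (s$i_end - 1L) * st + w
      j_start <- s$i_start + s$offset
      j_end <- s$i_end + s$offset
      if (s$channel == "forward") {
        b_start <- (j_start - 1L) * st + 1L
        b_end <- (j_end - 1L) * st + w
      } else {
        # window j of revcomp(B) covers B positions
        # [len_b - ((j-1) step + w) + 1, len_b - (j-1) step]
        b_start <- grid$len_b - ((j_end - 1L) * st + w) + 1L
        b_end <- grid$len_b - (j_start - 1L) * st
      }
      data.frame(a_start = a_start, a_end = a_end,
                 b_start = b_start, b_end = b_end,
                 orientation = s$channel,
                 mean_identity = s$mean_identity,
                 n_windows = s$i_end - s$i_start + 1L,
                 stringsAsFactors = FALSE)
    }))
  }

  extent_a <- (nrow(grid$fwd) - 1L) * st + w
  extent_b <- (ncol(grid$fwd) - 1L) * st + w
  unmatched_a <- .uncovered(segments$a_start, segments$a_end, extent_a,
                            min_unmatched)
  unmatched_b <- .uncovered(segments$b_start, segments$b_end, extent_b,
                            min_unmatched)
  structure(list(segments = segments, unmatched_a = unmatched_a,
                 unmatched_b = unmatched_b, window = w, step = st),
            class = "segment_report")
}

# maximal runs of TRUE allowing up to `bridge` consecutive FALSE cells
# inside; returned runs start and end on TRUE cells and contain >= min_len
# TRUE cells
.threshold_runs <- function(flags, min_len, bridge) {
  runs <- list()
  n <- length(flags)
  i <- 1L
  while (i <= n) {
    if (!flags[i]) { i <- i + 1L; next }
    start <- i
    last_true <- i
    j <- i + 1L
    gap <- 0L
    while (j <= n) {
      if (flags[j]) {
        last_true <- j
        gap <- 0L
      } else {
        gap <- gap + 1L
        if (gap > bridge) break
      }
      j <- j + 1L
    }
    if (sum(flags[start:last_true]) >= min_len) {
      runs[[length(runs) + 1L]] <- c(start, last_true)
    }
    i <- last_true + 1L
  }
  runs
}

# complement of the union of [starts, ends] within [1, extent]
.uncovered <- function(starts, ends, extent, min_len) {
  if (length(starts) == 0L) {
    iv <- data.frame(start = 1L, end = extent)
  } else {
    o <- order(starts)
    starts <- starts[o]
    ends <- ends[o]
    merged_s <- starts[1L]
    merged_e <- ends[1L]
    ms <- integer(0)
    me <- integer(0)
    for (i in seq_along(starts)[-1L]) {
      if (starts[i] <= merged_e + 1L) {
        merged_e <- max(merged_e, ends[i])
      } else {
        ms <- c(ms, merged_s)
        me <- c(me, merged_e)
        merged_s <- starts[i]
        merged_e <- ends[i]
      }
    }
    ms <- c(ms, merged_s)
    me <- c(me, merged_e)
    gaps_s <- c(1L, me + 1L)
    gaps_e <- c(ms - 1L, extent)
    keep <- gaps_e >= gaps_s
    iv <- data.frame(start = gaps_s[keep], end = gaps_e[keep])
  }
  iv[iv$end - iv$start + 1L >= min_len, , drop = FALSE]
}

#' Write a recurrence grid as TSV
#'
#' @param grid A [compute_grid()] result.
#' @param path Output prefix; `<path>_fwd.tsv` and `<path>_rev.tsv` are
#'   written with window start coordinates as dimnames.
#' @return The two paths, invisibly.
#' @export
write_grid_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "recurrence_grid"))
  lab <- function(nw) (seq_len(nw) - 1L) * grid$step + 1L
  out <- c(paste0(path, "_fwd.tsv"), paste0(path, "_rev.tsv"))
  for (ch in 1:2) {
    m <- if (ch == 1L) grid$fwd else grid$rev
    dimnames(m) <- list(lab(nrow(m)), lab(ncol(m)))
    utils::write.table(format(m, digits = 4L), out[ch], sep = "\t",
                       quote = FALSE, col.names = NA)
  }
  invisible(out)
}

#' Write unmatched intervals as BED (0-based half-open)
#'
#' @param report A [detect_segments()] result.
#' @param names_ab Sequence names for the two axes.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_unmatched_bed <- function(report, names_ab, path) {
  stopifnot(inherits(report, "segment_report"), length(names_ab) == 2L)
  rows <- rbind(
    if (nrow(report$unmatched_a))
      data.frame(chrom = names_ab[1L], start = report$unmatched_a$start - 1L,
                 end = report$unmatched_a$end),
    if (nrow(report$unmatched_b))
      data.frame(chrom = names_ab[2L], start = report$unmatched_b$start - 1L,
                 end = report$unmatched_b$end)
  )
  if (is.null(rows)) rows <- data.frame(chrom = character(0), start = integer(0),
                                        end = integer(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
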