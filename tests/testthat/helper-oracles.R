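# Independent oracles and fixture builders used across the test files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Full-matrix local Smith-Waterman (linear gap penalty), with the same
# deterministic tie-breaks the package documents: cell predecessors prefer
# diagonal > up (gap in reference) > left (gap in read); the best cell is
# the first maximum in (row, column) order. Plain R, no seeding or banding,
# so it is an independent check of the seed-and-extend aligner.
sw_local_r <- function(read, ref, match = 1L, mismatch = -1L, gap = -2L) {
  a <- strsplit(read, "")[[1]]
  b <- strsplit(ref, "")[[1]]
  m <- length(a)
  n <- length(b)
  H <- matrix(0L, m + 1L, n + 1L)
  D <- matrix(0L, m + 1L, n + 1L)
  best <- 0L
  bi <- 0L
  bj <- 0L
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- if (a[i] == b[j]) match else mismatch
      v <- 0L
      dd <- 0L
      cand <- H[i, j] + sub
      if (cand > v) { v <- cand; dd <- 1L }
      cand <- H[i, j + 1L] + gap
      if (cand > v) { v <- cand; dd <- 2L }
      cand <- H[i + 1L, j] + gap
      if (cand > v) { v <- cand; dd <- 3L }
      H[i + 1L, j + 1L] <- v
      D[i + 1L, j + 1L] <- if (v > 0L) dd else 0L
      if (v > best) { best <- v; bi <- i; bj <- j }
    }
  }
  if (best <= 0L) return(list(score = 0L, matches = 0L, alnlen = 0L))
  i <- bi
  j <- bj
  matches <- 0L
  alnlen <- 0L
  while (i > 0L && j > 0L && H[i + 1L, j + 1L] > 0L) {
    dd <- D[i + 1L, j + 1L]
    if (dd == 0L) break
    alnlen <- alnlen + 1L
    if (dd == 1L) {
      if (a[i] == b[j]) matches <- matches + 1L
      i <- i - 1L
      j <- j - 1L
    } else if (dd == 2L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(score = best, matches = matches, alnlen = alnlen)
}

# read-from-reference case generator for the aligner oracle test: a
# substring with at most 2 edits, kept >= 3 nt from the substring ends and
# >= 3 nt apart, so a 15-mer seed always exists and the optimal local
# alignment is unique up to the documented tie-breaks
make_aligner_case <- function() {
  L <- sample(150:300, 1L)
  ref <- rand_dna(L)
  rl <- sample(50:60, 1L)
  st <- sample(1:(L - rl + 1L), 1L)
  rd <- substr(ref, st, st + rl - 1L)
  ch <- strsplit(rd, "")[[1]]
  n_edit <- sample(0:2, 1L)
  has_indel <- n_edit > 0L && stats::runif(1L) < 0.3
  n_sub <- n_edit - as.integer(has_indel)
  pos_pool <- 4:(length(ch) - 3L)
  ed <- if (n_edit > 0L) sort(sample(pos_pool, n_edit)) else integer(0)
  while (length(ed) > 1L && min(diff(ed)) < 3L) ed <- sort(sample(pos_pool, n_edit))
  if (n_sub > 0L) {
    for (p in ed[seq_len(n_sub)]) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    }
  }
  if (has_indel) {
    p <- ed[n_edit]
    if (stats::runif(1L) < 0.5) {
      ch <- ch[-p]
    } else {
      ch <- append(ch, sample(c("A", "C", "G", "T"), 1L), after = p)
    }
  }
  rd <- paste(ch, collapse = "")
  strand <- if (stats::runif(1L) < 0.5) "+" else "-"
  if (strand == "-") rd <- revcomp(rd)
  list(read = rd, ref = ref, strand = strand)
}

# brute-force ITIM oracle: regular-expression lookahead over the tail
itim_oracle <- function(tail) {
  m <- gregexpr("(?=[ILVS].Y..[LV])", tail, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# random protein string
rand_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"), n, TRUE),
        collapse = "")
}

# canonical bipartition key used to query bootstrap support tables
split_key <- function(set, tips) {
  anchor <- sort(tips)[1L]
  side <- if (anchor %in% set) setdiff(tips, set) else set
  paste(sort(side), collapse = "|")
}
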