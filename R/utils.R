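#' @useDynLib lrcprofiler, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# Kyte-Doolittle hydropathy index
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Evaluate code under a temporary RNG seed
#'
#' Seeds the generator, evaluates `code`, and restores the caller's RNG
#' state, so seeded computations do not perturb the surrounding stream.
#'
#' @param seed Single integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

chars_seq <- function(x) paste(x, collapse = "")

#' Reverse complement of a nucleotide string
#'
#' @param x A character string over the alphabet ACGTN (case-insensitive).
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  vapply(x, function(s) {
    chars_seq(rev(seq_chars(chartr("ACGTNacgtn", "TGCANTGCAN", s))))
  }, character(1L), USE.NAMES = FALSE)
}

#' Ungapped percent identity between two equal-length sequences
#'
#' Positions are compared one-to-one; any position where either sequence has
#' a non-ACGT character counts as a mismatch unless both characters are equal.
#'
#' @param a,b Character strings of equal length.
#' @return Fraction of identical positions in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  if (length(ca) != length(cb)) {
    stop("sequences must have equal length for ungapped identity", call. = FALSE)
  }
  mean(ca == cb)
}

# random non-stop codons (uniform over the 61 sense codons)
random_codons <- function(n) {
  all_codons <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
                      1L, paste, collapse = "")
  sense <- setdiff(all_codons, STOP_CODONS)
  sample(sense, n, replace = TRUE)
}

# Is the codon containing position `pos` (1-based, frame from position 1)
# a stop codon after substituting `base` at `pos`?
.makes_stop <- function(chars, pos, base) {
  ci <- (pos - 1L) %/% 3L
  cod <- chars[(ci * 3L + 1L):(ci * 3L + 3L)]
  cod[pos - ci * 3L] <- base
  chars_seq(cod) %in% STOP_CODONS
}

# Substitute exactly k positions drawn from `pool` (1-based indices into
# `chars`), each to a uniformly drawn alternative base. With `frame_guard`,
# substitutions that would create an in-frame stop codon are re-drawn among
# the remaining alternatives (at least one of the three is always safe).
mutate_exact <- function(chars, pool, k, frame_guard = TRUE) {
  if (k == 0L) return(chars)
  if (k > length(pool)) {
    stop("requested more substitutions than mutable positions", call. = FALSE)
  }
  pos <- sample(pool, k)
  for (p in pos) {
    alts <- setdiff(BASES, chars[p])
    alts <- sample(alts)
    if (frame_guard) {
      ok <- !vapply(alts, function(b) .makes_stop(chars, p, b), logical(1L))
      alts <- alts[ok]
    }
    chars[p] <- alts[1L]
  }
  chars
}

# match probability between two lineages diverged from a common ancestor by
# uniform-substitution rates e1 and e2
.match_same_anc <- function(e1, e2) (1 - e1) * (1 - e2) + e1 * e2 / 3

# composition of two uniform substitution channels: effective rate
.compose_rate <- function(b, e) 1 - ((1 - b) * (1 - e) + b * e / 3)

fmt_int <- function(x) formatC(x, format = "d", big.mark = "")
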