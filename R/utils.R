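# Internal helpers shared across modules.

# Weighted lower median: smallest x whose cumulative weight reaches half the
# total. Used for the coverage baseline and the assembly-median GC.
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), length(x) > 0L)
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(as.numeric(w))
  x[match(TRUE, cw >= cw[length(cw)] / 2)]
}

# All k-mers of a sequence as a character vector (1-based start positions).
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

# Positions (1-based) of k-mers occurring exactly once in seq, named by k-mer.
unique_kmer_positions <- function(seq, k) {
  km <- seq_kmers(seq, k)
  dup <- duplicated(km) | duplicated(km, fromLast = TRUE)
  pos <- which(!dup)
  names(pos) <- km[pos]
  pos
}

rotate_seq <- function(seq, r) {
  # r is 0-based: rotation starting at position r + 1
  n <- nchar(seq)
  if (n == 0L || r %% n == 0L) return(seq)
  r <- r %% n
  paste0(substr(seq, r + 1L, n), substr(seq, 1L, r))
}

canonical_rotation <- function(seq) rotate_seq(seq, min_rotation_cpp(seq))

# Identity percent truncated (not rounded) to 2 decimals, computed with
# exact integer floor division so printed triples stay self-consistent.
truncate_identity <- function(identical, alignment_length) {
  ((10000 * as.numeric(identical)) %/% as.numeric(alignment_length)) / 100
}

`%||%` <- function(x, y) if (is.null(x)) y else x
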