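# Anchored banded global alignment.
#
# Scoring is fixed package-wide: match +1, mismatch -1, gap open -2 (charged
# on the first gap column), gap extend -1 (each further column), i.e. a gap
# of length g costs -(g + 1). The summary statistics, not the score, are the
# contract; the scheme is kept simple and documented.

#' Construct an alignment summary from its counts
#'
#' An alignment summary holds the column bookkeeping of a global pairwise
#' alignment: `alignment_length` columns split exactly into `identical`,
#' `mismatches` and `gaps` (a gap column counts once regardless of which
#' sequence carries the gap; a run of g gap columns contributes g). The
#' identity percentage is `identical / alignment_length`, truncated -- not
#' rounded -- to two decimals, which keeps printed triples such as
#' 40,259 identical over 40,405 columns = 99.63% self-consistent.
#'
#' @param alignment_length Total alignment columns.
#' @param identical Columns with equal residues.
#' @param gaps Columns containing a gap in either sequence.
#' @param columns Optional integer vector of per-column codes (0 match,
#'   1 mismatch, 2 gap), kept for windowed divergence profiling.
#' @param score Optional alignment score.
#' @return An object of class `alignment_summary`.
#' @examples
#' alignment_summary(40405, 40259, 137)$identity_pct # 99.63
#' @export
alignment_summary <- function(alignment_length, identical, gaps,
                              columns = NULL, score = NULL) {
  mismatches <- alignment_length - identical - gaps
  if (mismatches < 0 || identical < 0 || gaps < 0 || alignment_length <= 0) {
    abort("alignment_summary: counts must be non-negative and sum to alignment_length")
  }
  structure(
    list(
      alignment_length = alignment_length,
      identical = identical,
      gaps = gaps,
      mismatches = mismatches,
      identity_pct = truncate_identity(identical, alignment_length),
      score = score,
      columns = columns
    ),
    class = "alignment_summary"
  )
}

summary_from_columns <- function(columns, score = NULL) {
  alignment_summary(
    alignment_length = length(columns),
    identical = sum(columns == 0L),
    gaps = sum(columns == 2L),
    columns = columns,
    score = score
  )
}

#' @export
print.alignment_summary <- function(x, ...) {
  cat("Global alignment summary\n")
  cat(sprintf("  Alignment length    %d\n", x$alignment_length))
  cat(sprintf("  Identical positions %d\n", x$identical))
  cat(sprintf("  Mismatches          %d\n", x$mismatches))
  cat(sprintf("  Gaps                %d\n", x$gaps))
  cat(sprintf("  Sequence identity   %.2f%%\n", x$identity_pct))
  invisible(x)
}

#' @export
glance.alignment_summary <- function(x, ...) {
  tibble::tibble(
    alignment_length = x$alignment_length,
    identical = x$identical,
    mismatches = x$mismatches,
    gaps = x$gaps,
    identity_pct = x$identity_pct,
    score = x$score %||% NA_real_
  )
}

#' Per-column codes of an alignment
#'
#' @param x An `alignment_summary` produced by [align_pair()] or
#'   [align_full_dp()].
#' @return Integer vector, one entry per alignment column: 0 match,
#'   1 mismatch, 2 gap.
#' @export
alignment_columns <- function(x) {
  stopifnot(inherits(x, "alignment_summary"))
  if (is.null(x$columns)) abort("alignment was summarised without columns")
  x$columns
}

#' Global pairwise alignment guided by a unique k-mer anchor chain
#'
#' End-to-end global alignment of two sequences. Shared k-mers that are
#' unique within each sequence are chained co-linearly and the affine-gap
#' dynamic programme is restricted to a corridor of half-width `pad` around
#' the chain, which makes near-identical inputs of tens of kilobases
#' tractable. When the chain covers less than `min_chain_cov` of the shorter
#' sequence the corridor is unreliable; inputs up to `max_full` bases then
#' fall back to the unrestricted dynamic programme, and longer inputs raise
#' an alignment-infeasible error.
#'
#' @param a,b Non-empty sequences (nucleotide or protein; residues are
#'   compared as characters).
#' @param k Anchor k-mer length (default 21).
#' @param pad Corridor half-width in bases around the anchor chain
#'   (default 150).
#' @param max_full Maximum shorter-sequence length for the unrestricted
#'   fallback (default 5000).
#' @param min_chain_cov Minimum fraction of the shorter sequence that the
#'   anchor chain must cover (default 0.5).
#' @return An `alignment_summary`; see [alignment_summary()].
#' @examples
#' s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
#' glance(align_pair(s, s))
#' @export
align_pair <- function(a, b, k = 21, pad = 150, max_full = 5000,
                       min_chain_cov = 0.5) {
  if (nchar(a) == 0L || nchar(b) == 0L) abort("align_pair: empty sequence")
  m <- nchar(a)
  n <- nchar(b)
  shorter <- min(m, n)

  chain <- NULL
  if (shorter >= k) {
    anc <- find_anchors(a, b, k)
    if (nrow(anc) > 0L) {
      ord <- order(anc$pos_a)
      anc <- anc[ord, ]
      keep <- lis_cpp(anc$pos_b)
      chain <- anc[keep, ]
      cov_pos <- unique(unlist(lapply(chain$pos_a, function(p) p:(p + k - 1L))))
      if (length(cov_pos) < min_chain_cov * shorter) chain <- NULL
    }
  }

  if (is.null(chain)) {
    if (shorter > max_full) {
      abort("align_pair: divergence too high for anchoring on long input")
    }
    lo <- rep(0L, m + 1L)
    hi <- rep(n, m + 1L)
  } else {
    bounds <- corridor_from_chain(m, n, chain, k, pad)
    lo <- bounds$lo
    hi <- bounds$hi
  }
  res <- nw_corridor_cpp(a, b, lo, hi)
  if (!isTRUE(res$feasible)) {
    if (shorter > max_full) abort("align_pair: corridor alignment infeasible")
    res <- nw_corridor_cpp(a, b, rep(0L, m + 1L), rep(n, m + 1L))
  }
  summary_from_columns(res$columns, res$score)
}

# Per-row column bounds interpolated through the (0-based) anchor chain.
corridor_from_chain <- function(m, n, chain, k, pad) {
  node_i <- c(0L, chain$pos_a, chain$pos_a + k, m)
  node_j <- c(0L, chain$pos_b, chain$pos_b + k, n)
  ord <- order(node_i, node_j)
  node_i <- node_i[ord]
  node_j <- node_j[ord]
  keep <- !duplicated(node_i)
  node_i <- node_i[keep]
  node_j <- node_j[keep]
  center <- stats::approx(node_i, node_j, xout = 0:m, rule = 2)$y
  lo <- pmax(0, floor(center) - pad)
  hi <- pmin(n, ceiling(center) + pad)
  lo <- cummax(lo)
  hi <- cummax(hi)
  hi <- pmax(hi, lo)
  lo[1] <- 0L
  hi[m + 1L] <- n
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Unrestricted global alignment (reference implementation)
#'
#' Naive full-matrix affine-gap global alignment with the same scoring and
#' tie-break conventions as [align_pair()]. Quadratic in memory; intended
#' for short inputs and as an internal reference for the corridor
#' implementation.
#'
#' @inheritParams align_pair
#' @return An `alignment_summary`.
#' @export
align_full_dp <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) abort("align_full_dp: empty sequence")
  res <- nw_full_oracle_cpp(a, b)
  summary_from_columns(res$columns, res$score)
}
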