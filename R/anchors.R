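# Unique k-mer anchoring, co-linear chaining and allelic block detection.
# All coordinates are 0-based, half-open; conversion to 1-based closed
# happens only at report boundaries.

#' Find unique-unique shared k-mer anchors between two sequences
#'
#' An anchor is a k-mer occurring exactly once in each of the two sequences.
#' Anchors are symmetric: swapping the arguments exchanges the coordinate
#' columns.
#'
#' @param a,b Sequences (character scalars).
#' @param k Anchor length, at least 11 (default 21).
#' @return Tibble with 0-based columns `pos_a`, `pos_b` and `k`.
#' @export
find_anchors <- function(a, b, k = 21) {
  if (k < 11) abort("find_anchors: k must be >= 11")
  pa <- unique_kmer_positions(a, k)
  pb <- unique_kmer_positions(b, k)
  shared <- intersect(names(pa), names(pb))
  tibble::tibble(
    pos_a = unname(pa[shared]) - 1L,
    pos_b = unname(pb[shared]) - 1L,
    k = as.integer(k)
  )
}

reverse_complement <- function(seq) {
  stringr::str_c(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
                 collapse = "")
}

#' Chain anchors into allelic synteny blocks
#'
#' Anchors are reduced to a longest strictly co-linear chain (increasing in
#' both coordinates), the chain is split wherever consecutive anchors are
#' more than `max_gap` bases apart in either sequence, and each resulting
#' segment that spans at least `min_block` bases in both sequences becomes a
#' block. Block identity is estimated by globally aligning the two spanned
#' substrings with [align_pair()]; the full alignment summary is kept in the
#' `alignment` list-column for downstream divergence profiling.
#'
#' @param a,b Sequences.
#' @param k Anchor k-mer length (default 21).
#' @param max_gap Maximum inter-anchor gap within a block, in bases
#'   (default 2000).
#' @param min_block Minimum block span in both sequences (default 1000,
#'   the conventional lower bound for calling two contigs allelic).
#' @param ids Length-2 character vector of sequence ids used in the output.
#' @param anchors Optional precomputed anchor tibble from [find_anchors()].
#' @return Tibble of blocks: `contig_a`, `contig_b`, `start_a`, `end_a`,
#'   `start_b`, `end_b` (0-based half-open), `n_anchors`, `identity_pct`,
#'   `orientation`, `alignment` (list-column of `alignment_summary`).
#' @export
chain_and_blocks <- function(a, b, k = 21, max_gap = 2000, min_block = 1000,
                             ids = c("a", "b"), anchors = NULL) {
  if (is.null(anchors)) anchors <- find_anchors(a, b, k)
  empty <- tibble::tibble(
    contig_a = character(0), contig_b = character(0),
    start_a = integer(0), end_a = integer(0),
    start_b = integer(0), end_b = integer(0),
    n_anchors = integer(0), identity_pct = numeric(0),
    orientation = character(0), alignment = list()
  )
  if (nrow(anchors) == 0L) return(empty)
  anchors <- anchors[order(anchors$pos_a), ]
  chain <- anchors[lis_cpp(anchors$pos_b), ]
  nc <- nrow(chain)
  gap_a <- diff(chain$pos_a) - k
  gap_b <- diff(chain$pos_b) - k
  brk <- which(gap_a > max_gap | gap_b > max_gap)
  seg_start <- c(1L, brk + 1L)
  seg_end <- c(brk, nc)
  blocks <- purrr::map_dfr(seq_along(seg_start), function(s) {
    i0 <- seg_start[s]
    i1 <- seg_end[s]
    sa <- chain$pos_a[i0]
    ea <- chain$pos_a[i1] + k
    sb <- chain$pos_b[i0]
    eb <- chain$pos_b[i1] + k
    if (min(ea - sa, eb - sb) < min_block) return(NULL)
    aln <- align_pair(substr(a, sa + 1L, ea), substr(b, sb + 1L, eb), k = k)
    tibble::tibble(
      contig_a = ids[1], contig_b = ids[2],
      start_a = sa, end_a = ea, start_b = sb, end_b = eb,
      n_anchors = i1 - i0 + 1L,
      identity_pct = aln$identity_pct,
      orientation = "+",
      alignment = list(aln)
    )
  })
  if (nrow(blocks) == 0L) empty else blocks
}

#' All-vs-all allelic block detection across an assembly
#'
#' Evaluates every unordered contig pair once (self-pairs excluded) with
#' [chain_and_blocks()]; pairs are canonically ordered by id so the output
#' is invariant under input order. By default only the forward strand is
#' scanned, matching co-oriented allelic contigs from a single assembler
#' run; with `both_strands = TRUE` the reverse complement of the second
#' contig is also scanned and reverse-strand blocks are reported with
#' orientation `"-"` and coordinates converted back to the forward strand.
#'
#' @param contigs Tibble with columns `id` and `seq`.
#' @param k,max_gap,min_block See [chain_and_blocks()].
#' @param both_strands Also scan the reverse complement (default `FALSE`).
#' @return Tibble of blocks sorted by span length (descending).
#' @export
all_vs_all <- function(contigs, k = 21, max_gap = 2000, min_block = 1000,
                       both_strands = FALSE) {
  if (nrow(contigs) < 2L) abort("all_vs_all: need at least two contigs")
  contigs <- contigs[order(contigs$id), ]
  idx <- lapply(contigs$seq, unique_kmer_positions, k = k)
  pairs <- utils::combn(nrow(contigs), 2L)
  blocks <- purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]
    j <- pairs[2, p]
    shared <- intersect(names(idx[[i]]), names(idx[[j]]))
    fwd <- NULL
    if (length(shared) > 0L) {
      anc <- tibble::tibble(
        pos_a = unname(idx[[i]][shared]) - 1L,
        pos_b = unname(idx[[j]][shared]) - 1L,
        k = as.integer(k)
      )
      fwd <- chain_and_blocks(contigs$seq[i], contigs$seq[j], k = k,
                              max_gap = max_gap, min_block = min_block,
                              ids = c(contigs$id[i], contigs$id[j]),
                              anchors = anc)
    }
    rev <- NULL
    if (both_strands) {
      rc <- reverse_complement(contigs$seq[j])
      rev <- chain_and_blocks(contigs$seq[i], rc, k = k,
                              max_gap = max_gap, min_block = min_block,
                              ids = c(contigs$id[i], contigs$id[j]))
      if (nrow(rev) > 0L) {
        nb <- nchar(contigs$seq[j])
        rev <- dplyr::mutate(rev,
                             orientation = "-",
                             start_b0 = nb - .data$end_b,
                             end_b = nb - .data$start_b,
                             start_b = .data$start_b0)
        rev$start_b0 <- NULL
      }
    }
    dplyr::bind_rows(fwd, rev)
  })
  if (nrow(blocks) == 0L) return(blocks)
  blocks[order(-(blocks$end_a - blocks$start_a)), ]
}

#' Windowed divergence profile of a block alignment
#'
#' Differences along the alignment (mismatch columns, plus each gap run
#' counted once at its opening column so indel length does not dominate the
#' signal) are binned into windows of alignment columns. Uneven counts
#' across windows indicate that some regions of an allelic contig pair are
#' more conserved than others.
#'
#' @param alignment An `alignment_summary` with columns retained (e.g. from
#'   the `alignment` list-column of [chain_and_blocks()]).
#' @param window Window size in alignment columns, at least 100
#'   (default 1000).
#' @return Tibble (class `divergence_profile`) with 0-based `window_start`
#'   and difference `count` per window.
#' @export
divergence_profile <- function(alignment, window = 1000) {
  if (window < 100) abort("divergence_profile: window must be >= 100")
  cols <- alignment_columns(alignment)
  is_gap <- cols == 2L
  gap_open <- is_gap & !c(FALSE, is_gap[-length(is_gap)])
  diff_col <- which(cols == 1L | gap_open)
  n_win <- ceiling(length(cols) / window)
  win <- (diff_col - 1L) %/% window
  counts <- tabulate(win + 1L, nbins = n_win)
  out <- tibble::tibble(
    window_start = (seq_len(n_win) - 1L) * as.integer(window),
    count = counts
  )
  class(out) <- c("divergence_profile", class(out))
  out
}

#' @export
autoplot.divergence_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$window_start, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "alignment column", y = "differences per window")
}

#' @rdname autoplot.divergence_profile
#' @param x A `divergence_profile`.
#' @param ... Unused.
#' @export
plot_divergence <- function(x, ...) autoplot.divergence_profile(x, ...)
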