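# Mitochondrial contig identification, tandem-duplication detection and
# bisection into circular chromosomes.

#' Identify mitochondrial contig candidates
#'
#' Fungal mitogenomes stand out from the nuclear genome on two axes: their
#' GC content deviates strongly from the assembly median, and they are
#' over-represented in read coverage because each cell carries many
#' mitochondria. A contig is reported as a candidate when both criteria
#' hold: its GC differs from the length-weighted median assembly GC by at
#' least `gc_delta_min` percentage points, and its coverage group (from
#' [classify_coverage()]) is IV. When no coverage classification is
#' supplied only the GC criterion is applied and the result is flagged
#' provisional.
#'
#' @param contigs Contig tibble with `id`, `length`, `gc`.
#' @param classes Optional `coverage_triage` tibble.
#' @param gc_delta_min Minimum GC deviation in percentage points
#'   (default 10; a 27% mitogenome against a 49% nuclear genome clears it
#'   with wide margin).
#' @param median_gc Assembly median GC fraction; computed length-weighted
#'   from `contigs` when omitted.
#' @return Tibble with per-contig `gc`, `gc_delta` (points), `group`,
#'   `passes_gc`, `passes_coverage`, `candidate` and a `provisional`
#'   attribute-backed column.
#' @export
find_mito_candidates <- function(contigs, classes = NULL, gc_delta_min = 10,
                                 median_gc = NULL) {
  stopifnot(all(c("id", "length", "gc") %in% names(contigs)))
  if (is.null(median_gc)) {
    median_gc <- weighted_median(contigs$gc, contigs$length)
  }
  provisional <- is.null(classes)
  out <- tibble::tibble(
    contig_id = contigs$id,
    length = contigs$length,
    gc = contigs$gc,
    gc_delta = 100 * abs(contigs$gc - median_gc)
  )
  if (provisional) {
    out$group <- factor(NA, levels = c("I", "II", "III", "IV", "V"))
    out$passes_coverage <- NA
  } else {
    m <- match(out$contig_id, classes$contig_id)
    if (anyNA(m)) abort("find_mito_candidates: coverage classes missing contigs")
    out$group <- classes$group[m]
    out$passes_coverage <- out$group == "IV"
  }
  out$passes_gc <- out$gc_delta >= gc_delta_min
  out$candidate <- out$passes_gc & (provisional | out$passes_coverage)
  out$provisional <- provisional
  attr(out, "median_gc") <- median_gc
  out
}

#' Detect an internal tandem duplication by k-mer self-matching
#'
#' Computes all exact k-mer self-matches at positive offset (restricted to
#' k-mers occurring exactly twice, which is the signature of a clean
#' two-unit tandem), finds the dominant offset band of width `band_bp`, and
#' calls the contig tandem-duplicated when the band period lies near half
#' the contig length (0.4-0.6 L) and the band's anchors cover at least
#' `min_support` of the first-unit positions. The cut points delimit one
#' duplication unit: the first band anchor, and that anchor shifted by its
#' local offset.
#'
#' @param seq Contig sequence, length at least `4 * k`.
#' @param k Self-match k-mer size (default 21).
#' @param band_bp Offset band tolerance in bases (default 200); absorbs the
#'   offset shift introduced by an indel between the two units.
#' @param min_support Minimum fraction of unit positions covered by
#'   band-consistent anchors (default 0.6).
#' @return Object of class `tandem_report`: list with `duplicated`,
#'   `period` (dominant offset), `support`, `cut_points` (0-based pair) and
#'   `n_anchors`.
#' @export
detect_tandem_duplication <- function(seq, k = 21, band_bp = 200,
                                      min_support = 0.6) {
  L <- nchar(seq)
  if (L < 4 * k) abort("detect_tandem_duplication: sequence shorter than 4k")
  km <- seq_kmers(seq, k)
  ord <- order(km)
  r <- rle(km[ord])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  twice <- which(r$lengths == 2L)
  no_report <- structure(
    list(duplicated = FALSE, period = NA_integer_, support = 0,
         cut_points = NULL, n_anchors = 0L),
    class = "tandem_report"
  )
  if (length(twice) == 0L) return(no_report)
  p1 <- ord[starts[twice]]
  p2 <- ord[ends[twice]]
  swap <- p1 > p2
  tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
  offsets <- p2 - p1

  # dominant offset band
  bin <- offsets %/% band_bp
  bin_counts <- table(bin)
  top <- as.integer(names(bin_counts)[which.max(bin_counts)])
  in_band <- bin >= top - 1L & bin <= top + 1L
  band_off <- offsets[in_band]
  band_p1 <- p1[in_band]
  period <- as.integer(names(sort(table(band_off), decreasing = TRUE))[1])

  cov <- unique(unlist(lapply(band_p1, function(p) p:(p + k - 1L))))
  unit_len <- L - period
  support <- length(cov[cov <= unit_len]) / unit_len
  duplicated <- period >= 0.4 * L && period <= 0.6 * L && support >= min_support
  if (!duplicated) {
    no_report$n_anchors <- sum(in_band)
    return(no_report)
  }
  first <- which.min(band_p1)
  cut0 <- band_p1[first] - 1L # 0-based
  structure(
    list(
      duplicated = TRUE,
      period = period,
      support = support,
      cut_points = c(cut0, cut0 + band_off[first]),
      n_anchors = sum(in_band)
    ),
    class = "tandem_report"
  )
}

#' @export
print.tandem_report <- function(x, ...) {
  cat("Tandem duplication report\n")
  cat(sprintf("  duplicated: %s\n", x$duplicated))
  if (x$duplicated) {
    cat(sprintf("  period    : %d bp\n", x$period))
    cat(sprintf("  support   : %.3f\n", x$support))
    cat(sprintf("  cut points: %d, %d (0-based)\n",
                x$cut_points[1], x$cut_points[2]))
  }
  invisible(x)
}

#' @export
glance.tandem_report <- function(x, ...) {
  tibble::tibble(
    duplicated = x$duplicated,
    period = x$period,
    support = x$support,
    n_anchors = x$n_anchors
  )
}

#' Bisect a tandem-duplicated contig into two circular chromosomes
#'
#' Splits the contig at the detected duplication cut points into two units
#' whose lengths sum to the contig length (the second unit wraps around the
#' contig end). Both units are rotated to their lexicographically minimal
#' rotation so the linearised output is deterministic; because that
#' canonical rotation is phase-independent for each unit, the un-rotated
#' cut-phase pair is kept for direct unit-vs-unit alignment (see
#' `cut_phase` element).
#'
#' @param seq The tandem-duplicated contig sequence.
#' @param report A `tandem_report` with `duplicated = TRUE`.
#' @return Object of class `mito_bisection`: list with `mt1`, `mt2`
#'   (canonically rotated circular sequences), `lengths`, and `cut_phase`
#'   (the in-phase pair as cut, for alignment).
#' @export
bisect_mito <- function(seq, report) {
  stopifnot(inherits(report, "tandem_report"))
  if (!isTRUE(report$duplicated)) {
    abort("bisect_mito: contig is not tandem-duplicated")
  }
  L <- nchar(seq)
  c0 <- report$cut_points[1]
  p <- report$cut_points[2] - report$cut_points[1]
  mt1 <- substr(seq, c0 + 1L, c0 + p)
  mt2 <- paste0(substr(seq, c0 + p + 1L, L), substr(seq, 1L, c0))
  structure(
    list(
      mt1 = canonical_rotation(mt1),
      mt2 = canonical_rotation(mt2),
      lengths = c(nchar(mt1), nchar(mt2)),
      cut_phase = list(mt1 = mt1, mt2 = mt2)
    ),
    class = "mito_bisection"
  )
}

#' @export
print.mito_bisection <- function(x, ...) {
  cat(sprintf("Bisected circular chromosomes: %d bp and %d bp\n",
              x$lengths[1], x$lengths[2]))
  invisible(x)
}

#' Align the two bisected mitochondrial chromosomes
#'
#' Globally aligns the in-phase (cut-phase) unit pair of a
#' [bisect_mito()] result and returns the alignment summary in the shape
#' used for mitogenome comparisons: alignment length, identical positions,
#' gaps and truncated identity percentage.
#'
#' @param bisection A `mito_bisection`.
#' @param ... Passed to [align_pair()].
#' @return An `alignment_summary`.
#' @export
compare_mito_units <- function(bisection, ...) {
  stopifnot(inherits(bisection, "mito_bisection"))
  align_pair(bisection$cut_phase$mt1, bisection$cut_phase$mt2, ...)
}
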