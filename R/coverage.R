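#' Coverage-group thresholds
#'
#' Boundaries, in units of the 1x unique-coverage baseline, between the five
#' coverage groups used to triage contigs of a dikaryotic assembly:
#' group I below `lo` (typically contamination), II for divergent allelic
#' contigs around 1x, III for collapsed (near-identical haplotype) contigs
#' around 2x, IV for over-represented organelle contigs, V above
#' `hi_organelle` (rDNA-like high-copy repeats). Intervals are left-closed,
#' right-open, so every coverage multiple maps to exactly one group.
#'
#' @param lo,hi_allelic,hi_collapsed,hi_organelle Increasing positive
#'   multiples of the baseline (defaults 0.5, 1.5, 3, 50).
#' @return A named list of thresholds.
#' @export
coverage_thresholds <- function(lo = 0.5, hi_allelic = 1.5,
                                hi_collapsed = 3, hi_organelle = 50) {
  if (!(0 < lo && lo < hi_allelic && hi_allelic < hi_collapsed &&
        hi_collapsed < hi_organelle)) {
    abort("thresholds must satisfy 0 < lo < hi_allelic < hi_collapsed < hi_organelle")
  }
  list(lo = lo, hi_allelic = hi_allelic,
       hi_collapsed = hi_collapsed, hi_organelle = hi_organelle)
}

#' Estimate the 1x unique-coverage baseline
#'
#' The baseline read density (reads per base) of unique, single-copy
#' sequence is estimated as the length-weighted median density over contigs
#' of at least `min_len` bases. The length-weighted median is robust against
#' the organelle and rDNA contigs that dominate raw read counts, and against
#' the collapsed-haplotype contigs at twice the unique density as long as
#' they carry less than half of the qualifying assembly length.
#'
#' @param records Tibble with columns `contig_id`, `length`, `read_count`.
#' @param min_len Minimum contig length considered (default 10000 bases);
#'   short high-copy repeat contigs rarely pass it.
#' @return Baseline density (reads per base), strictly positive.
#' @export
estimate_baseline <- function(records, min_len = 10000) {
  rec <- dplyr::filter(records, .data$length >= min_len)
  if (nrow(rec) == 0L) {
    abort(paste0("estimate_baseline: no contig of length >= ", min_len))
  }
  base <- weighted_median(rec$read_count / rec$length, rec$length)
  if (base <= 0) abort("estimate_baseline: baseline density is not positive")
  base
}

#' Classify contigs into coverage groups I-V
#'
#' Each contig's read density is expressed as a multiple of the baseline and
#' binned by [coverage_thresholds()] (left-closed, right-open): I below
#' `lo`; II in \[`lo`, `hi_allelic`); III in \[`hi_allelic`, `hi_collapsed`);
#' IV in \[`hi_collapsed`, `hi_organelle`); V at or above `hi_organelle`.
#' Classification is scale-invariant: multiplying all read counts by a
#' constant and re-estimating the baseline leaves every group label
#' unchanged.
#'
#' @param records Tibble with columns `contig_id`, `length`, `read_count`.
#' @param baseline Baseline density from [estimate_baseline()].
#' @param thresholds See [coverage_thresholds()].
#' @return Tibble (class `coverage_triage`) with `contig_id`, `length`,
#'   `read_count`, `density`, `multiple` and `group` (factor with levels
#'   I-V). The baseline and thresholds used are kept as attributes.
#' @export
classify_coverage <- function(records, baseline,
                              thresholds = coverage_thresholds()) {
  if (!is.numeric(baseline) || baseline <= 0) {
    abort("classify_coverage: baseline must be positive")
  }
  if (any(records$length <= 0)) {
    abort(paste0("zero-length contig: row ", which(records$length <= 0)[1]))
  }
  out <- dplyr::mutate(
    records,
    density = .data$read_count / .data$length,
    # rounded to 9 decimals so division noise cannot push an exact boundary
    # multiple (e.g. 1.5x) across its left-closed edge
    multiple = round(.data$density / baseline, 9),
    group = cut(.data$multiple,
                breaks = c(-Inf, thresholds$lo, thresholds$hi_allelic,
                           thresholds$hi_collapsed, thresholds$hi_organelle, Inf),
                labels = c("I", "II", "III", "IV", "V"),
                right = FALSE)
  )
  attr(out, "baseline") <- baseline
  attr(out, "thresholds") <- thresholds
  class(out) <- c("coverage_triage", class(out))
  out
}

#' Diploid-character report from coverage groups
#'
#' Summarises the fraction of assembly length in the allelic (II) and
#' collapsed (III) coverage groups and applies a heuristic diploid-character
#' call: the assembly is flagged diploid when groups II + III carry at least
#' `frac_len_min` of the total length (the nuclear genome dominates) and
#' either group III is non-negligible (`frac_iii_min`) or an independently
#' measured single-copy-marker duplication fraction (from
#' [assess_markers()]) reaches `dup_min`. The thresholds are heuristics and
#' deliberately configurable.
#'
#' @param classes A `coverage_triage` tibble from [classify_coverage()].
#' @param dup_fraction Optional duplicated/(single + duplicated) marker
#'   fraction.
#' @param frac_len_min,frac_iii_min,dup_min Heuristic thresholds (defaults
#'   0.8, 0.05, 0.3).
#' @return An object of class `ploidy_report`: a list with
#'   `baseline_density`, `frac_len_II`, `frac_len_III`, `frac_dup_markers`
#'   and `diploid_character`.
#' @export
ploidy_report <- function(classes, dup_fraction = NULL,
                          frac_len_min = 0.8, frac_iii_min = 0.05,
                          dup_min = 0.3) {
  stopifnot(all(c("length", "group") %in% names(classes)))
  if (!is.null(dup_fraction) && is.na(dup_fraction)) dup_fraction <- NULL
  total <- sum(as.numeric(classes$length))
  frac_ii <- sum(as.numeric(classes$length[classes$group == "II"])) / total
  frac_iii <- sum(as.numeric(classes$length[classes$group == "III"])) / total
  diploid <- (frac_ii + frac_iii >= frac_len_min) &&
    (frac_iii >= frac_iii_min ||
       (!is.null(dup_fraction) && dup_fraction >= dup_min))
  structure(
    list(
      baseline_density = attr(classes, "baseline"),
      frac_len_II = frac_ii,
      frac_len_III = frac_iii,
      frac_dup_markers = dup_fraction,
      diploid_character = diploid
    ),
    class = "ploidy_report"
  )
}

#' @export
print.ploidy_report <- function(x, ...) {
  cat("Ploidy report\n")
  cat(sprintf("  baseline density : %.6g reads/base\n",
              x$baseline_density %||% NA_real_))
  cat(sprintf("  length in group II : %.1f%%\n", 100 * x$frac_len_II))
  cat(sprintf("  length in group III: %.1f%%\n", 100 * x$frac_len_III))
  if (!is.null(x$frac_dup_markers)) {
    cat(sprintf("  duplicated markers : %.1f%%\n", 100 * x$frac_dup_markers))
  }
  cat(sprintf("  diploid character  : %s\n", x$diploid_character))
  invisible(x)
}

#' @export
glance.ploidy_report <- function(x, ...) {
  tibble::tibble(
    baseline_density = x$baseline_density %||% NA_real_,
    frac_len_II = x$frac_len_II,
    frac_len_III = x$frac_len_III,
    frac_dup_markers = x$frac_dup_markers %||% NA_real_,
    diploid_character = x$diploid_character
  )
}

#' @export
tidy.coverage_triage <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "coverage_triage")
  out
}

#' @export
glance.coverage_triage <- function(x, ...) {
  tb <- table(x$group)
  tibble::tibble(
    n_contigs = nrow(x),
    baseline_density = attr(x, "baseline"),
    n_I = as.integer(tb[["I"]]), n_II = as.integer(tb[["II"]]),
    n_III = as.integer(tb[["III"]]), n_IV = as.integer(tb[["IV"]]),
    n_V = as.integer(tb[["V"]])
  )
}

#' Contig-length versus read-count triage plot
#'
#' Log-log scatter of contig length against read count, coloured by coverage
#' group, with the fitted 1x baseline drawn as a reference line
#' (`read_count = baseline * length`).
#'
#' @param object,x A `coverage_triage` tibble from [classify_coverage()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_triage <- function(object, ...) {
  baseline <- attr(object, "baseline")
  ref <- tibble::tibble(
    length = range(object$length),
    read_count = baseline * range(object$length)
  )
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$length, y = .data$read_count)) +
    ggplot2::geom_line(data = ref, colour = "red") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "contig length (bp)", y = "read count",
                  colour = "group")
}

#' @rdname autoplot.coverage_triage
#' @export
plot_coverage <- function(x, ...) autoplot.coverage_triage(x, ...)
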