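# End-to-end triage pipeline and combined report.

report_conventions <- function() {
  list(
    coordinates = "0-based, half-open",
    identity = "identical / alignment_length, truncated (not rounded) to 2 decimals",
    gap_columns = "a gap column counts once regardless of which sequence carries the gap",
    group_intervals = "left-closed, right-open in baseline multiples",
    scoring = "match +1, mismatch -1, gap open -2 (first column), gap extend -1"
  )
}

#' Run the full triage pipeline on one assembly
#'
#' Executes, in order: assembly statistics, coverage triage and the
#' diploid-character report, mitochondrial candidate identification (with
#' tandem-duplication detection, bisection and unit alignment for each
#' candidate), all-vs-all allelic block detection, marker duplication
#' assessment (when markers are supplied) and the terpene-synthase motif
#' screen (when proteins are supplied). Thresholds used are echoed in the
#' report together with a conventions block.
#'
#' @param contigs Contig tibble from [read_fasta()] or
#'   [simulate_dikaryon()].
#' @param counts Read-count tibble (`contig_id`, `length`, `read_count`).
#' @param proteins,markers Optional protein tibbles (`id`, `seq`).
#' @param min_len Minimum contig length for baseline estimation.
#' @param thresholds [coverage_thresholds()].
#' @param gc_delta_min GC deviation (points) for mito candidacy.
#' @param k,max_gap,min_block Allelic block detection parameters.
#' @param identity_min,coverage_min Marker assessment parameters.
#' @return List of class `triage_report`.
#' @export
run_pipeline <- function(contigs, counts, proteins = NULL, markers = NULL,
                         min_len = 10000, thresholds = coverage_thresholds(),
                         gc_delta_min = 10, k = 21, max_gap = 2000,
                         min_block = 1000, identity_min = 90,
                         coverage_min = 0.7) {
  if (!setequal(contigs$id, counts$contig_id)) {
    abort("run_pipeline: contigs and counts cover different contig sets")
  }
  stats <- assembly_stats(contigs)
  baseline <- estimate_baseline(counts, min_len = min_len)
  triage <- classify_coverage(counts, baseline, thresholds)

  mito_cand <- find_mito_candidates(contigs, triage, gc_delta_min = gc_delta_min)
  mito_detail <- lapply(mito_cand$contig_id[mito_cand$candidate], function(id) {
    seq <- contigs$seq[match(id, contigs$id)]
    detail <- list(contig_id = id)
    if (nchar(seq) >= 4 * k) {
      rep <- detect_tandem_duplication(seq, k = k)
      detail$tandem <- glance(rep)
      if (rep$duplicated) {
        bis <- bisect_mito(seq, rep)
        detail$unit_lengths <- bis$lengths
        detail$alignment <- glance(compare_mito_units(bis))
      }
    }
    detail
  })

  blocks <- all_vs_all(contigs, k = k, max_gap = max_gap,
                       min_block = min_block)

  marker_summary <- NULL
  dup_fraction <- NULL
  if (!is.null(markers) && !is.null(proteins)) {
    assessment <- assess_markers(proteins, markers,
                                 identity_min = identity_min,
                                 coverage_min = coverage_min)
    marker_summary <- glance(assessment)
    dup_fraction <- marker_summary$dup_fraction
  }
  ploidy <- ploidy_report(triage, dup_fraction = dup_fraction)

  motif_summary <- NULL
  if (!is.null(proteins)) {
    hits <- scan_proteins(proteins)
    cls <- classify_terpene_synthase(hits, proteins$id)
    motif_summary <- summarize_repertoire(cls)
  }

  structure(
    list(
      conventions = report_conventions(),
      parameters = list(
        min_len = min_len, thresholds = thresholds,
        gc_delta_min = gc_delta_min, k = k, max_gap = max_gap,
        min_block = min_block, identity_min = identity_min,
        coverage_min = coverage_min
      ),
      stats = stats,
      triage = triage,
      ploidy = ploidy,
      mito = list(candidates = mito_cand[mito_cand$candidate, ],
                  detail = mito_detail),
      blocks = blocks,
      markers = marker_summary,
      motifs = motif_summary
    ),
    class = "triage_report"
  )
}

#' Write a triage report as JSON
#'
#' Serialises a [run_pipeline()] report (tables as data frames, alignment
#' list-columns dropped) to a JSON file; machine artifacts carry the
#' conventions block so downstream consumers never guess coordinate or
#' identity rules.
#'
#' @param report A `triage_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "triage_report"))
  out <- report
  out$stats <- as.list(tibble::as_tibble(out$stats))
  out$triage <- tidy(out$triage)
  out$ploidy <- as.list(glance(out$ploidy))
  out$blocks$alignment <- NULL
  out <- unclass(out)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
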