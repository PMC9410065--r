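# Ground-truthed synthetic dikaryotic genome scenarios.
#
# One RNG stream per scenario, seeded from the config and consumed in fixed
# order (nuclear pairs, mitogenome, rDNA, contaminant, read counts,
# proteins), so a seed fully determines every output byte.

#' Configuration of a synthetic dikaryon scenario
#'
#' Defaults emulate the structure of a dikaryotic basidiomycete assembly:
#' pairs of haplotype loci whose zero-divergence fraction collapses into
#' single contigs at twice the unique coverage, a low-GC mitochondrial
#' chromosome at elevated copy number (optionally assembled as one
#' tandem-duplicated contig or as two near-identical variants), a high-copy
#' rDNA-like repeat contig, and a low-coverage contaminant. Read counts are
#' Poisson with mean `copy * length * depth / read_len`.
#'
#' @param seed Integer seed; fully determines the scenario.
#' @param n_nuclear_pairs Number of haplotype locus pairs (default 8).
#' @param contig_len_range Nuclear locus length range in bases
#'   (default 30000-60000).
#' @param frac_identical_regions Fraction of each locus with zero
#'   haplotype divergence, emitted once as a collapsed contig (default 0.3).
#' @param divergence_range Per-base substitution rate range for divergent
#'   regions (default 0.005-0.03; rates above 0.2 are rejected as
#'   infeasible).
#' @param indel_rate Indel events per base in divergent regions
#'   (default 1e-4); lengths are geometric (p = 0.5), capped at 100 bases.
#' @param nuclear_gc Nuclear GC fraction (default 0.494).
#' @param mito_len Mitogenome unit length (default 40000).
#' @param mito_gc Mitogenome GC fraction (default 0.27).
#' @param mito_copy Mitogenome copy number (default 20).
#' @param mito_mode One of `"tandem_duplicated"` (one contig of two
#'   tandem units), `"two_variants"`, `"single"`.
#' @param mito_n_subs Substitutions between the two mitogenome units
#'   (default 40).
#' @param mito_indel_len Length of the single planted insertion between the
#'   units (default 91). Edits are placed interior to the unit (none within
#'   the first 100 bases; insertion within the middle 80%) and
#'   substitutions never abut the insertion site.
#' @param rdna_len,rdna_gc,rdna_copy rDNA-like repeat contig (defaults
#'   8000 bases, GC 0.48, copy 100).
#' @param contam_len,contam_gc,contam_copy Contaminant contig (defaults
#'   20000 bases, GC 0.55, copy 0.2).
#' @param depth Unique-coverage reads per base (default 30).
#' @param read_len Read length in bases (default 10000).
#' @param n_markers Number of single-copy marker proteins (default 40).
#' @param frac_marker_duplicated Fraction of marker loci divergent between
#'   haplotypes, hence present as two predicted protein copies
#'   (default 0.5; copies differ by 2% of residues).
#' @param marker_len_range Marker protein length range (default 200-400).
#' @param n_decoy_proteins Unrelated random proteins added to the protein
#'   set (default 10).
#' @param track_window Window size of the alternating conserved/hotspot
#'   divergence tracks inside divergent regions (default 2000).
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_nuclear_pairs = 8L,
                            contig_len_range = c(30000L, 60000L),
                            frac_identical_regions = 0.3,
                            divergence_range = c(0.005, 0.03),
                            indel_rate = 1e-4,
                            nuclear_gc = 0.494,
                            mito_len = 40000L,
                            mito_gc = 0.27,
                            mito_copy = 20,
                            mito_mode = c("tandem_duplicated", "two_variants",
                                          "single"),
                            mito_n_subs = 40L,
                            mito_indel_len = 91L,
                            rdna_len = 8000L,
                            rdna_gc = 0.48,
                            rdna_copy = 100,
                            contam_len = 20000L,
                            contam_gc = 0.55,
                            contam_copy = 0.2,
                            depth = 30,
                            read_len = 10000L,
                            n_markers = 40L,
                            frac_marker_duplicated = 0.5,
                            marker_len_range = c(200L, 400L),
                            n_decoy_proteins = 10L,
                            track_window = 2000L) {
  mito_mode <- match.arg(mito_mode)
  fracs <- c(frac_identical_regions, frac_marker_duplicated,
             mito_gc, nuclear_gc, rdna_gc, contam_gc)
  if (any(fracs < 0 | fracs > 1)) abort("config error: fractions must lie in [0, 1]")
  if (max(divergence_range) > 0.2) {
    abort("config error: divergence_range above 0.2 is infeasible for allelic contigs")
  }
  if (min(divergence_range) < 0 || diff(divergence_range) < 0) {
    abort("config error: invalid divergence_range")
  }
  cfg <- list(
    seed = as.integer(seed), n_nuclear_pairs = as.integer(n_nuclear_pairs),
    contig_len_range = contig_len_range,
    frac_identical_regions = frac_identical_regions,
    divergence_range = divergence_range, indel_rate = indel_rate,
    nuclear_gc = nuclear_gc, mito_len = as.integer(mito_len),
    mito_gc = mito_gc, mito_copy = mito_copy, mito_mode = mito_mode,
    mito_n_subs = as.integer(mito_n_subs),
    mito_indel_len = as.integer(mito_indel_len),
    rdna_len = as.integer(rdna_len), rdna_gc = rdna_gc, rdna_copy = rdna_copy,
    contam_len = as.integer(contam_len), contam_gc = contam_gc,
    contam_copy = contam_copy, depth = depth, read_len = as.integer(read_len),
    n_markers = as.integer(n_markers),
    frac_marker_duplicated = frac_marker_duplicated,
    marker_len_range = marker_len_range,
    n_decoy_proteins = as.integer(n_decoy_proteins),
    track_window = as.integer(track_window)
  )
  class(cfg) <- "scenario_config"
  cfg
}

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(STD_AA, n, replace = TRUE), collapse = "")
}

substitute_bases <- function(chars, positions) {
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  chars
}

# Divergent haplotype copy: substitutions in alternating low/high-rate
# windows (0.2x and 1.8x the region rate, so the mean rate is preserved and
# divergence profiles have planted non-uniformity), plus geometric indels.
mutate_region <- function(seq, rate, indel_rate, track_window, gc) {
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  win <- (seq_len(n) - 1L) %/% track_window
  win_rate <- ifelse(win %% 2L == 0L, 0.2 * rate, 1.8 * rate)
  is_sub <- runif(n) < win_rate
  sub_pos <- which(is_sub)
  chars <- substitute_bases(chars, sub_pos)
  out <- paste(chars, collapse = "")

  n_ind <- if (n > 300L) rpois(1L, indel_rate * n) else 0L
  indels <- tibble::tibble(pos = integer(0), len = integer(0),
                           type = character(0))
  if (n_ind > 0L) {
    pos <- sort(sample(n - 200L, n_ind) + 100L, decreasing = TRUE)
    len <- pmin(rgeom(n_ind, 0.5) + 1L, 100L)
    type <- sample(c("ins", "del"), n_ind, replace = TRUE)
    for (e in seq_len(n_ind)) {
      if (type[e] == "ins") {
        out <- paste0(substr(out, 1L, pos[e]), random_dna(len[e], gc),
                      substr(out, pos[e] + 1L, nchar(out)))
      } else {
        out <- paste0(substr(out, 1L, pos[e] - 1L),
                      substr(out, pos[e] + len[e], nchar(out)))
      }
    }
    indels <- tibble::tibble(pos = rev(pos), len = rev(len), type = rev(type))
  }
  list(seq = out, n_subs = length(sub_pos), sub_pos = sub_pos,
       indels = indels)
}

#' @importFrom stats rgeom
make_mito_units <- function(cfg) {
  u1 <- random_dna(cfg$mito_len, cfg$mito_gc)
  if (cfg$mito_mode == "single") return(list(u1 = u1, u2 = NULL))
  ipos <- sample(round(0.1 * cfg$mito_len):round(0.9 * cfg$mito_len), 1L)
  # keep substitutions clear of the insertion site: a substitution within
  # gap-sliding range of a random insertion can be absorbed into an
  # equally-long gap placement, so planted edit counts would no longer be
  # the alignment optimum
  sub_cand <- setdiff(101:cfg$mito_len, (ipos - 25L):(ipos + 25L))
  sub_pos <- sort(sample(sub_cand, cfg$mito_n_subs))
  chars <- strsplit(u1, "", fixed = TRUE)[[1]]
  chars <- substitute_bases(chars, sub_pos)
  u2 <- paste(chars, collapse = "")
  u2 <- paste0(substr(u2, 1L, ipos),
               random_dna(cfg$mito_indel_len, cfg$mito_gc),
               substr(u2, ipos + 1L, cfg$mito_len))
  list(u1 = u1, u2 = u2, sub_pos = sub_pos, ins_pos = ipos)
}

copy_to_group <- function(copy, thresholds = coverage_thresholds()) {
  as.character(cut(copy,
                   breaks = c(-Inf, thresholds$lo, thresholds$hi_allelic,
                              thresholds$hi_collapsed, thresholds$hi_organelle,
                              Inf),
                   labels = c("I", "II", "III", "IV", "V"), right = FALSE))
}

#' Simulate a ground-truthed dikaryotic genome scenario
#'
#' Generates an assembly, a per-contig read-count table, a predicted
#' protein set and a marker set, together with the full planted truth
#' (copy numbers, expected coverage groups, allelic pair divergence,
#' mitogenome edits, marker statuses). Identical-haplotype regions are
#' emitted once as collapsed contigs at copy 2; divergent regions are
#' emitted as contig pairs at copy 1 each. Everything is deterministic
#' given `config$seed`.
#'
#' @param config A [scenario_config()].
#' @return List of class `dikaryon_scenario` with elements `contigs`
#'   (tibble `id`, `seq`, `length`, `gc`), `counts` (tibble `contig_id`,
#'   `length`, `read_count`), `proteins`, `markers` (tibbles `id`, `seq`)
#'   and `truth` (class `synthetic_truth`).
#' @export
simulate_dikaryon <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  set.seed(cfg$seed)

  ids <- character(0)
  seqs <- character(0)
  copies <- numeric(0)
  roles <- character(0)
  pairs <- NULL

  for (i in seq_len(cfg$n_nuclear_pairs)) {
    L <- round(runif(1, cfg$contig_len_range[1], cfg$contig_len_range[2]))
    ident_len <- round(cfg$frac_identical_regions * L)
    div_len <- L - ident_len
    if (ident_len > 0L) {
      ids <- c(ids, sprintf("collapsed_%02d", i))
      seqs <- c(seqs, random_dna(ident_len, cfg$nuclear_gc))
      copies <- c(copies, 2)
      roles <- c(roles, "collapsed")
    }
    if (div_len > 0L) {
      hap_a <- random_dna(div_len, cfg$nuclear_gc)
      rate <- runif(1, cfg$divergence_range[1], cfg$divergence_range[2])
      mut <- mutate_region(hap_a, rate, cfg$indel_rate, cfg$track_window,
                           cfg$nuclear_gc)
      id_a <- sprintf("hapA_%02d", i)
      id_b <- sprintf("hapB_%02d", i)
      ids <- c(ids, id_a, id_b)
      seqs <- c(seqs, hap_a, mut$seq)
      copies <- c(copies, 1, 1)
      roles <- c(roles, "allelic", "allelic")
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(
        contig_a = id_a, contig_b = id_b, region_len = div_len,
        rate = rate, n_subs = mut$n_subs,
        n_indel_events = nrow(mut$indels),
        indel_bases = sum(mut$indels$len %||% 0L)
      ))
    }
  }

  mito <- make_mito_units(cfg)
  mito_ids <- character(0)
  if (cfg$mito_mode == "tandem_duplicated") {
    mito_ids <- "mito_tandem"
    ids <- c(ids, mito_ids)
    seqs <- c(seqs, paste0(mito$u1, mito$u2))
    copies <- c(copies, cfg$mito_copy)
    roles <- c(roles, "mito")
  } else if (cfg$mito_mode == "two_variants") {
    mito_ids <- c("mito_1", "mito_2")
    ids <- c(ids, mito_ids)
    seqs <- c(seqs, mito$u1, mito$u2)
    copies <- c(copies, cfg$mito_copy, cfg$mito_copy)
    roles <- c(roles, "mito", "mito")
  } else {
    mito_ids <- "mito"
    ids <- c(ids, mito_ids)
    seqs <- c(seqs, mito$u1)
    copies <- c(copies, cfg$mito_copy)
    roles <- c(roles, "mito")
  }

  ids <- c(ids, "rdna_repeat", "contaminant")
  seqs <- c(seqs, random_dna(cfg$rdna_len, cfg$rdna_gc),
            random_dna(cfg$contam_len, cfg$contam_gc))
  copies <- c(copies, cfg$rdna_copy, cfg$contam_copy)
  roles <- c(roles, "rdna", "contaminant")

  lengths <- nchar(seqs)
  expected <- copies * lengths * cfg$depth / cfg$read_len
  counts <- tibble::tibble(
    contig_id = ids,
    length = lengths,
    read_count = rpois(length(ids), expected)
  )

  contigs <- tibble::tibble(
    id = ids, seq = seqs, length = lengths,
    gc = vapply(seqs, gc_content, numeric(1), USE.NAMES = FALSE)
  )

  # marker and protein sets
  n_dup <- round(cfg$frac_marker_duplicated * cfg$n_markers)
  marker_len <- round(runif(cfg$n_markers, cfg$marker_len_range[1],
                            cfg$marker_len_range[2]))
  marker_seq <- vapply(marker_len, random_protein, character(1))
  markers <- tibble::tibble(
    id = sprintf("marker_%03d", seq_len(cfg$n_markers)),
    seq = marker_seq
  )
  prot_ids <- character(0)
  prot_seqs <- character(0)
  status <- character(cfg$n_markers)
  for (m in seq_len(cfg$n_markers)) {
    prot_ids <- c(prot_ids, sprintf("prot_%03d_a", m))
    prot_seqs <- c(prot_seqs, marker_seq[m])
    if (m <= n_dup) {
      nsub <- ceiling(0.02 * marker_len[m])
      chars <- strsplit(marker_seq[m], "", fixed = TRUE)[[1]]
      pos <- sample(marker_len[m], nsub)
      for (p in pos) chars[p] <- sample(setdiff(STD_AA, chars[p]), 1L)
      prot_ids <- c(prot_ids, sprintf("prot_%03d_b", m))
      prot_seqs <- c(prot_seqs, paste(chars, collapse = ""))
      status[m] <- "duplicated"
    } else {
      status[m] <- "single"
    }
  }
  if (cfg$n_decoy_proteins > 0L) {
    decoy_len <- round(runif(cfg$n_decoy_proteins, cfg$marker_len_range[1],
                             cfg$marker_len_range[2]))
    prot_ids <- c(prot_ids, sprintf("decoy_%03d",
                                    seq_len(cfg$n_decoy_proteins)))
    prot_seqs <- c(prot_seqs, vapply(decoy_len, random_protein, character(1)))
  }
  proteins <- tibble::tibble(id = prot_ids, seq = prot_seqs)

  truth <- structure(
    list(
      contigs = tibble::tibble(
        contig_id = ids, length = lengths, copy = copies, role = roles,
        expected_group = copy_to_group(copies),
        expected_count = expected
      ),
      allelic_pairs = pairs %||% tibble::tibble(
        contig_a = character(0), contig_b = character(0),
        region_len = integer(0), rate = numeric(0), n_subs = integer(0),
        n_indel_events = integer(0), indel_bases = integer(0)
      ),
      mito = list(mode = cfg$mito_mode, contig_ids = mito_ids,
                  unit1 = mito$u1, unit2 = mito$u2,
                  n_subs = if (cfg$mito_mode == "single") 0L else cfg$mito_n_subs,
                  indel_len = if (cfg$mito_mode == "single") 0L else cfg$mito_indel_len),
      markers = tibble::tibble(marker_id = markers$id, status = status),
      config = cfg
    ),
    class = "synthetic_truth"
  )

  structure(
    list(contigs = contigs, counts = counts, proteins = proteins,
         markers = markers, truth = truth),
    class = "dikaryon_scenario"
  )
}

#' Expected per-contig read counts of a scenario
#'
#' The Poisson mean used by the generator:
#' `copy * length * depth / read_len`.
#'
#' @param config The [scenario_config()] the truth was generated from.
#' @param truth A `synthetic_truth` from [simulate_dikaryon()].
#' @return Tibble `contig_id`, `expected`.
#' @export
expected_counts <- function(config, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  tc <- truth$contigs
  tibble::tibble(
    contig_id = tc$contig_id,
    expected = tc$copy * tc$length * config$depth / config$read_len
  )
}

#' Write a simulated scenario to disk
#'
#' Emits `assembly.fa`, `counts.tsv`, `proteins.faa`, `markers.faa` and
#' `truth.json` (sequence-free truth summary) into a directory.
#'
#' @param scenario A `dikaryon_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "dikaryon_scenario"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(scenario$contigs, file.path(dir, "assembly.fa"))
  write_counts_tsv(scenario$counts, file.path(dir, "counts.tsv"))
  write_fasta(scenario$proteins, file.path(dir, "proteins.faa"))
  write_fasta(scenario$markers, file.path(dir, "markers.faa"))
  truth <- scenario$truth
  truth$mito$unit1 <- NULL
  truth$mito$unit2 <- NULL
  truth$config <- unclass(truth$config)
  jsonlite::write_json(
    unclass(truth), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}

#' Emit a synthetic PAF mapping matching a scenario's read counts
#'
#' Writes one primary PAF record per counted read (tag `tp:A:P`), so that
#' [read_counts_from_paf()] recovers the scenario's count table exactly.
#'
#' @param scenario A `dikaryon_scenario`.
#' @param path Output PAF path.
#' @return `path`, invisibly.
#' @export
write_scenario_paf <- function(scenario, path) {
  stopifnot(inherits(scenario, "dikaryon_scenario"))
  counts <- scenario$counts
  cfg <- scenario$truth$config
  con <- file(path, "w")
  on.exit(close(con))
  rid <- 0L
  for (i in seq_len(nrow(counts))) {
    n <- counts$read_count[i]
    if (n == 0L) next
    tlen <- counts$length[i]
    span <- min(cfg$read_len, tlen)
    lines <- sprintf(
      "read_%06d\t%d\t0\t%d\t+\t%s\t%d\t0\t%d\t%d\t%d\t60\ttp:A:P",
      rid + seq_len(n), cfg$read_len, cfg$read_len,
      counts$contig_id[i], tlen, span, span, span
    )
    rid <- rid + n
    writeLines(lines, con)
  }
  invisible(path)
}
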