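# Single-copy marker duplication assessment and two-species pan-genome
# accounting on supplied protein sets.
#
# Marker matching is a deliberate mechanistic simplification of a
# BUSCO-style assessment: supplied marker proteins are matched by global
# alignment identity, not by profile HMMs. The duplicated fraction of
# near-universal single-copy markers is the ploidy diagnostic this
# reproduces on synthetic dikaryons.

# identity over aligned (residue-residue) columns and marker coverage
protein_hit_stats <- function(marker_seq, protein_seq) {
  aln <- align_pair(marker_seq, protein_seq)
  cols <- alignment_columns(aln)
  aligned <- sum(cols != 2L)
  list(
    identity_pct = if (aligned == 0L) 0 else 100 * sum(cols == 0L) / aligned,
    coverage = aligned / nchar(marker_seq),
    alignment_length = aln$alignment_length
  )
}

# 6-mer prefilter: candidate pairs must share at least one hexamer, which
# near-homologs at the identities of interest essentially always do while
# unrelated proteins essentially never do.
protein_kmer_sets <- function(seqs, k = 6L) {
  lapply(seqs, function(s) unique(seq_kmers(s, k)))
}

#' Assess single-copy marker status in a protein set
#'
#' Each marker is searched in the protein set by global alignment. A
#' protein is a qualifying hit when its identity over aligned columns
#' reaches `identity_min` percent across at least `coverage_min` of the
#' marker length. Markers with two or more qualifying hits are `duplicated`
#' (in a dikaryotic assembly this signals diverged allelic copies), exactly
#' one hit is `single`, and a marker whose best qualifying-identity hit
#' covers only 30-70% of its length is `fragmented`; anything else is
#' `missing`.
#'
#' @param proteins Tibble of predicted proteins (`id`, `seq`).
#' @param markers Tibble of marker proteins (`id`, `seq`).
#' @param identity_min Minimum percent identity over aligned columns
#'   (default 90).
#' @param coverage_min Minimum fraction of marker length aligned
#'   (default 0.7).
#' @return Tibble (class `marker_assessment`) with `marker_id`, `status`,
#'   `n_hits`, `best_identity` and a `hits` list-column; summary fractions
#'   (including `dup_fraction` = duplicated / (single + duplicated)) are
#'   available via [glance()].
#' @export
assess_markers <- function(proteins, markers, identity_min = 90,
                           coverage_min = 0.7) {
  if (nrow(markers) == 0L) abort("assess_markers: empty marker set")
  if (nrow(proteins) == 0L) abort("assess_markers: empty protein set")
  pk <- protein_kmer_sets(proteins$seq)
  out <- purrr::map_dfr(seq_len(nrow(markers)), function(i) {
    mk <- unique(seq_kmers(markers$seq[i], 6L))
    cand <- which(vapply(pk, function(s) any(mk %in% s), logical(1)))
    hits <- purrr::map_dfr(cand, function(j) {
      st <- protein_hit_stats(markers$seq[i], proteins$seq[j])
      tibble::tibble(protein_id = proteins$id[j],
                     identity_pct = st$identity_pct,
                     coverage = st$coverage)
    })
    if (nrow(hits) == 0L) {
      hits <- tibble::tibble(protein_id = character(0),
                             identity_pct = numeric(0), coverage = numeric(0))
    }
    hits <- dplyr::filter(hits, .data$identity_pct >= identity_min)
    qual <- dplyr::filter(hits, .data$coverage >= coverage_min)
    status <- if (nrow(qual) >= 2L) {
      "duplicated"
    } else if (nrow(qual) == 1L) {
      "single"
    } else if (nrow(hits) > 0L &&
               any(hits$coverage >= 0.3 & hits$coverage <= 0.7)) {
      "fragmented"
    } else {
      "missing"
    }
    tibble::tibble(
      marker_id = markers$id[i],
      status = status,
      n_hits = nrow(qual),
      best_identity = if (nrow(hits) > 0L) max(hits$identity_pct) else NA_real_,
      hits = list(hits)
    )
  })
  out$status <- factor(out$status,
                       levels = c("single", "duplicated", "fragmented", "missing"))
  class(out) <- c("marker_assessment", class(out))
  out
}

#' @export
glance.marker_assessment <- function(x, ...) {
  n <- nrow(x)
  ns <- sum(x$status == "single")
  nd <- sum(x$status == "duplicated")
  tibble::tibble(
    n_markers = n,
    frac_single = ns / n,
    frac_duplicated = nd / n,
    frac_fragmented = sum(x$status == "fragmented") / n,
    frac_missing = sum(x$status == "missing") / n,
    dup_fraction = if (ns + nd > 0L) nd / (ns + nd) else NA_real_
  )
}

best_match_in <- function(seq, targets, target_kmers, my_kmers) {
  cand <- which(vapply(target_kmers, function(s) any(my_kmers %in% s),
                       logical(1)))
  if (length(cand) == 0L) return(NULL)
  stats <- purrr::map_dfr(cand, function(j) {
    st <- protein_hit_stats(seq, targets$seq[j])
    tibble::tibble(idx = j, id = targets$id[j],
                   identity_pct = st$identity_pct,
                   alignment_length = st$alignment_length)
  })
  # best identity; ties broken by longer alignment, then lexicographic id
  stats <- stats[order(-stats$identity_pct, -stats$alignment_length, stats$id), ]
  stats[1, ]
}

#' Reciprocal best matches between two protein sets
#'
#' Pairs (p, q) such that q is p's best-identity global-alignment match in
#' set B and p is q's best in set A, with identity at least `identity_min`.
#' Ties are broken by longer alignment, then lexicographic id. A shared
#' hexamer prefilter skips alignments between unrelated proteins.
#'
#' @param set_a,set_b Protein tibbles (`id`, `seq`).
#' @param identity_min Minimum percent identity over aligned columns
#'   (default 50).
#' @return Orthology tibble `protein_a`, `protein_b`, `identity_pct`.
#' @export
reciprocal_best_match <- function(set_a, set_b, identity_min = 50) {
  ka <- protein_kmer_sets(set_a$seq)
  kb <- protein_kmer_sets(set_b$seq)
  best_ab <- lapply(seq_len(nrow(set_a)), function(i) {
    best_match_in(set_a$seq[i], set_b, kb, ka[[i]])
  })
  best_ba <- lapply(seq_len(nrow(set_b)), function(j) {
    best_match_in(set_b$seq[j], set_a, ka, kb[[j]])
  })
  pairs <- purrr::map_dfr(seq_len(nrow(set_a)), function(i) {
    hit <- best_ab[[i]]
    if (is.null(hit) || hit$identity_pct < identity_min) return(NULL)
    back <- best_ba[[hit$idx]]
    if (is.null(back) || back$id != set_a$id[i]) return(NULL)
    tibble::tibble(protein_a = set_a$id[i], protein_b = hit$id,
                   identity_pct = hit$identity_pct)
  })
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(protein_a = character(0), protein_b = character(0),
                          identity_pct = numeric(0)))
  }
  pairs
}

# single-linkage clusters of near-identical proteins within one set
collapse_paralogs <- function(set, identity_min) {
  n <- nrow(set)
  if (n == 0L) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ks <- protein_kmer_sets(set$seq)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (!any(ks[[i]] %in% ks[[j]])) next
        st <- protein_hit_stats(set$seq[i], set$seq[j])
        if (st$identity_pct >= identity_min) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Pan-genome counts from core and singleton tallies
#'
#' The pan-genome of two species is the union of their shared core genes
#' and each species' singletons: `pan = core + singletons_a + singletons_b`.
#' The invariant is enforced at construction.
#'
#' @param core Number of core (shared orthologous) genes.
#' @param singletons_a,singletons_b Species-specific gene counts after
#'   paralog collapsing.
#' @return Object of class `pangenome_counts`.
#' @examples
#' pangenome_counts(8654, 4832, 14339)$pan # 27825
#' @export
pangenome_counts <- function(core, singletons_a, singletons_b) {
  stopifnot(core >= 0, singletons_a >= 0, singletons_b >= 0)
  out <- structure(
    list(core = core, singletons_a = singletons_a,
         singletons_b = singletons_b,
         pan = core + singletons_a + singletons_b),
    class = "pangenome_counts"
  )
  stopifnot(out$pan == out$core + out$singletons_a + out$singletons_b)
  out
}

#' @export
print.pangenome_counts <- function(x, ...) {
  cat(sprintf("Pan-genome: %d genes (%d core + %d + %d singletons)\n",
              x$pan, x$core, x$singletons_a, x$singletons_b))
  invisible(x)
}

#' @export
glance.pangenome_counts <- function(x, ...) {
  tibble::tibble(core = x$core, singletons_a = x$singletons_a,
                 singletons_b = x$singletons_b, pan = x$pan)
}

#' Pan-genome accounting from an orthology table
#'
#' Given a one-to-one orthology table (e.g. from
#' [reciprocal_best_match()]), counts core genes as the number of pairs and
#' singletons as the genes of each set that belong to no core pair, after
#' collapsing within-set paralogs (near-identical copies at
#' `identity_min`) so that paralogous genes are not counted.
#'
#' @param orthology Tibble `protein_a`, `protein_b` (one-to-one; a
#'   many-to-one pairing is a consistency error).
#' @param set_a,set_b Protein tibbles (`id`, `seq`).
#' @param identity_min Percent identity at which within-set paralogs are
#'   collapsed (default 90).
#' @return A `pangenome_counts` object.
#' @export
compute_pangenome <- function(orthology, set_a, set_b, identity_min = 90) {
  if (anyDuplicated(orthology$protein_a) || anyDuplicated(orthology$protein_b)) {
    abort("compute_pangenome: orthology pairing is not one-to-one")
  }
  if (!all(orthology$protein_a %in% set_a$id) ||
      !all(orthology$protein_b %in% set_b$id)) {
    abort("compute_pangenome: orthology references unknown proteins")
  }
  core <- nrow(orthology)
  cl_a <- collapse_paralogs(set_a, identity_min)
  cl_b <- collapse_paralogs(set_b, identity_min)
  core_cl_a <- unique(cl_a[match(orthology$protein_a, set_a$id)])
  core_cl_b <- unique(cl_b[match(orthology$protein_b, set_b$id)])
  pangenome_counts(
    core = core,
    singletons_a = length(unique(cl_a)) - length(core_cl_a),
    singletons_b = length(unique(cl_b)) - length(core_cl_b)
  )
}
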