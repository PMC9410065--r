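# Terpene-synthase catalytic motif screen.
#
# Class I terpene synthases activate their isoprenoid substrate by
# ionization and carry the aspartate-rich motif DDXX(D/E) ("1a") and/or the
# NSE/DTE triad (N/D)DXX(S/T)XXXE ("1b"); class II enzymes protonate the
# substrate and carry DXDD ("2"). Bifunctional enzymes carry motifs of both
# classes.

STD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Terpene-synthase motif definitions
#'
#' Positional residue-class patterns: `1a` = D, D, X, X, \[D/E\];
#' `1b` = \[N/D\], D, X, X, \[S/T\], X, X, X, E; `2` = D, X, D, D, where X
#' stands for any of the 20 standard amino acids. Matching is exact and
#' case-insensitive; the ambiguity residue `X` in an input sequence matches
#' nothing, including wildcard positions (a conservative rule that avoids
#' spurious calls on low-quality translations).
#'
#' @return Tibble with columns `name`, `class` and `pattern` (list-column
#'   of per-position allowed-residue vectors).
#' @export
motif_definitions <- function() {
  tibble::tibble(
    name = c("1a", "1b", "2"),
    class = c("I", "I", "II"),
    pattern = list(
      list("D", "D", STD_AA, STD_AA, c("D", "E")),
      list(c("N", "D"), "D", STD_AA, STD_AA, c("S", "T"),
           STD_AA, STD_AA, STD_AA, "E"),
      list("D", STD_AA, "D", "D")
    )
  )
}

#' Scan a protein for terpene-synthase motifs
#'
#' Tests every position of the sequence against every motif; overlapping
#' and nested hits are all reported.
#'
#' @param seq Amino-acid string (20 standard residues plus `X`, case
#'   insensitive).
#' @param motifs Motif table from [motif_definitions()].
#' @param protein_id Optional id recorded in the output.
#' @return Tibble of hits: `protein_id`, `motif`, `start` (0-based),
#'   `matched`.
#' @examples
#' scan_protein("MDDAADKL") # motif 1a at position 1
#' @export
scan_protein <- function(seq, motifs = motif_definitions(),
                         protein_id = NA_character_) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% c(STD_AA, "X"))
  if (any(bad)) {
    abort(paste0("illegal amino-acid residue '", chars[bad][1],
                 "' at position ", which(bad)[1]))
  }
  n <- length(chars)
  hits <- purrr::map_dfr(seq_len(nrow(motifs)), function(m) {
    pat <- motifs$pattern[[m]]
    len <- length(pat)
    if (n < len) return(NULL)
    ok <- rep(TRUE, n - len + 1L)
    for (t in seq_len(len)) {
      ok <- ok & (chars[t:(n - len + t)] %in% pat[[t]])
    }
    starts <- which(ok)
    if (length(starts) == 0L) return(NULL)
    tibble::tibble(
      protein_id = protein_id,
      motif = motifs$name[m],
      start = starts - 1L,
      matched = substring(seq, starts, starts + len - 1L)
    )
  })
  if (nrow(hits) == 0L) {
    hits <- tibble::tibble(protein_id = character(0), motif = character(0),
                           start = integer(0), matched = character(0))
  }
  hits
}

#' Scan a protein set for terpene-synthase motifs
#'
#' @param proteins Tibble with columns `id` and `seq`.
#' @inheritParams scan_protein
#' @return Tibble of hits across all proteins (see [scan_protein()]).
#' @export
scan_proteins <- function(proteins, motifs = motif_definitions()) {
  hits <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    scan_protein(proteins$seq[i], motifs, protein_id = proteins$id[i])
  })
  if (nrow(hits) == 0L) {
    hits <- tibble::tibble(protein_id = character(0), motif = character(0),
                           start = integer(0), matched = character(0))
  }
  hits
}

#' Classify proteins as class I / class II terpene synthases
#'
#' A protein with a class I motif (1a or 1b) and no class II motif is
#' `classI_only`; with only DXDD it is `classII_only`; with motifs of both
#' classes it is `bifunctional`; with no motif, `none`.
#'
#' @param hits Hit tibble from [scan_proteins()].
#' @param protein_ids Ids of all screened proteins (so motif-free proteins
#'   are classified too).
#' @return Tibble `protein_id`, `has_1a`, `has_1b`, `has_2`, `category`.
#' @export
classify_terpene_synthase <- function(hits, protein_ids) {
  out <- tibble::tibble(
    protein_id = protein_ids,
    has_1a = protein_ids %in% hits$protein_id[hits$motif == "1a"],
    has_1b = protein_ids %in% hits$protein_id[hits$motif == "1b"],
    has_2 = protein_ids %in% hits$protein_id[hits$motif == "2"]
  )
  class_i <- out$has_1a | out$has_1b
  out$category <- dplyr::case_when(
    class_i & out$has_2 ~ "bifunctional",
    class_i ~ "classI_only",
    out$has_2 ~ "classII_only",
    .default = "none"
  )
  out$category <- factor(out$category,
                         levels = c("classI_only", "classII_only",
                                    "bifunctional", "none"))
  out
}

#' Summarise a terpene-synthase repertoire
#'
#' Tallies the category counts and the counts of every motif-presence
#' combination over \{1a, 1b, 2\}; totals sum to the number of proteins and
#' are invariant under input order.
#'
#' @param classifications Tibble from [classify_terpene_synthase()].
#' @return List with `by_category` and `by_combination` tibbles and
#'   `n_proteins`.
#' @export
summarize_repertoire <- function(classifications) {
  by_cat <- tibble::tibble(
    category = levels(classifications$category),
    n = as.integer(table(classifications$category))
  )
  combos <- tidyr::expand_grid(has_1a = c(FALSE, TRUE),
                               has_1b = c(FALSE, TRUE),
                               has_2 = c(FALSE, TRUE))
  by_combo <- dplyr::left_join(
    combos,
    dplyr::count(classifications, .data$has_1a, .data$has_1b, .data$has_2),
    by = c("has_1a", "has_1b", "has_2")
  )
  by_combo$n <- ifelse(is.na(by_combo$n), 0L, by_combo$n)
  list(
    n_proteins = nrow(classifications),
    by_category = by_cat,
    by_combination = by_combo
  )
}
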