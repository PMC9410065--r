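#' Read a FASTA file into a contig tibble
#'
#' Parses a (multi-record) FASTA file and returns one row per record with the
#' sequence upper-cased. For nucleotide input the per-contig GC fraction is
#' computed over non-N bases; for protein input the `gc` column is omitted.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` (default) or `"protein"`. DNA sequences are validated
#'   against the alphabet `A`, `C`, `G`, `T`, `N`.
#' @return A tibble with columns `id`, `seq`, `length` and (for DNA) `gc`.
#'   Record order follows the file. Duplicate ids are an error.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGTACGT"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate FASTA id: ", ids[duplicated(ids)][1]))
  }
  seqs <- unname(toupper(as.character(set)))
  out <- tibble::tibble(id = ids, seq = seqs, length = nchar(seqs))
  if (type == "dna") {
    bad <- stringr::str_detect(out$seq, "[^ACGTN]")
    if (any(bad)) {
      abort(paste0("illegal nucleotide character in record '", out$id[bad][1], "'"))
    }
    out$gc <- vapply(out$seq, gc_content, numeric(1), USE.NAMES = FALSE)
  } else {
    bad <- stringr::str_detect(out$seq, "[^ACDEFGHIKLMNPQRSTVWYX*]")
    if (any(bad)) {
      abort(paste0("illegal amino-acid character in record '", out$id[bad][1], "'"))
    }
  }
  out
}

# Cheap structural validation so format errors can name the offending line;
# record parsing itself is done by Biostrings.
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) abort("empty FASTA file")
  if (!startsWith(lines[nonblank[1]], ">")) {
    abort(paste0("malformed FASTA: line ", nonblank[1], " is not a header"))
  }
  headers <- which(startsWith(lines, ">"))
  for (h in headers) {
    if (nchar(trimws(sub("^>", "", lines[h]))) == 0L) {
      abort(paste0("malformed FASTA: empty header at line ", h))
    }
    nxt <- lines[h + 1L]
    if (is.na(nxt) || startsWith(nxt, ">") || !nzchar(trimws(nxt))) {
      abort(paste0("malformed FASTA: empty sequence for header at line ", h))
    }
  }
  invisible(TRUE)
}

#' Write contigs to a FASTA file
#'
#' Sequences are wrapped at 80 columns. Round-trips with [read_fasta()]
#' byte-identically at the residue level.
#'
#' @param contigs Tibble with columns `id` and `seq` (e.g. from
#'   [read_fasta()] or [simulate_dikaryon()]).
#' @param path Output path.
#' @param desc Optional character vector of description suffixes appended to
#'   each header after the id.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, desc = NULL) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  set <- Biostrings::BStringSet(contigs$seq)
  names(set) <- if (is.null(desc)) contigs$id else paste(contigs$id, desc)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' GC fraction of a nucleotide sequence
#'
#' Computes (#G + #C) / (#non-N bases). N bases are excluded from both
#' numerator and denominator; an all-N sequence yields `NA`.
#'
#' @param seq Nucleotide string over `A`, `C`, `G`, `T`, `N` (case
#'   insensitive).
#' @return GC fraction in \[0, 1\], or `NA_real_` for all-N input.
#' @examples
#' gc_content("ATGC") # 0.5
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (stringr::str_detect(seq, "[^ACGTN]")) {
    abort("illegal character: sequence alphabet is {A,C,G,T,N}")
  }
  informative <- stringr::str_count(seq, "[ACGT]")
  if (informative == 0L) return(NA_real_)
  stringr::str_count(seq, "[GC]") / informative
}

#' Whole-assembly summary statistics
#'
#' N50 is the length of the shortest contig in the smallest prefix of the
#' descending-sorted contig lengths whose cumulative sum reaches half the
#' total assembly length; when the half-total falls exactly on a cumulative
#' boundary, the contig closing the prefix defines N50. The reported GC
#' percentage is length-weighted across contigs and rounded half-up to one
#' decimal (the full-precision value is kept in attribute `gc_pct_full`).
#'
#' @param contigs Tibble with columns `length` and `gc` (see [read_fasta()]).
#' @return A one-row tibble (class `assembly_stats`) with `n_contigs`,
#'   `total_length`, `largest_contig`, `n50` and `gc_pct`.
#' @examples
#' ctg <- tibble::tibble(length = c(5, 4, 3, 2, 1), gc = rep(0.5, 5))
#' assembly_stats(ctg) # N50 = 4
#' @export
assembly_stats <- function(contigs) {
  if (nrow(contigs) == 0L) abort("assembly_stats: empty contig collection")
  stopifnot(all(c("length", "gc") %in% names(contigs)))
  len <- sort(contigs$length, decreasing = TRUE)
  total <- sum(as.numeric(len))
  n50 <- len[match(TRUE, cumsum(as.numeric(len)) >= total / 2)]
  gc_full <- sum(contigs$gc * as.numeric(contigs$length), na.rm = TRUE) /
    sum(as.numeric(contigs$length[!is.na(contigs$gc)]))
  out <- tibble::tibble(
    n_contigs = nrow(contigs),
    total_length = total,
    largest_contig = len[1],
    n50 = n50,
    gc_pct = floor(gc_full * 1000 + 0.5) / 10
  )
  attr(out, "gc_pct_full") <- gc_full * 100
  class(out) <- c("assembly_stats", class(out))
  out
}

#' Derive per-contig read counts from a PAF mapping
#'
#' Counts primary alignments per target contig from a minimap2-style PAF
#' file. Records carrying a `tp:A:S` (secondary) tag are ignored. When an
#' assembly is supplied, contigs without any mapped read are included with a
#' zero count.
#'
#' @param path PAF file (tab-separated, >= 12 columns).
#' @param contigs Optional contig tibble (columns `id`, `length`); provides
#'   zero-count rows and authoritative lengths.
#' @return Tibble `contig_id`, `length`, `read_count`.
#' @export
read_counts_from_paf <- function(path, contigs = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 12L)) {
    abort(paste0("malformed PAF: line ", which(nfield < 12L)[1],
                 " has fewer than 12 columns"))
  }
  target <- vapply(fields, `[[`, character(1), 6L)
  tlen <- as.numeric(vapply(fields, `[[`, character(1), 7L))
  secondary <- vapply(fields, function(f) {
    length(f) > 12L && any(f[13:length(f)] == "tp:A:S")
  }, logical(1))
  counts <- table(target[!secondary])
  if (is.null(contigs)) {
    ids <- sort(unique(target))
    len <- tlen[match(ids, target)]
  } else {
    ids <- contigs$id
    len <- contigs$length
  }
  tibble::tibble(
    contig_id = ids,
    length = len,
    read_count = as.integer(counts[ids]) |> (\(x) ifelse(is.na(x), 0L, x))()
  )
}

#' Read / write a per-contig read-count table
#'
#' Plain TSV with header `contig_id`, `length`, `read_count`.
#'
#' @param path TSV path.
#' @return `read_counts_tsv()` returns the tibble; `write_counts_tsv()`
#'   returns `path` invisibly.
#' @export
read_counts_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           contig_id = readr::col_character(),
                           length = readr::col_double(),
                           read_count = readr::col_double()
                         ))
  if (any(out$length <= 0)) {
    abort(paste0("zero-length contig in counts table: row ",
                 which(out$length <= 0)[1]))
  }
  out
}

#' @rdname read_counts_tsv
#' @param counts Tibble with columns `contig_id`, `length`, `read_count`.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts[, c("contig_id", "length", "read_count")], path)
  invisible(path)
}
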