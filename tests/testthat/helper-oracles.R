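# Shared fixture builders and independent oracles.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_protein <- function(n, x_prob = 0) {
  letters <- if (x_prob > 0) c(AA20, "X") else AA20
  probs <- if (x_prob > 0) c(rep((1 - x_prob) / 20, 20), x_prob) else NULL
  paste(sample(letters, n, replace = TRUE, prob = probs), collapse = "")
}

# substitute exactly n_subs random positions (returns sequence)
plant_substitutions <- function(seq, n_subs, alphabet = c("A", "C", "G", "T")) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(ch), n_subs)
  for (p in pos) ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
  list(seq = paste(ch, collapse = ""), pos = sort(pos))
}

# N50 by explicit prefix enumeration
brute_n50 <- function(lengths) {
  len <- sort(lengths, decreasing = TRUE)
  total <- sum(len)
  for (i in seq_along(len)) {
    if (sum(len[seq_len(i)]) >= total / 2) return(len[i])
  }
}

# length-weighted GC percent by direct base counting
brute_gc_pct <- function(seqs) {
  ch <- unlist(strsplit(seqs, "", fixed = TRUE))
  100 * sum(ch %in% c("G", "C")) / sum(ch != "N")
}

# lower weighted median by enumeration over candidate values
brute_weighted_median <- function(x, w) {
  half <- sum(w) / 2
  for (v in sort(unique(x))) {
    if (sum(w[x <= v]) >= half) return(v)
  }
}

# regex-engine motif oracle (overlapping matches via lookahead)
oracle_motif_hits <- function(seq, protein_id = NA_character_) {
  wc <- "[ACDEFGHIKLMNPQRSTVWY]"
  pats <- list(
    `1a` = paste0("(?=DD", wc, "{2}[DE])"),
    `1b` = paste0("(?=[ND]D", wc, "{2}[ST]", wc, "{3}E)"),
    `2` = paste0("(?=D", wc, "DD)")
  )
  out <- lapply(names(pats), function(nm) {
    m <- gregexpr(pats[[nm]], seq, perl = TRUE)[[1]]
    starts <- as.integer(m)
    starts <- starts[starts > 0]
    if (length(starts) == 0) return(NULL)
    tibble::tibble(protein_id = protein_id, motif = nm, start = starts - 1L)
  })
  dplyr::bind_rows(out)
}

glance_counts <- function(aln) {
  g <- generics::glance(aln)
  g[, c("alignment_length", "identical", "mismatches", "gaps", "score")]
}
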