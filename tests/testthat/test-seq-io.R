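test_that("read_fasta parses records, upper-cases, and computes GC", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), tf)
  ctg <- read_fasta(tf)
  expect_equal(ctg$id, "c1")
  expect_equal(ctg$seq, "ACGT")
  expect_equal(ctg$length, 4L)
  expect_equal(ctg$gc, 0.5)
})

test_that("read_fasta rejects duplicate ids and malformed records by line", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c1", "GGCC"), tf)
  expect_error(read_fasta(tf), "duplicate")

  writeLines(c(">c1", "ACGT", ">c2", ">c3", "GG"), tf)
  expect_error(read_fasta(tf), "line 3")

  writeLines(c("ACGT"), tf)
  expect_error(read_fasta(tf), "line 1")
})

test_that("FASTA write/read round-trips residues on random assemblies", {
  set.seed(11)
  for (i in 1:5) {
    contigs <- tibble::tibble(
      id = sprintf("ctg%02d", 1:8),
      seq = vapply(sample(50:400, 8), rand_dna, character(1))
    )
    tf <- withr::local_tempfile(fileext = ".fa")
    write_fasta(contigs, tf)
    back <- read_fasta(tf)
    expect_identical(back$id, contigs$id)
    expect_identical(back$seq, contigs$seq)
  }
})

test_that("gc_content handles N exclusion, degenerate and sampled input", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("AANN"), 0)
  expect_true(is.na(gc_content("NNNN")))
  expect_error(gc_content("ACGU"), "alphabet")

  set.seed(271)
  s <- rand_dna(10000, gc = 0.271)
  expect_lt(abs(gc_content(s) - 0.271), 0.02)
})

test_that("assembly_stats matches brute force and is order-invariant", {
  ctg <- tibble::tibble(length = c(5, 4, 3, 2, 1), gc = rep(0.5, 5))
  st <- assembly_stats(ctg)
  expect_equal(st$total_length, 15)
  expect_equal(st$n50, 4)

  one <- assembly_stats(tibble::tibble(length = 1234, gc = 0.4))
  expect_equal(one$n50, 1234)
  expect_equal(one$largest_contig, 1234)

  expect_error(assembly_stats(tibble::tibble(length = numeric(0),
                                             gc = numeric(0))), "empty")

  set.seed(21)
  for (i in 1:50) {
    lens <- sample(1:5000, sample(2:30, 1), replace = TRUE)
    gcs <- runif(length(lens))
    ctg <- tibble::tibble(length = lens, gc = gcs)
    st <- assembly_stats(ctg)
    expect_equal(st$n50, brute_n50(lens))
    expect_equal(st$largest_contig, max(lens))
    expect_lte(st$n50, st$largest_contig)
    # reordering contigs leaves every statistic unchanged
    st2 <- assembly_stats(ctg[sample(nrow(ctg)), ])
    expect_equal(tibble::as_tibble(st), tibble::as_tibble(st2))
  }
})

test_that("PAF read counting keeps primaries and zero-count contigs", {
  tf <- withr::local_tempfile(fileext = ".paf")
  line <- function(read, target, tag = "tp:A:P") {
    paste(read, 100, 0, 100, "+", target, 5000, 0, 100, 100, 100, 60, tag,
          sep = "\t")
  }
  writeLines(c(line("r1", "c1"), line("r2", "c1"), line("r3", "c1"),
               line("r4", "c2"), line("r5", "c2", tag = "tp:A:S")), tf)
  counts <- read_counts_from_paf(tf)
  expect_equal(counts$read_count[counts$contig_id == "c1"], 3L)
  expect_equal(counts$read_count[counts$contig_id == "c2"], 1L)

  contigs <- tibble::tibble(id = c("c1", "c2", "c3"),
                            length = c(5000, 5000, 700))
  counts2 <- read_counts_from_paf(tf, contigs)
  expect_equal(counts2$read_count[counts2$contig_id == "c3"], 0L)

  writeLines("r1\t100\t0\t100\t+\tc1\t5000", tf)
  expect_error(read_counts_from_paf(tf), "12 columns")
})
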