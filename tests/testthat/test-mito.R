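test_that("mito candidacy requires both GC deviation and over-representation", {
  set.seed(61)
  contigs <- tibble::tibble(
    id = c(sprintf("nuc%02d", 1:10), "mt", "rep"),
    length = c(rep(50000, 10), 40000, 30000),
    gc = c(runif(10, 0.48, 0.50), 0.271, 0.49)
  )
  counts <- tibble::tibble(
    contig_id = contigs$id,
    length = contigs$length,
    read_count = round(c(rep(1, 10), 20, 20) * contigs$length * 0.003)
  )
  cls <- classify_coverage(counts, estimate_baseline(counts))
  cand <- find_mito_candidates(contigs, cls)
  expect_equal(cand$contig_id[cand$candidate], "mt")
  # the collapsed-repeat contig is group IV but fails the GC criterion
  expect_true(cand$passes_coverage[cand$contig_id == "rep"])
  expect_false(cand$passes_gc[cand$contig_id == "rep"])
})

test_that("GC-only candidacy is flagged provisional", {
  contigs <- tibble::tibble(id = c("a", "b"), length = c(5e4, 4e4),
                            gc = c(0.49, 0.27))
  cand <- find_mito_candidates(contigs)
  expect_true(all(cand$provisional))
  expect_equal(cand$contig_id[cand$candidate], "b")
})

test_that("an exact two-unit tandem repeat is detected with full support", {
  set.seed(62)
  u <- rand_dna(5000, gc = 0.27)
  rep <- detect_tandem_duplication(paste0(u, u))
  expect_true(rep$duplicated)
  expect_equal(rep$period, 5000L)
  expect_gte(rep$support, 0.99)

  bis <- bisect_mito(paste0(u, u), rep)
  expect_equal(bis$mt1, bis$mt2)
  expect_equal(sum(bis$lengths), 10000L)
  # equals the lexicographically smallest rotation of the unit (brute force)
  rotations <- vapply(0:4999, function(r) {
    paste0(substr(u, r + 1, 5000), substr(u, 1, r))
  }, character(1))
  expect_equal(bis$mt1, min(rotations))
})

test_that("random sequence is not called tandem-duplicated", {
  set.seed(63)
  rep <- detect_tandem_duplication(rand_dna(10000))
  expect_false(rep$duplicated)
  expect_error(detect_tandem_duplication(rand_dna(50)), "4k")
  expect_error(bisect_mito(rand_dna(10000), rep), "not tandem")
})

test_that("mutated tandem units are recovered with planted edit counts", {
  cfg <- scenario_config(seed = 8, n_nuclear_pairs = 0, mito_len = 5000)
  sc <- simulate_dikaryon(cfg)
  seq <- sc$contigs$seq[sc$contigs$id == "mito_tandem"]
  expect_equal(nchar(seq), 10091L)

  rep <- detect_tandem_duplication(seq)
  expect_true(rep$duplicated)
  expect_gte(rep$period, 5000L)
  expect_lte(rep$period, 5091L)

  bis <- bisect_mito(seq, rep)
  expect_setequal(bis$lengths, c(5000L, 5091L))
  expect_equal(abs(diff(bis$lengths)), 91L)

  aln <- compare_mito_units(bis)
  expect_equal(aln$mismatches, 40L)
  expect_equal(aln$gaps, 91L)
  expect_equal(aln$identity_pct,
               floor(1e4 * aln$identical / aln$alignment_length) / 100)
})

test_that("two_variants and single modes shape the assembly accordingly", {
  sc2 <- simulate_dikaryon(scenario_config(seed = 9, n_nuclear_pairs = 0,
                                           mito_len = 5000,
                                           mito_mode = "two_variants"))
  expect_setequal(sc2$truth$mito$contig_ids, c("mito_1", "mito_2"))
  s1 <- sc2$contigs$seq[sc2$contigs$id == "mito_1"]
  s2 <- sc2$contigs$seq[sc2$contigs$id == "mito_2"]
  aln <- align_pair(s1, s2)
  expect_equal(aln$mismatches, 40L)
  expect_equal(aln$gaps, 91L)

  sc3 <- simulate_dikaryon(scenario_config(seed = 9, n_nuclear_pairs = 0,
                                           mito_len = 5000,
                                           mito_mode = "single"))
  expect_false(detect_tandem_duplication(
    sc3$contigs$seq[sc3$contigs$id == "mito"])$duplicated)
})
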