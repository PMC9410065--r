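test_that("anchors are unique-unique shared k-mers, symmetric, strand-aware", {
  set.seed(51)
  a <- rand_dna(1000)
  anc <- find_anchors(a, a)
  expect_true(all(anc$pos_a == anc$pos_b))
  expect_gt(nrow(anc), 900)

  b <- rand_dna(1200)
  ab <- find_anchors(a, b)
  ba <- find_anchors(b, a)
  expect_setequal(paste(ab$pos_a, ab$pos_b), paste(ba$pos_b, ba$pos_a))

  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", a), "")[[1]]), collapse = "")
  expect_equal(nrow(find_anchors(a, rc)), 0L)

  expect_error(find_anchors(a, b, k = 9), ">= 11")
})

test_that("anchors of a planted shared segment stay inside the segment", {
  set.seed(52)
  shared <- rand_dna(500)
  a <- paste0(rand_dna(2000), shared, rand_dna(2500))
  b <- paste0(rand_dna(1000), shared, rand_dna(3500))
  anc <- find_anchors(a, b)
  expect_gt(nrow(anc), 400)
  expect_true(all(anc$pos_a >= 2000 & anc$pos_a + 21 <= 2500))
  expect_true(all(anc$pos_b >= 1000 & anc$pos_b + 21 <= 1500))
})

test_that("identical contigs give one full-identity block", {
  set.seed(53)
  a <- rand_dna(10000)
  blocks <- chain_and_blocks(a, a)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$identity_pct, 100)
  expect_equal(blocks$start_a, 0L)
  expect_equal(blocks$end_a, 10000)
})

test_that("an unrelated insert beyond max_gap splits a pair into two blocks", {
  set.seed(54)
  seg1 <- rand_dna(5000)
  seg2 <- rand_dna(4000)
  a <- paste0(seg1, seg2)
  b <- paste0(seg1, rand_dna(10000), seg2)
  blocks <- chain_and_blocks(a, b, max_gap = 2000)
  expect_equal(nrow(blocks), 2L)
  # and no reported block is shorter than min_block
  short <- chain_and_blocks(rand_dna(900), rand_dna(900), min_block = 1000)
  expect_equal(nrow(short), 0L)
})

test_that("a 100-kb pair at 1% divergence yields one ~99%-identity block", {
  set.seed(55)
  a <- rand_dna(100000)
  b <- plant_substitutions(a, 1000)$seq
  blocks <- chain_and_blocks(a, b)
  expect_equal(nrow(blocks), 1L)
  expect_gte(blocks$end_a - blocks$start_a, 99000)
  expect_gt(blocks$identity_pct, 98.5)
  expect_lt(blocks$identity_pct, 99.5)
})

test_that("all_vs_all reports exactly the planted allelic pairs", {
  cfg <- scenario_config(seed = 3, n_nuclear_pairs = 3,
                         contig_len_range = c(15000, 25000),
                         mito_len = 5000)
  sc <- simulate_dikaryon(cfg)
  blocks <- all_vs_all(sc$contigs)
  found <- unique(paste(blocks$contig_a, blocks$contig_b))
  planted <- paste(sc$truth$allelic_pairs$contig_a,
                   sc$truth$allelic_pairs$contig_b)
  expect_setequal(found, planted)

  # largest reported block matches the planted largest homologous region
  largest <- max(blocks$end_a - blocks$start_a)
  expect_lt(abs(largest - max(sc$truth$allelic_pairs$region_len)) /
              max(sc$truth$allelic_pairs$region_len), 0.02)

  # invariance under contig input order
  perm <- sc$contigs[sample(nrow(sc$contigs)), ]
  blocks2 <- all_vs_all(perm)
  expect_equal(blocks[, 1:8], blocks2[, 1:8])
})

test_that("unrelated contigs produce an empty pair table", {
  set.seed(56)
  contigs <- tibble::tibble(id = c("x", "y", "z"),
                            seq = vapply(rep(8000, 3), rand_dna, character(1)))
  expect_equal(nrow(all_vs_all(contigs)), 0L)
})

test_that("divergence profiles localise differences and count gap runs once", {
  set.seed(57)
  a <- rand_dna(10000)
  prof0 <- divergence_profile(align_pair(a, a), window = 1000)
  expect_true(all(prof0$count == 0))

  # plant all 50 substitutions inside one window
  ch <- strsplit(a, "")[[1]]
  pos <- sample(4001:5000, 50)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  b <- paste(ch, collapse = "")
  prof <- divergence_profile(align_pair(a, b), window = 1000)
  expect_equal(sum(prof$count), 50)
  expect_equal(prof$count[5], 50)

  # one 35-base deletion counts as a single difference event
  b2 <- paste0(substr(a, 1, 2000), substr(a, 2036, 10000))
  aln <- align_pair(a, b2)
  prof2 <- divergence_profile(aln, window = 1000)
  expect_equal(sum(prof2$count), 1)
  expect_equal(aln$gaps, 35L)

  expect_error(divergence_profile(aln, window = 50), ">= 100")
})

test_that("uniform divergence is Poisson-dispersed across windows", {
  set.seed(58)
  rejections <- 0
  for (i in 1:30) {
    a <- rand_dna(20000)
    b <- plant_substitutions(a, rbinom(1, 20000, 0.01))$seq
    prof <- divergence_profile(align_pair(a, b), window = 1000)
    cnt <- prof$count
    stat <- sum((cnt - mean(cnt))^2) / mean(cnt)
    p <- stats::pchisq(stat, df = length(cnt) - 1, lower.tail = FALSE)
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 3)
})
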