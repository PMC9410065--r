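make_records <- function(lengths, multiples, depth = 30, read_len = 10000,
                         noise = FALSE) {
  lam <- multiples * lengths * depth / read_len
  tibble::tibble(
    contig_id = sprintf("c%03d", seq_along(lengths)),
    length = lengths,
    read_count = if (noise) rpois(length(lam), lam) else round(lam)
  )
}

test_that("baseline is the length-weighted median density", {
  rec <- make_records(rep(1e5, 4), rep(1, 4))
  expect_equal(estimate_baseline(rec), 30 / 10000)

  # two 100-kb contigs at density d and one at 2d -> baseline d
  rec <- tibble::tibble(contig_id = c("a", "b", "c"),
                        length = rep(1e5, 3),
                        read_count = c(300, 300, 600))
  expect_equal(estimate_baseline(rec), 0.003)

  expect_error(estimate_baseline(rec, min_len = 1e7), "no contig")

  set.seed(5)
  for (i in 1:40) {
    n <- sample(3:12, 1)
    rec <- tibble::tibble(contig_id = as.character(1:n),
                          length = sample(10000:50000, n),
                          read_count = sample(10:500, n))
    expect_equal(estimate_baseline(rec, min_len = 0),
                 brute_weighted_median(rec$read_count / rec$length,
                                       rec$length))
  }
})

test_that("multiples map onto groups with left-closed boundaries", {
  rec <- make_records(rep(1e5, 6), c(1, 2, 20, 100, 0.2, 1.5))
  cls <- classify_coverage(rec, baseline = 30 / 10000)
  expect_equal(as.character(cls$group),
               c("II", "III", "IV", "V", "I", "III"))
  # every contig gets exactly one label
  expect_false(anyNA(cls$group))
})

test_that("classification is invariant under count rescaling", {
  set.seed(9)
  rec <- make_records(runif(20, 5e4, 2e5),
                      sample(c(0.2, 1, 2, 20, 100), 20, replace = TRUE),
                      noise = TRUE)
  cls1 <- classify_coverage(rec, estimate_baseline(rec))
  rec2 <- dplyr::mutate(rec, read_count = read_count * 7)
  cls2 <- classify_coverage(rec2, estimate_baseline(rec2))
  expect_identical(as.character(cls1$group), as.character(cls2$group))
})

test_that("diploid-character rule combines length fractions and markers", {
  rec <- make_records(rep(1e5, 10), rep(1, 10))
  cls <- classify_coverage(rec, 30 / 10000)
  # all group II, no group III, no marker data -> not called diploid
  expect_false(ploidy_report(cls)$diploid_character)
  # marker duplication rescues the call
  expect_true(ploidy_report(cls, dup_fraction = 0.5)$diploid_character)

  # contamination-only scenario
  rec <- make_records(rep(1e5, 5), rep(0.2, 5))
  cls <- classify_coverage(rec, 30 / 10000)
  rep <- ploidy_report(cls)
  expect_false(rep$diploid_character)
  expect_equal(rep$frac_len_II, 0)
})

test_that("simulated dikaryon yields a diploid call and accurate baseline", {
  sc <- simulate_dikaryon(scenario_config(seed = 1))
  base <- estimate_baseline(sc$counts)
  truth_density <- sc$truth$config$depth / sc$truth$config$read_len
  expect_lt(abs(base - truth_density) / truth_density, 0.1)

  cls <- classify_coverage(sc$counts, base)
  expect_true(ploidy_report(cls)$diploid_character)

  # half the assembly collapsed (2x), half divergent (1x), short-read depth
  sc2 <- simulate_dikaryon(scenario_config(seed = 1,
                                           frac_identical_regions = 2 / 3,
                                           mito_len = 5000,
                                           depth = 60, read_len = 150))
  base2 <- estimate_baseline(sc2$counts)
  truth2 <- 60 / 150
  expect_lt(abs(base2 - truth2) / truth2, 0.1)
})

test_that("triage tibble supports tidy/glance/autoplot", {
  rec <- make_records(rep(1e5, 5), c(0.2, 1, 2, 20, 100))
  cls <- classify_coverage(rec, 30 / 10000)
  expect_s3_class(tidy(cls), "tbl_df")
  g <- glance(cls)
  expect_equal(g$n_II, 1L)
  expect_equal(g$n_contigs, 5L)
  p <- autoplot(cls)
  expect_s3_class(p, "ggplot")
})
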