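test_that("exact single-copy markers are all single with zero duplication", {
  set.seed(71)
  markers <- tibble::tibble(id = sprintf("m%02d", 1:10),
                            seq = vapply(sample(150:300, 10), rand_protein,
                                         character(1)))
  proteins <- tibble::tibble(id = sprintf("p%02d", 1:10), seq = markers$seq)
  res <- assess_markers(proteins, markers)
  expect_true(all(res$status == "single"))
  expect_equal(glance(res)$dup_fraction, 0)
  expect_error(assess_markers(proteins, markers[0, ]), "empty marker")
})

test_that("a half-length protein copy is called fragmented", {
  set.seed(72)
  mk <- rand_protein(300)
  markers <- tibble::tibble(id = "m1", seq = mk)
  proteins <- tibble::tibble(id = "p1", seq = substr(mk, 1, 150))
  res <- assess_markers(proteins, markers)
  expect_equal(as.character(res$status), "fragmented")
  # an unrelated protein set leaves the marker missing
  res2 <- assess_markers(tibble::tibble(id = "q", seq = rand_protein(300)),
                         markers)
  expect_equal(as.character(res2$status), "missing")
})

test_that("simulated dikaryon markers recover the planted duplication", {
  sc <- simulate_dikaryon(scenario_config(seed = 13, n_nuclear_pairs = 0,
                                          mito_len = 5000, n_markers = 20))
  res <- assess_markers(sc$proteins, sc$markers)
  expect_identical(as.character(res$status), sc$truth$markers$status)
  expect_equal(glance(res)$dup_fraction, 0.5)
})

test_that("reciprocal best matching recovers planted orthologs, resists paralogs", {
  set.seed(73)
  expect_equal(nrow(reciprocal_best_match(
    tibble::tibble(id = "a1", seq = rand_protein(200)),
    tibble::tibble(id = "b1", seq = rand_protein(200))
  )), 0L)

  base <- vapply(rep(200, 6), rand_protein, character(1))
  mutate_prot <- function(s, frac) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), round(frac * length(ch)))
    for (p in pos) ch[p] <- sample(setdiff(AA20, ch[p]), 1)
    paste(ch, collapse = "")
  }
  set_a <- tibble::tibble(id = sprintf("a%d", 1:6), seq = base)
  set_b <- tibble::tibble(id = sprintf("b%d", 1:6),
                          seq = vapply(base, mutate_prot, character(1), 0.2))
  rbm <- reciprocal_best_match(set_a, set_b, identity_min = 60)
  expect_equal(nrow(rbm), 6L)
  expect_identical(sub("a", "", rbm$protein_a), sub("b", "", rbm$protein_b))

  # a near-identical paralog of a1 does not add a pair
  set_a2 <- dplyr::bind_rows(set_a, tibble::tibble(
    id = "a1_paralog", seq = mutate_prot(base[1], 0.01)
  ))
  rbm2 <- reciprocal_best_match(set_a2, set_b, identity_min = 60)
  expect_equal(nrow(rbm2), 6L)
})

test_that("pan-genome accounting obeys its arithmetic invariant", {
  pc <- pangenome_counts(5, 5, 3)
  expect_equal(pc$pan, 13)
  expect_equal(glance(pc)$pan, 13)

  set.seed(74)
  seqs_a <- vapply(rep(180, 10), rand_protein, character(1))
  seqs_b <- c(seqs_a[1:5], vapply(rep(180, 3), rand_protein, character(1)))
  set_a <- tibble::tibble(id = sprintf("a%02d", 1:10), seq = seqs_a)
  set_b <- tibble::tibble(id = sprintf("b%02d", 1:8), seq = seqs_b)
  orth <- tibble::tibble(protein_a = set_a$id[1:5], protein_b = set_b$id[1:5])
  pc <- compute_pangenome(orth, set_a, set_b)
  expect_equal(pc$core, 5)
  expect_equal(pc$singletons_a, 5)
  expect_equal(pc$singletons_b, 3)
  expect_equal(pc$pan, 13)

  # identical proteomes: all core, no singletons
  pc2 <- compute_pangenome(
    tibble::tibble(protein_a = set_a$id, protein_b = paste0("x", set_a$id)),
    set_a, tibble::tibble(id = paste0("x", set_a$id), seq = set_a$seq)
  )
  expect_equal(pc2$pan, 10)
  expect_equal(pc2$singletons_a + pc2$singletons_b, 0)

  bad <- tibble::tibble(protein_a = c("a01", "a01"),
                        protein_b = c("b01", "b02"))
  expect_error(compute_pangenome(bad, set_a, set_b), "one-to-one")
})
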