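two_species_ds <- function() {
  cl <- dplyr::bind_rows(
    tibble::tibble(cluster_id = "c1", species_pair = "CEL-DME",
                   species = c("CEL", "DME"),
                   protein_id = c("w1", "f1"), inparalog_score = c(1, 1)),
    tibble::tibble(cluster_id = "c2", species_pair = "CEL-DME",
                   species = c("CEL", "DME"),
                   protein_id = c("w2", "f2"), inparalog_score = c(1, 1)))
  ia <- tibble::tibble(species = "DME", source_id = "f1",
                       target_id = "f2", evidence = "direct",
                       effect = "stimulation", pmids = list(integer()))
  signalog_dataset(clusters = cl, interactions = ia)
}

test_that("one source interaction maps to exactly one interolog", {
  ds <- two_species_ds()
  il <- derive_interologs(ds, "CEL")
  expect_equal(nrow(il), 1)
  expect_equal(il$protein_a, "w1")
  expect_equal(il$protein_b, "w2")
  expect_equal(il$provenance, "DME:f1->f2")
})

test_that("endpoints without orthologs contribute nothing", {
  ds <- two_species_ds()
  ds$interactions <- tibble::tibble(
    species = "DME", source_id = "f1", target_id = "orphan",
    evidence = "direct", effect = "unknown", pmids = list(integer()))
  expect_equal(nrow(derive_interologs(ds, "CEL")), 0)
})

test_that("self-pairs are suppressed, duplication cases kept", {
  # one fly self-interaction whose single ortholog would give w1-w1
  cl <- tibble::tibble(
    cluster_id = "c1", species_pair = "CEL-DME",
    species = c("CEL", "CEL", "DME"),
    protein_id = c("w1", "w1b", "f1"),
    inparalog_score = c(1, 0.8, 1))
  ia <- tibble::tibble(species = "DME", source_id = "f1",
                       target_id = "f1", evidence = "direct",
                       effect = "unknown", pmids = list(integer()))
  ds <- signalog_dataset(clusters = cl, interactions = ia)
  il <- derive_interologs(ds, "CEL")
  # f1 maps to both w1 and w1b: the cross pair survives, self-pairs die
  expect_equal(nrow(il), 1)
  expect_setequal(c(il$protein_a, il$protein_b), c("w1", "w1b"))
})

test_that("interolog derivation matches the quadruple-loop oracle", {
  set.seed(211)
  for (i in 1:40) {
    ds <- rand_dataset(n_per = sample(4:10, 1), n_int = sample(3:8, 1))
    tgt <- sample(ds$species, 1)
    il <- derive_interologs(ds, tgt)
    expect_equal(interolog_keys(il), oracle_interologs(ds, tgt))
  }
})

test_that("canonical pair order: (a,b) and (b,a) never both appear", {
  set.seed(223)
  for (i in 1:10) {
    ds <- rand_dataset(n_per = 8, n_int = 10)
    il <- derive_interologs(ds, ds$species[1])
    expect_true(all(norm_id(il$protein_a) <= norm_id(il$protein_b)))
    expect_false(any(duplicated(interolog_keys(il))))
  }
})

test_that("derivation is invariant to input row order", {
  set.seed(227)
  ds <- rand_dataset(n_per = 8, n_int = 10)
  ds2 <- ds
  ds2$interactions <- ds2$interactions[rev(seq_len(nrow(ds2$interactions))), ]
  ds2$clusters <- ds2$clusters[order(ds2$clusters$protein_id), ]
  tgt <- ds$species[2]
  expect_equal(tibble::as_tibble(derive_interologs(ds, tgt)),
               tibble::as_tibble(derive_interologs(ds2, tgt)))
})

test_that("signalog-touching filter keeps the right subset", {
  ds <- two_species_ds()
  il <- derive_interologs(ds, "CEL")
  none <- filter_signalog_touching(il, signalogr:::empty_predictions("CEL"))
  expect_equal(nrow(none), 0)
  p <- as_signalog_predictions(tibble::tibble(
    species = "CEL", protein_id = "w1", pathway = "Notch"))
  both <- filter_signalog_touching(il, p)
  expect_equal(nrow(both), 1)
  set.seed(229)
  ds2 <- rand_dataset(n_per = 10, n_int = 12)
  tgt <- ds2$species[1]
  il2 <- derive_interologs(ds2, tgt)
  p2 <- predict_signalogs(ds2, tgt)
  kept <- filter_signalog_touching(il2, p2)
  sig <- norm_id(p2$protein_id)
  expect_true(all(interolog_keys(kept) %in% interolog_keys(il2)))
  manual <- il2[norm_id(il2$protein_a) %in% sig |
                  norm_id(il2$protein_b) %in% sig, ]
  expect_equal(interolog_keys(kept), interolog_keys(manual))
})

test_that("interolog set comparison reports correct set algebra", {
  ds <- two_species_ds()
  il <- derive_interologs(ds, "CEL")
  same <- compare_interolog_sets(il, il)
  expect_equal(same$pct_shared_of_union, 100)
  expect_equal(same$n_only_a, 0)

  other <- tibble::tibble(species = "CEL", protein_a = "x1",
                          protein_b = "x2", provenance = "")
  disj <- compare_interolog_sets(il, other)
  expect_equal(disj$n_shared, 0)
  expect_equal(disj$pct_shared_of_union, 0)

  set.seed(233)
  for (i in 1:10) {
    mk <- function(n) tibble::tibble(
      species = "CEL",
      protein_a = sprintf("p%d", sample(1:12, n, replace = TRUE)),
      protein_b = sprintf("p%d", sample(13:25, n, replace = TRUE)),
      provenance = "")
    a <- mk(8); b <- mk(8)
    res <- compare_interolog_sets(a, b)
    ka <- unique(paste(pmin(norm_id(a$protein_a), norm_id(a$protein_b)),
                       pmax(norm_id(a$protein_a), norm_id(a$protein_b))))
    kb <- unique(paste(pmin(norm_id(b$protein_a), norm_id(b$protein_b)),
                       pmax(norm_id(b$protein_a), norm_id(b$protein_b))))
    expect_equal(res$n_shared, length(intersect(ka, kb)))
    expect_equal(res$n_shared + res$n_only_a, res$n_a)
    expect_equal(res$pct_shared_of_union,
                 percent1(100 * length(intersect(ka, kb)) /
                            length(union(ka, kb))))
  }
  expect_error(compare_interolog_sets(
    il, tibble::tibble(species = "HSA", protein_a = "a", protein_b = "b",
                       provenance = "")), "different species")
})
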