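test_that("the Notch fixture yields six new-protein worm predictions", {
  ds <- load_fixture("table1_notch")
  p <- predict_signalogs(ds, "CEL")
  expect_equal(nrow(p), 6)
  expect_true(all(p$pathway == "Notch"))
  expect_true(all(p$is_new_protein))
  expect_setequal(p$protein_id, c("aqp-6", "crb-1", "D1009.3",
                                  "F10D7.5", "nsh-1", "num-1"))
  # provenance merges both source species where both orthologs exist
  expect_match(p$provenance[p$protein_id == "num-1"], "DME:numb")
  expect_match(p$provenance[p$protein_id == "num-1"], "HSA:NUMB")
})

test_that("no source annotations means no predictions", {
  ds <- load_fixture("table1_notch")
  ds$annotations <- ds$annotations[0, ]
  p <- predict_signalogs(ds, "CEL")
  expect_equal(nrow(p), 0)
})

test_that("prediction matches the brute-force triple-loop oracle", {
  set.seed(101)
  for (i in 1:40) {
    ds <- rand_dataset(n_per = sample(4:10, 1),
                       n_clusters = sample(2:5, 1))
    tgt <- sample(ds$species, 1)
    p <- predict_signalogs(ds, tgt)
    expect_equal(prediction_keys(p), oracle_predict(ds, tgt))
  }
})

test_that("no emitted membership pre-exists in the target species", {
  set.seed(113)
  for (i in 1:15) {
    ds <- rand_dataset(n_per = 8, p_annot = 0.7)
    for (tgt in ds$species) {
      p <- predict_signalogs(ds, tgt)
      known <- paste(norm_id(
        ds$annotations$protein_id[ds$annotations$species == tgt]),
        ds$annotations$pathway[ds$annotations$species == tgt])
      expect_false(any(prediction_keys(p) %in% known))
    }
  }
})

test_that("every provenance entry independently justifies its prediction", {
  set.seed(127)
  ds <- rand_dataset(n_per = 10, p_annot = 0.6)
  p <- predict_signalogs(ds, ds$species[1])
  entries <- tidy(p)
  ann_key <- paste(norm_id(ds$annotations$species),
                   norm_id(ds$annotations$protein_id),
                   ds$annotations$pathway)
  expect_gt(nrow(entries), 0)
  expect_true(all(paste(norm_id(entries$source_species),
                        norm_id(entries$ortholog_id),
                        entries$pathway) %in% ann_key))
})

test_that("predictions at a higher threshold are a subset", {
  set.seed(139)
  for (i in 1:10) {
    ds <- rand_dataset(n_per = 8)
    tgt <- ds$species[1]
    lo <- prediction_keys(predict_signalogs(ds, tgt, threshold = 0.1))
    hi <- prediction_keys(predict_signalogs(ds, tgt, threshold = 0.6))
    expect_true(all(hi %in% lo))
  }
})

test_that("identical inputs give identical sorted output", {
  set.seed(149)
  ds <- rand_dataset(n_per = 10)
  p1 <- predict_signalogs(ds, ds$species[2])
  p2 <- predict_signalogs(ds, ds$species[2])
  expect_identical(p1, p2)
  expect_false(is.unsorted(norm_id(p1$protein_id)))
})

test_that("an annotated protein can gain a different pathway", {
  cl <- tibble::tibble(
    cluster_id = "c1", species_pair = "CEL-HSA",
    species = c("CEL", "HSA"), protein_id = c("dual-1", "DUAL"),
    inparalog_score = c(1, 1))
  ann <- tibble::tibble(
    species = c("CEL", "HSA", "HSA"),
    protein_id = c("dual-1", "DUAL", "DUAL"),
    pathway = c("WNT", "WNT", "Notch"),
    role = "other", pmids = list(integer(), integer(), integer()))
  ds <- signalog_dataset(clusters = cl, annotations = ann)
  p <- predict_signalogs(ds, "CEL")
  expect_equal(p$pathway, "Notch")
  expect_false(p$is_new_protein)
})

test_that("require_no_interactions excludes interacting proteins", {
  ds <- load_fixture("table1_notch")
  ds$interactions <- tibble::tibble(
    species = "CEL", source_id = "num-1", target_id = "crb-1",
    evidence = "direct", effect = "unknown", pmids = list(integer()))
  p <- predict_signalogs(ds, "CEL", require_no_interactions = TRUE)
  expect_equal(nrow(p), 4)
  expect_false(any(p$protein_id %in% c("num-1", "crb-1")))
})

test_that("self-transfer is impossible by construction", {
  ds <- load_fixture("table1_notch")
  p <- predict_signalogs(ds, "DME")
  # fly orthologs of worm genes: the worm genes carry no annotations,
  # so nothing can transfer INTO fly from worm; human Notch members
  # have no fly cluster links in this fixture
  expect_equal(nrow(p), 0)
  expect_error(predict_signalogs(ds, "XXX"), "configured species")
})

test_that("summary counts satisfy the multi-pathway identity", {
  set.seed(163)
  for (i in 1:10) {
    ds <- rand_dataset(n_per = 10, p_annot = 0.7)
    p <- predict_signalogs(ds, ds$species[1])
    s <- summarize_predictions(p)
    expect_equal(s$n_annotations,
                 (s$n_signalog_proteins - s$n_multi_pathway_proteins) +
                   s$n_annotations_of_multi)
    expect_equal(sum(s$per_pathway$n), s$n_annotations)
  }
  s0 <- summarize_predictions(signalogr:::empty_predictions("CEL"))
  expect_equal(s0$n_signalog_proteins, 0)
  expect_equal(s0$n_annotations, 0)
})

test_that("coverage is 100% when every ortholog shares the pathway", {
  cl <- dplyr::bind_rows(
    tibble::tibble(cluster_id = "c1", species_pair = "CEL-HSA",
                   species = c("CEL", "HSA"),
                   protein_id = c("a1", "h1"), inparalog_score = c(1, 1)),
    tibble::tibble(cluster_id = "c2", species_pair = "CEL-DME",
                   species = c("CEL", "DME"),
                   protein_id = c("a1", "d1"), inparalog_score = c(1, 1)),
    tibble::tibble(cluster_id = "c3", species_pair = "DME-HSA",
                   species = c("DME", "HSA"),
                   protein_id = c("d1", "h1"), inparalog_score = c(1, 1)))
  ann <- tibble::tibble(species = c("CEL", "DME", "HSA"),
                        protein_id = c("a1", "d1", "h1"),
                        pathway = "Notch", role = "other",
                        pmids = list(integer(), integer(), integer()))
  ds <- signalog_dataset(clusters = cl, annotations = ann)
  cov <- coverage_stats(ds)
  expect_equal(cov$frac_with_ortholog, c(100, 100, 100))
  expect_equal(cov$frac_ortholog_signaling, c(100, 100, 100))
  expect_equal(cov$frac_identical_pathway, c(100, 100, 100))
  expect_equal(glance(cov)$mean_ortholog_signaling, 100)
})

test_that("coverage fractions match a brute-force recount", {
  set.seed(179)
  ds <- rand_dataset(n_per = 10, p_annot = 0.6)
  cov <- coverage_stats(ds)
  links <- signalogr:::directed_links(build_ortholog_maps(ds, 0.3))
  ann <- ds$annotations
  for (r in seq_len(nrow(cov))) {
    sp <- cov$species[r]
    prot <- unique(norm_id(ann$protein_id[ann$species == sp]))
    n_with <- 0; n_sig <- 0; n_ident <- 0
    for (p in prot) {
      lk <- links[links$species == sp & norm_id(links$protein_id) == p, ]
      if (nrow(lk) == 0) next
      n_with <- n_with + 1
      osig <- FALSE; oident <- FALSE
      own <- ann$pathway[ann$species == sp & norm_id(ann$protein_id) == p]
      for (j in seq_len(nrow(lk))) {
        oann <- ann[ann$species == lk$ortholog_species[j] &
                      norm_id(ann$protein_id) ==
                        norm_id(lk$ortholog_id[j]), ]
        if (nrow(oann) > 0) osig <- TRUE
        if (any(oann$pathway %in% own)) oident <- TRUE
      }
      n_sig <- n_sig + osig
      n_ident <- n_ident + oident
    }
    expect_equal(cov$frac_with_ortholog[r],
                 percent1(100 * n_with / length(prot)))
    expect_equal(cov$frac_ortholog_signaling[r],
                 percent1(100 * n_sig / n_with))
    expect_equal(cov$frac_identical_pathway[r],
                 percent1(100 * n_ident / n_with))
  }
})

test_that("species without annotations are excluded from means", {
  ds <- load_fixture("table1_notch")  # CEL itself is unannotated
  expect_warning(cov <- coverage_stats(ds), "no annotated proteins")
  expect_true(is.na(cov$frac_with_ortholog[cov$species == "CEL"]))
  expect_warning(coverage_mean(cov$frac_ortholog_signaling), "undefined")
  g <- suppressWarnings(glance(cov))
  expect_false(is.na(g$mean_ortholog_signaling))
})

test_that("prediction tables round-trip through TSV", {
  ds <- load_fixture("table1_notch")
  p <- predict_signalogs(ds, "CEL")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(p, f, header = "test header")
  p2 <- read_predictions(f)
  expect_equal(tibble::as_tibble(p), tibble::as_tibble(p2))
})
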