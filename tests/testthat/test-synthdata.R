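test_that("the same seed yields byte-identical output", {
  ds1 <- generate_dataset(generator_config(seed = 99,
                                           n_proteins_per_species = 20))
  ds2 <- generate_dataset(generator_config(seed = 99,
                                           n_proteins_per_species = 20))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds1, d1); write_dataset(ds2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  ds3 <- generate_dataset(generator_config(seed = 100,
                                           n_proteins_per_species = 20))
  expect_false(identical(ds1$clusters, ds3$clusters))
})

test_that("zero cluster coverage gives no clusters and no predictions", {
  ds <- generate_dataset(generator_config(seed = 5, cluster_coverage = 0,
                                          n_proteins_per_species = 10))
  expect_equal(nrow(ds$clusters), 0)
  expect_equal(nrow(predict_signalogs(ds, "CEL")), 0)
})

test_that("generated datasets pass full loader validation", {
  for (s in c(1, 2, 3)) {
    ds <- generate_dataset(generator_config(seed = s,
                                            n_proteins_per_species = 30))
    dir <- withr::local_tempdir()
    write_dataset(ds, dir)
    expect_no_error(read_dataset(dir))
    # interactions run within species among annotated proteins
    akey <- paste(ds$annotations$species,
                  norm_id(ds$annotations$protein_id))
    expect_true(all(paste(ds$interactions$species,
                          norm_id(ds$interactions$source_id)) %in% akey))
    expect_true(all(paste(ds$interactions$species,
                          norm_id(ds$interactions$target_id)) %in% akey))
  }
})

test_that("predictions on generated data never duplicate known pairs", {
  for (s in 11:14) {
    ds <- generate_dataset(generator_config(seed = s,
                                            n_proteins_per_species = 25))
    for (tgt in ds$species) {
      p <- predict_signalogs(ds, tgt)
      known <- paste(norm_id(
        ds$annotations$protein_id[ds$annotations$species == tgt]),
        ds$annotations$pathway[ds$annotations$species == tgt])
      expect_false(any(prediction_keys(p) %in% known))
    }
  }
})

test_that("observed multi-pathway fraction is within 3 SE of the rate", {
  rate <- 0.15
  n_ann <- 0; n_multi <- 0
  for (s in 21:22) {
    ds <- generate_dataset(generator_config(
      seed = s, n_proteins_per_species = 1000, multi_pathway_rate = rate))
    per <- ds$annotations |>
      dplyr::count(.data$species, norm_id(.data$protein_id))
    n_ann <- n_ann + nrow(per)
    n_multi <- n_multi + sum(per$n > 1)
  }
  expect_gt(n_ann, 2000)
  se <- sqrt(rate * (1 - rate) / n_ann)
  expect_lt(abs(n_multi / n_ann - rate), 3 * se)
})

test_that("invalid generator configs are rejected", {
  expect_error(generator_config(annotation_rate = 1.2), "rates")
  expect_error(generator_config(n_proteins_per_species = 0), ">= 1")
  expect_error(generator_config(species = "CEL"), "two species")
  expect_error(generator_config(inparalog_extra_rate = -1),
               "non-negative")
})

test_that("runtime grows subquadratically with protein count", {
  t_small <- system.time(
    generate_dataset(generator_config(seed = 1,
                                      n_proteins_per_species = 50)))[3]
  t_big <- system.time(
    generate_dataset(generator_config(seed = 1,
                                      n_proteins_per_species = 200)))[3]
  # 4x the proteins should cost clearly less than 16x the time
  expect_lt(t_big, max(16 * t_small, 30))
})

test_that("unknown fixture names list the available fixtures", {
  expect_error(load_fixture("nope"), "table1_notch")
})

test_that("fixture contents match their published tables", {
  f2 <- load_fixture("table2_drug")
  expect_equal(nrow(f2$table), 19)
  expect_equal(sum(nzchar(f2$table$drugs)), 5)
  expect_equal(f2$n_human_signalogs, 73L)
  expect_equal(relevance_score(f2$attributes), f2$table$score)

  fb <- load_fixture("fig2_breakdown")
  expect_equal(sum(fb$per_species), fb$n_signalog_proteins)
  s <- summarize_predictions(fb$predictions)
  expect_equal(s$n_signalog_proteins, 253)
  expect_equal(s$n_multi_pathway_proteins, 39)
  expect_equal(s$n_annotations_of_multi, 87)

  ds1 <- load_fixture("table1_notch")
  expect_equal(sort(unique(
    ds1$annotations$protein_id[ds1$annotations$species == "DME"])),
    sort(c("bip", "crb", "sca", "neur", "sno", "numb")))
  expect_equal(sort(unique(
    ds1$annotations$protein_id[ds1$annotations$species == "HSA"])),
    sort(c("NOTCH2", "NEURL", "SBNO1", "NUMB")))
})
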