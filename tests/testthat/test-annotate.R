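test_that("the five novelty classes partition all flag combinations", {
  combos <- expand.grid(o = c(FALSE, TRUE), f = c(FALSE, TRUE),
                        p = c(FALSE, TRUE))
  cls <- classify_novelty(combos$o, combos$f, combos$p)
  expect_true(all(cls %in% 1:5))
  expect_equal(length(cls), 8)
  # spot-check the definition of each class
  expect_equal(classify_novelty(TRUE, TRUE, TRUE), 5L)
  expect_equal(classify_novelty(TRUE, TRUE, FALSE), 4L)
  expect_equal(classify_novelty(FALSE, TRUE, FALSE), 3L)
  expect_equal(classify_novelty(TRUE, FALSE, FALSE), 2L)
  expect_equal(classify_novelty(FALSE, FALSE, FALSE), 1L)
  # class-1 wording overlaps 2/3 in prose; most-specific-first keeps the
  # partition exclusive
  expect_equal(sort(unique(cls)), c(1L, 2L, 3L, 4L, 5L))
})

test_that("published novelty classes reproduce from the Notch fixture", {
  ds <- load_fixture("table1_notch")
  at <- ds$attributes
  cls <- classify_novelty(at$orthologs_known, at$function_known, FALSE)
  names(cls) <- at$protein_id
  expect_equal(cls[["num-1"]], 4L)
  expect_equal(cls[["aqp-6"]], 3L)
  expect_equal(cls[["D1009.3"]], 1L)
  expect_equal(cls[["nsh-1"]], 2L)
  expect_equal(cls[["F10D7.5"]], 4L)
})

test_that("relevance score counts the four key properties", {
  all4 <- tibble::tibble(is_membrane = TRUE, is_enzyme = TRUE,
                         has_kinase_domain = TRUE,
                         is_disease_related = TRUE)
  expect_equal(relevance_score(all4), 4L)
  none <- tibble::tibble(is_membrane = FALSE, is_enzyme = FALSE,
                         has_kinase_domain = FALSE,
                         is_disease_related = FALSE)
  expect_equal(relevance_score(none), 0L)
  # each single flag gives one
  for (f in names(all4)) {
    one <- none; one[[f]] <- TRUE
    expect_equal(relevance_score(one), 1L)
  }
  # monotone: adding a flag never decreases the score
  combos <- expand.grid(m = c(FALSE, TRUE), e = c(FALSE, TRUE),
                        k = c(FALSE, TRUE), d = c(FALSE, TRUE))
  at <- tibble::tibble(is_membrane = combos$m, is_enzyme = combos$e,
                       has_kinase_domain = combos$k,
                       is_disease_related = combos$d)
  sc <- relevance_score(at)
  expect_true(all(sc >= 0 & sc <= 4))
  expect_equal(sc, rowSums(combos))
})

test_that("candidate table ranks, flags targets, counts novel ones", {
  f2 <- load_fixture("table2_drug")
  ct <- candidate_table(f2$predictions, f2$attributes, f2$drug_target_ids)
  expect_equal(nrow(ct), 19)
  expect_equal(sum(ct$is_current_target), 5)
  expect_equal(sum(!nzchar(ct$known_drugs)), 14)
  expect_equal(sum(ct$is_novel_candidate), 14)
  expect_false(is.unsorted(rev(ct$score)))
  # printed scores reproduce
  expect_equal(ct$score[ct$protein_id == "ANPRA"], 4L)
  expect_equal(ct$score[ct$protein_id == "CASK"], 4L)
  expect_equal(ct$score[ct$protein_id == "NDST1"], 1L)
  expect_equal(ct$predicted_pathways[ct$protein_id == "MARK2"],
               "EGF/MAPK;WNT")
})

test_that("candidate rows are stable under input re-ordering", {
  f2 <- load_fixture("table2_drug")
  shuffled <- f2$predictions[rev(seq_len(nrow(f2$predictions))), ]
  ct1 <- candidate_table(f2$predictions, f2$attributes, f2$drug_target_ids)
  ct2 <- candidate_table(as_signalog_predictions(shuffled),
                         f2$attributes, f2$drug_target_ids)
  expect_equal(ct1, ct2)
  expect_equal(nrow(candidate_table(
    signalogr:::empty_predictions("HSA"), f2$attributes)), 0)
  # row count equals distinct signalog proteins
  expect_equal(nrow(ct1), length(unique(norm_id(f2$predictions$protein_id))))
})

test_that("orthodisease report reproduces the published worm and fly rows", {
  f3 <- load_fixture("table3_worm_orthodisease")
  r3 <- orthodisease_report(f3$predictions, f3$maps, f3$attributes, "HSA")
  expect_equal(nrow(r3), 10)
  expect_setequal(r3$protein_id, f3$table$signalog)
  expect_match(r3$diseases[r3$protein_id == "ARR-1"], "Oguchi")
  expect_equal(r3$disease_orthologs[r3$protein_id == "PTC-1"], "PTC1;PTC2")

  f4 <- load_fixture("table4_fly_orthodisease")
  r4 <- orthodisease_report(f4$predictions, f4$maps, f4$attributes, "HSA")
  expect_equal(nrow(r4), 9)
  expect_equal(nrow(r3) + nrow(r4), 19)
})

test_that("orthodisease report is empty without disease-flagged orthologs", {
  f3 <- load_fixture("table3_worm_orthodisease")
  at <- f3$attributes
  at$is_disease_related <- FALSE
  r <- orthodisease_report(f3$predictions, f3$maps, at, "HSA")
  expect_equal(nrow(r), 0)
  expect_error(
    orthodisease_report(f3$predictions, f3$maps, f3$attributes, "CEL"),
    "must differ")
})
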