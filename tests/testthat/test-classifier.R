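test_that("cancer cohort: any-slot malignancy qualifies; groups 44/45 do not", {
  in_slot5 <- make_record(id = "a", dx = c("786.2", "250.01", "493.92",
                                           "959.9", "170.9"))
  only_44 <- make_record(id = "b", dx = c("239.9", "238.75"))
  only_45 <- make_record(id = "c", dx = "V58.11")
  no_neoplasm <- make_record(id = "d", dx = c("493.92", "486"))
  recs <- bind_records(in_slot5, only_44, only_45, no_neoplasm)
  cohort <- identify_cancer_cohort(recs, test_map, test_scheme)
  expect_identical(cohort$id, "a")
  expect_identical(attr(cohort, "n_excluded_non_cancer"), 3L)
})

test_that("unmapped diagnosis codes are counted, not fatal", {
  r <- make_record(dx = c("204.00", "777.77"))
  cohort <- identify_cancer_cohort(r, test_map, test_scheme)
  expect_identical(nrow(cohort), 1L)
  expect_identical(attr(cohort, "n_unmapped_dx_codes"), 1L)
})

test_that("chemotherapy window: dated hits, rescue rule, negative days", {
  day1 <- make_record(dx = "204.00", pr = "99.25", prday = 1)
  expect_true(has_chemo_in_window(day1, test_map, test_scheme)$hit)

  day5 <- make_record(dx = "204.00", pr = "99.25", prday = 5)
  expect_false(has_chemo_in_window(day5, test_map, test_scheme)$hit)
  # window end is configurable
  expect_true(has_chemo_in_window(day5, test_map, test_scheme,
                                  window_last_day = 5)$hit)

  rescue <- make_record(dx = "204.00", pr = c("99.25", "87.03"),
                        prday = c(NA, NA), prday_reported = FALSE)
  res <- has_chemo_in_window(rescue, test_map, test_scheme)
  expect_true(res$hit)
  expect_true(res$rescue)
  expect_identical(res$evidence$slot, 1L)

  # rescue requires chemotherapy as the *primary* procedure
  not_primary <- make_record(dx = "204.00", pr = c("87.03", "99.25"),
                             prday = c(NA, NA), prday_reported = FALSE)
  expect_false(has_chemo_in_window(not_primary, test_map, test_scheme)$hit)

  neg <- make_record(dx = "204.00", pr = "99.25", prday = -1)
  res <- has_chemo_in_window(neg, test_map, test_scheme)
  expect_false(res$hit)           # a recorded (negative) day blocks rescue
  expect_true(res$negative_day_flag)
})

test_that("procedure window has no missing-date rescue", {
  biopsy0 <- make_record(dx = "204.00", pr = "41.31", prday = 0)
  expect_true(has_cancer_procedure_in_window(biopsy0, test_map,
                                             test_scheme)$hit)
  no_days <- make_record(dx = "204.00", pr = "41.31", prday = NA_real_,
                         prday_reported = FALSE)
  expect_false(has_cancer_procedure_in_window(no_days, test_map,
                                              test_scheme)$hit)
  imaging <- make_record(dx = "204.00", pr = "87.03", prday = 0)
  expect_false(has_cancer_procedure_in_window(imaging, test_map,
                                              test_scheme)$hit)
})

test_that("diagnosis trigger substitutes the secondary only behind
           cancer/chemo/cytopenia primaries", {
  cyto_inf <- make_record(dx = c("288.00", "486", "204.00"))
  hit <- dx_trigger_lookup(cyto_inf, test_map, test_scheme, "INFECTION")
  expect_true(hit$hit)
  expect_identical(hit$evidence$slot, 2L)

  primary_inf <- make_record(dx = c("486", "204.00"))
  hit <- dx_trigger_lookup(primary_inf, test_map, test_scheme, "INFECTION")
  expect_true(hit$hit)
  expect_identical(hit$evidence$slot, 1L)

  # an OTHER primary blocks the substitution
  other_inf <- make_record(dx = c("493.92", "486", "204.00"))
  expect_false(dx_trigger_lookup(other_inf, test_map, test_scheme,
                                 "INFECTION")$hit)
  # so does a TOX_OTHER primary
  toxo_inf <- make_record(dx = c("787.01", "486", "204.00"))
  expect_false(dx_trigger_lookup(toxo_inf, test_map, test_scheme,
                                 "INFECTION")$hit)

  # TOXICITY matches cytopenias and other toxicities alike
  expect_true(dx_trigger_lookup(make_record(dx = c("288.00", "204.00")),
                                test_map, test_scheme, "TOXICITY")$hit)
  expect_true(dx_trigger_lookup(make_record(dx = c("204.00", "787.01")),
                                test_map, test_scheme, "TOXICITY")$hit)
  # single-diagnosis record: secondary clause simply unavailable
  expect_false(dx_trigger_lookup(make_record(dx = "204.00"),
                                 test_map, test_scheme, "TOXICITY")$hit)
})

test_that("step order: chemotherapy beats procedure, infection beats toxicity", {
  both <- make_record(dx = "204.00", pr = c("41.31", "99.25"),
                      prday = c(0, 0))
  # both window predicates fire, so the step order decides the label
  expect_true(has_cancer_procedure_in_window(both, test_map, test_scheme)$hit)
  expect_true(has_chemo_in_window(both, test_map, test_scheme)$hit)
  expect_identical(classify_admission(both, test_map, test_scheme)$intent,
                   "CHEMO")

  cyto_inf <- make_record(dx = c("288.00", "486", "204.00"))
  expect_true(dx_trigger_lookup(cyto_inf, test_map, test_scheme,
                                "TOXICITY")$hit)
  res <- classify_admission(cyto_inf, test_map, test_scheme)
  expect_identical(res$intent, "INFECTION")
  expect_identical(res$rule_fired, "infection_secondary")
})

test_that("cohort records matching no rule are UNDEFINED", {
  res <- classify_admission(make_record(dx = c("204.00", "493.92")),
                            test_map, test_scheme)
  expect_identical(res$intent, "UNDEFINED")
  res <- classify_admission(make_record(dx = c("204.00", "191.9")),
                            test_map, test_scheme)
  expect_identical(res$intent, "UNDEFINED")
})

test_that("classify_cohort partitions the cohort and records evidence", {
  empty <- make_record()[0, ]
  counts <- intent_counts(classify_cohort(empty, test_map, test_scheme))
  expect_identical(sum(counts), 0L)

  recs <- bind_records(
    make_record(id = "chemo", dx = "204.00", pr = "99.25", prday = 0),
    make_record(id = "inf", dx = c("288.00", "486", "204.00")),
    make_record(id = "undef", dx = c("204.00", "493.92")))
  cl <- classify_cohort(recs, test_map, test_scheme)
  expect_identical(intent_counts(cl),
                   c(CHEMO = 1L, PROCEDURE = 0L, INFECTION = 1L,
                     TOXICITY = 0L, UNDEFINED = 1L))
  expect_identical(cl$evidence_code[cl$id == "chemo"], "99.25")
  expect_identical(cl$evidence_day[cl$id == "chemo"], 0)
  expect_identical(cl$evidence_slot[cl$id == "inf"], 2L)

  # evidence tie-break: earliest day, then lowest slot
  tie <- make_record(dx = "204.00", pr = c("99.28", "99.25", "99.25"),
                     prday = c(1, 0, 0))
  res <- classify_admission(tie, test_map, test_scheme)
  expect_identical(res$evidence$slot, 2L)
  expect_identical(res$evidence$day, 0)
})

test_that("every cohort admission gets exactly one intent on synthetic data", {
  sim <- generate_cohort(generator_config(n_records = 600, seed = 301))
  cohort <- identify_cancer_cohort(sim$records, test_map, test_scheme)
  cl <- classify_cohort(cohort, test_map, test_scheme)
  expect_identical(nrow(cl), nrow(cohort))
  expect_false(anyNA(cl$intent))
  expect_identical(sum(intent_counts(cl)), nrow(cohort))
})

test_that("adding a non-triggering diagnosis never changes the intent", {
  sim <- generate_cohort(generator_config(n_records = 300, seed = 77))
  cohort <- identify_cancer_cohort(sim$records, test_map, test_scheme)
  before <- classify_cohort(cohort, test_map, test_scheme)
  perturbed <- cohort
  for (i in seq_len(nrow(perturbed))) {
    free <- which(is.na(unlist(perturbed[i, paste0("dx", 3:25)])))
    slot <- paste0("dx", 2 + free[1])
    perturbed[i, slot] <- "786.2"   # cough: OTHER category, never a trigger
  }
  after <- classify_cohort(perturbed, test_map, test_scheme)
  expect_identical(as.character(before$intent), as.character(after$intent))
})

test_that("classifier agrees with the brute-force oracle on random records", {
  sim <- generate_cohort(generator_config(n_records = 2000, seed = 13))
  cohort <- identify_cancer_cohort(sim$records, test_map, test_scheme)
  cl <- classify_cohort(cohort, test_map, test_scheme)
  oracle <- oracle_classify(cohort, test_map, test_scheme)
  expect_identical(as.character(cl$intent), oracle)
})
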