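test_that("generation is reproducible under a fixed seed", {
  a <- generate_cohort(generator_config(n_records = 400, seed = 7))
  b <- generate_cohort(generator_config(n_records = 400, seed = 7))
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  c2 <- generate_cohort(generator_config(n_records = 400, seed = 8))
  expect_false(identical(a$records, c2$records))
})

test_that("config validation rejects malformed mixtures and probabilities", {
  expect_error(generator_config(intent_mixture = c(CHEMO = 1)), "mixture")
  expect_error(generator_config(
    intent_mixture = c(CHEMO = 0.5, PROCEDURE = 0.5, INFECTION = 0.5,
                       TOXICITY = -0.3, UNDEFINED = 0.5, NON_CANCER = -0.7)),
    "sum to 1|\\[0, 1\\]")
  expect_error(generator_config(p_missing_prday = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(los_sdlog = c(
    CHEMO = 0, PROCEDURE = 1, INFECTION = 1, TOXICITY = 1, UNDEFINED = 1,
    NON_CANCER = 1)), "positive")
})

test_that("a pure noise-free chemotherapy mixture classifies 100% CHEMO", {
  cfg <- generator_config(
    n_records = 150, seed = 42,
    intent_mixture = c(CHEMO = 1, PROCEDURE = 0, INFECTION = 0,
                       TOXICITY = 0, UNDEFINED = 0, NON_CANCER = 0),
    p_missing_prday = 0, p_negative_day = 0)
  sim <- generate_cohort(cfg)
  cohort <- identify_cancer_cohort(sim$records, test_map, test_scheme)
  expect_identical(nrow(cohort), 150L)
  cl <- classify_cohort(cohort, test_map, test_scheme)
  expect_true(all(cl$intent == "CHEMO"))
})

test_that("intent mixture is respected within multinomial sampling error", {
  n <- 10000
  cfg <- generator_config(
    n_records = n, seed = 99,
    intent_mixture = c(CHEMO = 0.2, PROCEDURE = 0.2, INFECTION = 0.2,
                       TOXICITY = 0.2, UNDEFINED = 0.2, NON_CANCER = 0))
  sim <- generate_cohort(cfg)
  counts <- table(factor(sim$truth$intent,
                         levels = c("CHEMO", "PROCEDURE", "INFECTION",
                                    "TOXICITY", "UNDEFINED", "NON_CANCER")))
  sd3 <- 3 * sqrt(n * 0.2 * 0.8)
  expect_true(all(abs(counts[1:5] - n / 5) < sd3))
  expect_identical(unname(counts[6]), 0L)
})

test_that("noise-free label recovery is exact across all intents", {
  cfg <- generator_config(n_records = 1500, seed = 11,
                          p_missing_prday = 0, p_negative_day = 0)
  sim <- generate_cohort(cfg)
  cohort <- identify_cancer_cohort(sim$records, test_map, test_scheme)
  truth <- sim$truth[match(cohort$id, sim$truth$id), ]
  expect_false(any(truth$intent == "NON_CANCER"))
  cl <- classify_cohort(cohort, test_map, test_scheme)
  expect_identical(as.character(cl$intent), truth$intent)
})

test_that("missingness injection blanks days and flags the record", {
  cfg0 <- generator_config(n_records = 200, seed = 3, p_missing_prday = 0,
                           p_negative_day = 0)
  sim0 <- generate_cohort(cfg0)
  expect_true(all(sim0$records$prday_reported))

  cfg1 <- generator_config(n_records = 200, seed = 3, p_missing_prday = 1,
                           p_negative_day = 0)
  sim1 <- generate_cohort(cfg1)
  expect_false(any(sim1$records$prday_reported))
  day_cols <- grep("^prday[0-9]+$", names(sim1$records), value = TRUE)
  expect_true(all(is.na(unlist(sim1$records[day_cols]))))
})

test_that("chemo records survive total day missingness via the rescue rule,
           procedure records never do", {
  pure <- function(intent) {
    mix <- c(CHEMO = 0, PROCEDURE = 0, INFECTION = 0, TOXICITY = 0,
             UNDEFINED = 0, NON_CANCER = 0)
    mix[intent] <- 1
    mix
  }
  chemo_cfg <- generator_config(n_records = 150, seed = 5,
                                intent_mixture = pure("CHEMO"),
                                p_missing_prday = 1, p_negative_day = 0)
  sim <- generate_cohort(chemo_cfg)
  cl <- classify_cohort(sim$records, test_map, test_scheme)
  expect_true(all(cl$intent == "CHEMO"))
  expect_true(all(cl$rule_fired == "chemo_primary_proc_no_days"))

  proc_cfg <- generator_config(n_records = 150, seed = 5,
                               intent_mixture = pure("PROCEDURE"),
                               p_missing_prday = 1, p_negative_day = 0)
  simp <- generate_cohort(proc_cfg)
  clp <- classify_cohort(simp$records, test_map, test_scheme)
  expect_false(any(clp$intent == "PROCEDURE"))
})

test_that("raising day missingness degrades procedure recall only", {
  recall <- function(p_miss) {
    cfg <- generator_config(n_records = 3000, seed = 17,
                            p_missing_prday = p_miss, p_negative_day = 0)
    sim <- generate_cohort(cfg)
    cohort <- identify_cancer_cohort(sim$records, test_map, test_scheme)
    truth <- sim$truth$intent[match(cohort$id, sim$truth$id)]
    assigned <- as.character(classify_cohort(cohort, test_map,
                                             test_scheme)$intent)
    vapply(c("PROCEDURE", "INFECTION", "TOXICITY"),
           function(k) mean(assigned[truth == k] == k), 0)
  }
  clean <- recall(0)
  noisy <- recall(0.5)
  expect_lt(noisy["PROCEDURE"], 0.7)
  expect_equal(clean["PROCEDURE"], c(PROCEDURE = 1))
  expect_equal(noisy["INFECTION"], c(INFECTION = 1))
  expect_equal(noisy["TOXICITY"], c(TOXICITY = 1))
})

test_that("negative chemotherapy days are flagged and never qualify", {
  cfg <- generator_config(
    n_records = 120, seed = 23,
    intent_mixture = c(CHEMO = 1, PROCEDURE = 0, INFECTION = 0,
                       TOXICITY = 0, UNDEFINED = 0, NON_CANCER = 0),
    p_missing_prday = 0, p_negative_day = 1)
  sim <- generate_cohort(cfg)
  cl <- classify_cohort(sim$records, test_map, test_scheme)
  expect_true(all(cl$negative_day_flag))
  expect_false(any(cl$rule_fired == "chemo_window"))
})

test_that("generated charges recover the configured log-normal means", {
  cfg <- generator_config(n_records = 10000, seed = 31)
  sim <- generate_cohort(cfg)
  truth <- sim$truth$intent
  for (intent in c("CHEMO", "PROCEDURE", "INFECTION", "TOXICITY")) {
    expected <- exp(cfg$charge_meanlog[[intent]] +
                      cfg$charge_sdlog[[intent]]^2 / 2)
    observed <- mean(sim$records$totchg[truth == intent])
    # 4 standard errors of the group mean, from the configured CV
    cv <- sqrt(exp(cfg$charge_sdlog[[intent]]^2) - 1)
    expect_lt(abs(observed - expected) / expected,
              4 * cv / sqrt(sum(truth == intent)))
  }
})
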