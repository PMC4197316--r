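# Synthetic KID-like discharge records with known ground-truth intents.
#
# The generator emulates the features of administrative discharge data the
# classifier must cope with: ordered diagnosis and procedure code slots,
# per-procedure day-from-admission integers, whole states that do not report
# procedure days, the occasional corrupt (negative) chemotherapy day,
# admissions that genuinely fit no indication, and non-cancer admissions
# mixed into the input. Codes are drawn from a compact dictionary of real
# ICD-9-CM codes so fixtures look like genuine claims. Each record is
# constructed so that, with all noise probabilities at zero, the stepwise
# classifier recovers the ground-truth label exactly.

TRUTH_LEVELS <- c(INTENTS, "NON_CANCER")

code_pools <- function() {
  list(
    malignancy_dx = c("191.9", "170.9", "189.0", "194.0", "201.90",
                      "202.80", "204.00", "204.01", "205.00", "198.3"),
    chemo_dx = c("V58.11", "V58.1"),
    infection_dx = c("038.9", "790.7", "112.0", "079.99", "047.9", "486",
                     "487.1", "465.9", "008.45", "599.0", "682.9", "780.6",
                     "780.60", "999.31", "996.62", "996.67", "996.69"),
    cytopenia_dx = c("285.9", "285.1", "287.5", "288.0", "288.00", "288.03",
                     "284.8", "284.1"),
    tox_other_dx = c("276.51", "276.5", "276.1", "780.39", "331.4", "577.0",
                     "578.9", "584.9", "998.11", "787.01", "789.00",
                     "780.79", "995.27", "996.4", "996.85"),
    other_dx = c("V57.89", "493.92", "648.91", "664.01", "V30.00", "959.9",
                 "250.01", "786.2"),
    uncertain_neoplasm_dx = c("239.9", "238.75"),
    icu_dx = c("427.5", "518.81", "799.1", "785.50", "785.52"),
    chemo_proc = c("99.25", "99.28"),
    hct_proc = c("41.00", "41.01", "41.05", "41.09"),
    cancer_proc = c("41.31", "40.11", "40.3", "03.31", "03.09", "01.59",
                    "02.2", "86.07", "38.93", "54.4", "55.51"),
    other_proc = c("87.03", "88.91", "99.04", "99.05", "47.09", "38.92",
                   "96.04", "93.90"))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the intent distribution reported for the pooled
#' 2003/2006/2009 pediatric cancer cohort (roughly 38/15/15/21/10 percent
#' across chemotherapy, procedure, infection, toxicity and undefined), with
#' a small non-cancer admixture; 14.1 percent of records come from states
#' that omit procedure days; about 0.3 percent of dated chemotherapy days
#' are recorded negative; and dated chemotherapy falls on days 0/1/2 in
#' roughly 78/16/6 percent of chemotherapy admissions. Length of stay and
#' total charge are log-normal per intent.
#'
#' @param n_records Number of admissions to generate.
#' @param seed Optional integer; when given, generation is reproducible.
#' @param intent_mixture Named probabilities over
#'   CHEMO/PROCEDURE/INFECTION/TOXICITY/UNDEFINED/NON_CANCER, summing to 1.
#' @param p_missing_prday Probability a record's state omits all procedure
#'   days.
#' @param p_negative_day Probability the dated chemotherapy day of a record
#'   is corrupted to a negative value.
#' @param chemo_day_probs Probabilities of chemotherapy on day 0, 1, 2.
#' @param los_meanlog,los_sdlog,charge_meanlog,charge_sdlog Named per-intent
#'   log-normal parameters (length-6 vectors over `TRUTH_LEVELS` order).
#' @param p_hct,p_icu,p_died Named per-intent event probabilities.
#' @param year_probs Probabilities over dataset years 2003/2006/2009.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(
    n_records = 1000L,
    seed = NULL,
    intent_mixture = c(CHEMO = 0.36, PROCEDURE = 0.15, INFECTION = 0.14,
                       TOXICITY = 0.20, UNDEFINED = 0.10, NON_CANCER = 0.05),
    p_missing_prday = 0.141,
    p_negative_day = 0.003,
    chemo_day_probs = c(0.78, 0.16, 0.06),
    los_meanlog = c(CHEMO = log(3.5), PROCEDURE = log(7), INFECTION = log(5),
                    TOXICITY = log(4.5), UNDEFINED = log(4),
                    NON_CANCER = log(3)),
    los_sdlog = c(CHEMO = 0.6, PROCEDURE = 0.7, INFECTION = 0.7,
                  TOXICITY = 0.7, UNDEFINED = 0.8, NON_CANCER = 0.8),
    charge_meanlog = c(CHEMO = log(25000), PROCEDURE = log(70000),
                       INFECTION = log(35000), TOXICITY = log(30000),
                       UNDEFINED = log(25000), NON_CANCER = log(15000)),
    charge_sdlog = c(CHEMO = 0.5, PROCEDURE = 0.6, INFECTION = 0.7,
                     TOXICITY = 0.7, UNDEFINED = 0.8, NON_CANCER = 0.8),
    p_hct = c(CHEMO = 0.06, PROCEDURE = 0.02, INFECTION = 0.02,
              TOXICITY = 0.05, UNDEFINED = 0.01, NON_CANCER = 0),
    p_icu = c(CHEMO = 0.01, PROCEDURE = 0.05, INFECTION = 0.09,
              TOXICITY = 0.07, UNDEFINED = 0.04, NON_CANCER = 0.02),
    p_died = c(CHEMO = 0.002, PROCEDURE = 0.01, INFECTION = 0.015,
               TOXICITY = 0.012, UNDEFINED = 0.01, NON_CANCER = 0.005),
    year_probs = c(`2003` = 0.309, `2006` = 0.327, `2009` = 0.364)) {
  cfg <- list(n_records = as.integer(n_records), seed = seed,
              intent_mixture = intent_mixture[TRUTH_LEVELS],
              p_missing_prday = p_missing_prday,
              p_negative_day = p_negative_day,
              chemo_day_probs = chemo_day_probs,
              los_meanlog = los_meanlog[TRUTH_LEVELS],
              los_sdlog = los_sdlog[TRUTH_LEVELS],
              charge_meanlog = charge_meanlog[TRUTH_LEVELS],
              charge_sdlog = charge_sdlog[TRUTH_LEVELS],
              p_hct = p_hct[TRUTH_LEVELS], p_icu = p_icu[TRUTH_LEVELS],
              p_died = p_died[TRUTH_LEVELS],
              year_probs = year_probs,
              pools = code_pools())
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_records < 0) stop("n_records must be non-negative")
  mix <- cfg$intent_mixture
  if (anyNA(mix) || length(mix) != 6) {
    stop("intent_mixture must name all of ",
         paste(TRUTH_LEVELS, collapse = ", "))
  }
  if (abs(sum(mix) - 1) > 1e-9) stop("intent_mixture must sum to 1")
  probs <- c(mix, cfg$p_missing_prday, cfg$p_negative_day,
             cfg$chemo_day_probs, cfg$p_hct, cfg$p_icu, cfg$p_died,
             cfg$year_probs)
  if (any(is.na(probs)) || any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$chemo_day_probs) - 1) > 1e-9) {
    stop("chemo_day_probs must sum to 1")
  }
  if (any(c(cfg$los_sdlog, cfg$charge_sdlog) <= 0)) {
    stop("log-normal scale parameters must be positive")
  }
  invisible(cfg)
}

#' Bundled CPI inflation factors
#'
#' All-Urban CPI multipliers to 2009 dollars for the three dataset years
#' (annual averages 184.0, 201.6, 214.5 give factors 1.166, 1.064, 1).
#'
#' @return Data frame with columns `year`, `factor_to_2009`.
#' @export
default_cpi_table <- function() {
  data.frame(year = c(2003L, 2006L, 2009L),
             factor_to_2009 = c(1.166, 1.064, 1.000))
}

N_DX_SLOTS <- 25L
N_PROC_SLOTS <- 15L

pick <- function(pool, n = 1L) sample(pool, n, replace = TRUE)

#' Generate a synthetic admission cohort with ground-truth labels
#'
#' Assembles `n_records` wide-format admission records whose diagnosis and
#' procedure codes are constructed so that the classifier's rule trace
#' reproduces the ground-truth intent whenever no noise flag interferes:
#' chemotherapy admissions carry a chemotherapy procedure (always the
#' primary procedure, as planned treatment) on day 0-2; procedure
#' admissions a cancer-directed procedure on day 0-2 and no early
#' chemotherapy; infection and toxicity admissions the qualifying
#' primary/secondary diagnosis pattern and no window procedures; undefined
#' admissions a cancer diagnosis but no trigger; non-cancer admissions no
#' malignancy code at all. Noise (missing procedure days, negative
#' chemotherapy days) is then injected via [inject_missingness()].
#'
#' @param cfg A `generator_config`.
#' @return List: `records` (wide admission table including a per-record
#'   `ccr` column), `truth` (data frame `id`, `intent`), `cpi` (CPI table),
#'   `config`.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_records
  pools <- cfg$pools

  truth <- if (n) sample(TRUTH_LEVELS, n, replace = TRUE,
                         prob = cfg$intent_mixture) else character()
  dx <- matrix(NA_character_, n, N_DX_SLOTS)
  pr <- matrix(NA_character_, n, N_PROC_SLOTS)
  prday <- matrix(NA_real_, n, N_PROC_SLOTS)

  place_dx <- function(row, codes) {
    row[seq_along(codes)] <- codes
    row
  }
  # first free slot at or after `from`, so injected codes never displace the
  # primary/secondary diagnoses that drive classification
  append_code <- function(row, code, from = 3L) {
    free <- which(is.na(row))
    free <- free[free >= from]
    if (length(free)) row[free[1L]] <- code
    row
  }

  for (i in seq_len(n)) {
    lab <- truth[i]
    dxr <- rep(NA_character_, N_DX_SLOTS)
    prr <- rep(NA_character_, N_PROC_SLOTS)
    dayr <- rep(NA_real_, N_PROC_SLOTS)
    np <- 0L
    add_proc <- function(code, day) {
      np <<- np + 1L
      prr[np] <<- code
      dayr[np] <<- day
    }

    if (lab == "CHEMO") {
      u <- stats::runif(1)
      dxr[1] <- if (u < 0.85) pick(pools$chemo_dx)
                else if (u < 0.95) pick(pools$malignancy_dx)
                else pick(pools$cytopenia_dx)
      dxr <- append_code(dxr, pick(pools$malignancy_dx), from = 2L)
      add_proc(pick(pools$chemo_proc),
               sample(0:2, 1, prob = cfg$chemo_day_probs))
      if (stats::runif(1) < 0.15) {           # minor procedure before chemo
        add_proc(pick(pools$cancer_proc), sample(0:2, 1))
      }
      if (stats::runif(1) < 0.3) {
        add_proc(pick(pools$other_proc), sample(0:2, 1))
      }
    } else if (lab == "PROCEDURE") {
      u <- stats::runif(1)
      dxr[1] <- if (u < 0.5) pick(pools$malignancy_dx)
                else if (u < 0.6) pick(pools$infection_dx)
                else if (u < 0.75) pick(pools$tox_other_dx)
                else if (u < 0.85) pick(pools$cytopenia_dx)
                else pick(pools$other_dx)
      dxr <- append_code(dxr, pick(pools$malignancy_dx), from = 2L)
      add_proc(pick(pools$cancer_proc), sample(0:2, 1))
      if (stats::runif(1) < 0.2) {            # chemotherapy later in the stay
        add_proc(pick(pools$chemo_proc), sample(3:10, 1))
      }
      if (stats::runif(1) < 0.4) {
        add_proc(pick(pools$other_proc), sample(0:5, 1))
      }
    } else if (lab == "INFECTION") {
      if (stats::runif(1) < 0.78) {
        dxr[1] <- pick(pools$infection_dx)
        dxr[2] <- pick(pools$malignancy_dx)
      } else {
        u <- stats::runif(1)
        dxr[1] <- if (u < 0.5) pick(pools$cytopenia_dx)
                  else if (u < 0.9) pick(pools$malignancy_dx)
                  else pick(pools$chemo_dx)
        dxr[2] <- pick(pools$infection_dx)
        dxr <- append_code(dxr, pick(pools$malignancy_dx))
      }
      if (stats::runif(1) < 0.3) {
        add_proc(pick(pools$other_proc), sample(0:3, 1))
      }
      if (stats::runif(1) < 0.15) {           # chemo resumed once stable
        # never in the primary slot: unplanned admissions do not have
        # chemotherapy as their principal procedure
        if (np == 0L) add_proc(pick(pools$other_proc), sample(0:3, 1))
        add_proc(pick(pools$chemo_proc), sample(3:10, 1))
      }
    } else if (lab == "TOXICITY") {
      if (stats::runif(1) < 0.8) {
        cyto <- stats::runif(1) < 0.6
        dxr[1] <- if (cyto) pick(pools$cytopenia_dx)
                  else pick(pools$tox_other_dx)
        # a cytopenia primary must not carry an infection secondary, or the
        # admission is (correctly) an infection admission
        dxr[2] <- if (cyto) {
          u <- stats::runif(1)
          if (u < 0.79) pick(pools$malignancy_dx)
          else if (u < 0.95) pick(pools$cytopenia_dx)
          else pick(pools$tox_other_dx)
        } else pick(pools$malignancy_dx)
      } else {
        dxr[1] <- if (stats::runif(1) < 0.8) pick(pools$malignancy_dx)
                  else pick(pools$chemo_dx)
        dxr[2] <- if (stats::runif(1) < 0.7) pick(pools$tox_other_dx)
                  else pick(pools$cytopenia_dx)
      }
      dxr <- append_code(dxr, pick(pools$malignancy_dx))
      if (stats::runif(1) < 0.25) {
        add_proc(pick(pools$other_proc), sample(0:3, 1))
      }
      if (stats::runif(1) < 0.1) {
        if (np == 0L) add_proc(pick(pools$other_proc), sample(0:3, 1))
        add_proc(pick(pools$chemo_proc), sample(3:10, 1))
      }
    } else if (lab == "UNDEFINED") {
      u <- stats::runif(1)
      if (u < 0.5) {
        dxr[1] <- pick(pools$malignancy_dx)
        dxr[2] <- if (stats::runif(1) < 0.39) pick(pools$malignancy_dx)
                  else pick(pools$other_dx)
      } else if (u < 0.7) {
        dxr[1] <- pick(pools$chemo_dx)
        dxr[2] <- pick(pools$other_dx)
        dxr <- append_code(dxr, pick(pools$malignancy_dx))
      } else {
        dxr[1] <- pick(pools$other_dx)
        dxr[2] <- pick(pools$malignancy_dx)
      }
      if (stats::runif(1) < 0.3) {
        add_proc(pick(pools$other_proc), sample(0:5, 1))
      }
    } else {                                  # NON_CANCER
      dxr[1] <- if (stats::runif(1) < 0.8) pick(pools$other_dx)
                else pick(pools$uncertain_neoplasm_dx)
      if (stats::runif(1) < 0.4) {
        dxr[2] <- pick(c(pools$other_dx, pools$infection_dx,
                         pools$cytopenia_dx))
      }
      if (stats::runif(1) < 0.3) {
        add_proc(pick(pools$other_proc), sample(0:3, 1))
      }
    }

    # non-triggering comorbidity filler in later slots
    n_extra <- stats::rpois(1, 1)
    for (k in seq_len(min(n_extra, 3))) {
      dxr <- append_code(dxr, pick(c(pools$other_dx,
                                     if (lab != "NON_CANCER") pools$malignancy_dx)))
    }
    # ICU-level illness proxied by arrest/shock codes in later slots
    if (stats::runif(1) < cfg$p_icu[[lab]]) {
      dxr <- append_code(dxr, pick(pools$icu_dx))
    }
    # HCT: early when it is the planned admission reason, later otherwise
    if (stats::runif(1) < cfg$p_hct[[lab]]) {
      hct_day <- switch(lab,
                        CHEMO = sample(5:11, 1),       # mean near day 8
                        PROCEDURE = sample(0:2, 1),
                        3L + stats::rpois(1, 7))       # mean near day 10
      np <- np + 1L
      prr[np] <- pick(pools$hct_proc)
      dayr[np] <- hct_day
    }

    dx[i, ] <- dxr
    pr[i, ] <- prr
    prday[i, ] <- dayr
  }

  los <- pmax(0L, as.integer(round(stats::rlnorm(
    n, cfg$los_meanlog[truth], cfg$los_sdlog[truth]))))
  charge <- round(stats::rlnorm(
    n, cfg$charge_meanlog[truth], cfg$charge_sdlog[truth]), 2)
  died <- stats::runif(n) < cfg$p_died[truth]
  year <- if (n) as.integer(sample(names(cfg$year_probs), n, replace = TRUE,
                                   prob = cfg$year_probs)) else integer()

  records <- data.frame(
    id = if (n) sprintf("A%06d", seq_len(n)) else character(),
    year = year, stringsAsFactors = FALSE)
  colnames(dx) <- paste0("dx", seq_len(N_DX_SLOTS))
  colnames(pr) <- paste0("pr", seq_len(N_PROC_SLOTS))
  colnames(prday) <- paste0("prday", seq_len(N_PROC_SLOTS))
  records <- cbind(records, as.data.frame(dx, stringsAsFactors = FALSE),
                   as.data.frame(pr, stringsAsFactors = FALSE),
                   as.data.frame(prday))
  records$los <- los
  records$totchg <- charge
  records$died <- died
  records$age_group <- if (n) sample(c("<1", "1-4", "5-9", "10-14", "15+"), n,
                                     replace = TRUE,
                                     prob = c(0.033, 0.239, 0.214, 0.211, 0.303))
                       else character()
  records$sex <- if (n) sample(c("M", "F"), n, replace = TRUE,
                               prob = c(0.553, 0.447)) else character()
  records$payer <- if (n) sample(c("public", "private", "other"), n,
                                 replace = TRUE,
                                 prob = c(0.364, 0.557, 0.079)) else character()
  records$race <- if (n) sample(c("white", "black", "hispanic", "other"), n,
                                replace = TRUE,
                                prob = c(0.55, 0.10, 0.22, 0.13)) else character()
  records$prday_reported <- rep(TRUE, n)
  records$ccr <- round(stats::runif(n, 0.3, 0.7), 4)

  records <- inject_missingness(records, cfg)
  list(records = records,
       truth = data.frame(id = records$id, intent = truth,
                          stringsAsFactors = FALSE),
       cpi = default_cpi_table(),
       config = cfg)
}

#' Inject procedure-day missingness and negative chemotherapy days
#'
#' With probability `p_missing_prday` a record's procedure days are all
#' blanked and `prday_reported` set to `FALSE`, emulating states that do not
#' submit procedure days. Independently, with probability `p_negative_day`,
#' the first dated chemotherapy procedure of a record has its day corrupted
#' to -1, emulating the rare negative dates seen in the source data.
#'
#' @param records Wide admission table.
#' @param cfg A `generator_config` (supplies the probabilities and the
#'   chemotherapy procedure codes).
#' @return The records with noise applied.
#' @export
inject_missingness <- function(records, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- nrow(records)
  if (!n) return(records)
  day_cols <- slot_cols(records, "prday")
  pr_cols <- slot_cols(records, "pr")
  blank <- stats::runif(n) < cfg$p_missing_prday
  if (any(blank)) {
    records[blank, day_cols] <- NA_real_
    records$prday_reported[blank] <- FALSE
  }
  negate <- stats::runif(n) < cfg$p_negative_day
  chemo_codes <- normalize_icd9(cfg$pools$chemo_proc)
  for (i in which(negate & !blank)) {
    codes <- normalize_icd9(as.character(unlist(records[i, pr_cols])))
    days <- as.numeric(unlist(records[i, day_cols]))
    j <- which(!is.na(codes) & codes %in% chemo_codes & !is.na(days))
    if (length(j)) records[i, day_cols[j[1L]]] <- -1
  }
  records
}
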