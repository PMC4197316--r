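# Stepwise assignment of one admission indication per discharge record.
#
# The algorithm rests on two clinical assumptions. First, a discharge
# diagnosis of cancer or of a cytopenia is not by itself a reason to be in
# hospital: cancer is a chronic condition and uncomplicated cytopenias are
# managed as outpatients. Second, when the primary diagnosis is one of
# those insufficient codes, the secondary diagnosis is an adequate
# substitute. Admission intent is therefore resolved in a fixed order:
#
#   1. CHEMO      chemotherapy procedure within the first days of stay
#                 (or, when the record carries no usable procedure days,
#                 chemotherapy as the primary procedure);
#   2. PROCEDURE  cancer-directed procedure within the same window;
#   3. INFECTION  infection as primary dx, or as secondary dx behind a
#                 malignancy / chemotherapy-encounter / cytopenia primary;
#   4. TOXICITY   same lookup for non-infectious toxicity (cytopenias count);
#   5. UNDEFINED  everything else.
#
# Chemotherapy outranks procedures so that minor procedures done before, but
# not delaying, chemotherapy stay chemotherapy admissions; infection
# outranks toxicity so that "cytopenia + infection" resolves to infection.

# ---- record plumbing --------------------------------------------------------

slot_cols <- function(records, prefix) {
  cols <- grep(paste0("^", prefix, "[0-9]+$"), names(records), value = TRUE)
  cols[order(as.integer(sub(prefix, "", cols)))]
}

# One admission as plain vectors; `i` indexes a row of the wide table.
as_admission <- function(records, i = 1L) {
  if (is.list(records) && !is.data.frame(records) &&
      all(c("dx_codes", "proc_codes") %in% names(records))) {
    return(records)
  }
  stopifnot(is.data.frame(records))
  r <- records[i, , drop = FALSE]
  get_slots <- function(prefix, as_num = FALSE) {
    cols <- slot_cols(records, prefix)
    v <- unlist(r[cols], use.names = FALSE)
    if (as_num) v <- suppressWarnings(as.numeric(v)) else v <- as.character(v)
    v[!is.na(v) & v == ""] <- NA
    v
  }
  dx <- get_slots("dx")
  pr <- get_slots("pr")
  prday <- get_slots("prday", as_num = TRUE)
  keep_pr <- !is.na(pr)
  list(id = r$id,
       dx_codes = dx[!is.na(dx)],
       proc_codes = pr[keep_pr],
       proc_days = if (length(prday)) prday[keep_pr] else rep(NA_real_, sum(keep_pr)),
       prday_reported = if ("prday_reported" %in% names(r))
         isTRUE(as.logical(r$prday_reported)) else TRUE)
}

# Category vectors for a record's codes; unmapped codes become NA and are
# counted by the caller rather than raised, so one dirty code cannot abort a
# whole cohort run.
admission_dx_categories <- function(adm, map, scheme) {
  grp <- ccs_group(adm$dx_codes, map, "dx", strict = FALSE)
  cat <- rep(NA_character_, length(grp))
  ok <- !is.na(grp)
  if (any(ok)) cat[ok] <- dx_category(grp[ok], adm$dx_codes[ok], scheme)
  list(group = grp, category = cat)
}

admission_proc_categories <- function(adm, map, scheme) {
  grp <- ccs_group(adm$proc_codes, map, "proc", strict = FALSE)
  cat <- rep(NA_character_, length(grp))
  ok <- !is.na(grp)
  if (any(ok)) cat[ok] <- proc_category(grp[ok], scheme)
  list(group = grp, category = cat)
}

no_evidence <- function() {
  list(code = NA_character_, slot = NA_integer_, day = NA_real_)
}

# Earliest qualifying day, then lowest slot, as the reported evidence.
pick_window_evidence <- function(hits, codes, days) {
  idx <- which(hits)
  idx <- idx[order(days[idx], idx)][1L]
  list(code = codes[idx], slot = idx, day = days[idx])
}

# ---- cohort definition ------------------------------------------------------

#' Identify the cancer cohort
#'
#' An admission belongs to the cancer cohort when any diagnosis slot maps to
#' a malignancy CCS group (11-43 under the default scheme). Neoplasms of
#' unspecified or uncertain behaviour (group 44 by default) never qualify --
#' that group is dominated by rare and benign lesions -- and a maintenance
#' chemotherapy encounter code (group 45) alone never qualifies either, to
#' keep out chemotherapy given for non-malignant disease. Unmapped codes are
#' counted and treated as non-qualifying.
#'
#' @param records Wide admission table (see [read_admissions()] for the
#'   schema).
#' @param map A `ccs_map`.
#' @param scheme A `category_scheme`.
#' @return The qualifying subset of `records`, with attributes
#'   `n_excluded_non_cancer` and `n_unmapped_dx_codes`.
#' @export
identify_cancer_cohort <- function(records, map, scheme) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  in_cohort <- logical(n)
  n_unmapped <- 0L
  for (i in seq_len(n)) {
    adm <- as_admission(records, i)
    grp <- ccs_group(adm$dx_codes, map, "dx", strict = FALSE)
    n_unmapped <- n_unmapped + sum(is.na(grp) & !is.na(adm$dx_codes))
    qual <- grp %in% scheme$malignancy_groups &
      !(grp %in% scheme$excluded_cancer_groups)
    in_cohort[i] <- any(qual, na.rm = TRUE)
  }
  out <- records[in_cohort, , drop = FALSE]
  attr(out, "n_excluded_non_cancer") <- n - sum(in_cohort)
  attr(out, "n_unmapped_dx_codes") <- n_unmapped
  out
}

# ---- the four trigger predicates -------------------------------------------

#' Chemotherapy within the admission window
#'
#' TRUE when a chemotherapy procedure (CCS procedure group 224 under the
#' default scheme) was performed on hospital day 0 through
#' `window_last_day`. Records whose state does not report procedure days --
#' or whose days are all missing -- fall back on a rescue rule: chemotherapy
#' as the *primary* procedure qualifies without a date. A chemotherapy
#' procedure with a negative recorded day never qualifies (the date is
#' corrupt) but is flagged via `negative_day_flag` so downstream review can
#' treat such assignments as suspect.
#'
#' @param r One admission: a one-row wide table, or a row index via
#'   `as_admission`-style list.
#' @param map,scheme CCS map and category scheme.
#' @param window_last_day Last qualifying day (day 0 = admission day).
#' @return List with `hit`, `evidence` (code/slot/day), `rescue` and
#'   `negative_day_flag`.
#' @export
has_chemo_in_window <- function(r, map, scheme, window_last_day = 2) {
  adm <- as_admission(r)
  pc <- admission_proc_categories(adm, map, scheme)
  chemo_window_check(pc$category, adm$proc_codes, adm$proc_days,
                     window_last_day)
}

chemo_window_check <- function(cats, codes, days, window_last_day) {
  is_chemo <- !is.na(cats) & cats == "CHEMOTHERAPY"
  neg <- any(is_chemo & !is.na(days) & days < 0)
  hits <- is_chemo & !is.na(days) & days >= 0 & days <= window_last_day
  if (any(hits)) {
    return(list(hit = TRUE, evidence = pick_window_evidence(hits, codes, days),
                rescue = FALSE, negative_day_flag = neg))
  }
  no_days <- length(days) == 0 || all(is.na(days))
  if (no_days && length(cats) >= 1 && is_chemo[1L]) {
    return(list(hit = TRUE,
                evidence = list(code = codes[1L], slot = 1L, day = NA_real_),
                rescue = TRUE, negative_day_flag = neg))
  }
  list(hit = FALSE, evidence = no_evidence(), rescue = FALSE,
       negative_day_flag = neg)
}

#' Cancer-directed procedure within the admission window
#'
#' TRUE when a procedure in the CANCER_PROCEDURE category was performed on
#' day 0 through `window_last_day`. Unlike chemotherapy there is no
#' missing-date rescue: with over a thousand candidate procedure codes, a
#' dateless fallback would be imprecise, so records without usable days are
#' left for the diagnosis-based steps (a known source of procedure
#' under-ascertainment in states that omit procedure days).
#'
#' @inheritParams has_chemo_in_window
#' @return List with `hit` and `evidence`.
#' @export
has_cancer_procedure_in_window <- function(r, map, scheme,
                                           window_last_day = 2) {
  adm <- as_admission(r)
  pc <- admission_proc_categories(adm, map, scheme)
  procedure_window_check(pc$category, adm$proc_codes, adm$proc_days,
                         window_last_day)
}

procedure_window_check <- function(cats, codes, days, window_last_day) {
  hits <- !is.na(cats) & cats == "CANCER_PROCEDURE" &
    !is.na(days) & days >= 0 & days <= window_last_day
  if (any(hits)) {
    list(hit = TRUE, evidence = pick_window_evidence(hits, codes, days))
  } else {
    list(hit = FALSE, evidence = no_evidence())
  }
}

#' Diagnosis trigger for infection / toxicity steps
#'
#' TRUE when the target category appears as the primary diagnosis, or as the
#' secondary diagnosis when the primary is an insufficient admission reason
#' (malignancy, chemotherapy encounter, or cytopenia). Only diagnosis slot 2
#' is consulted as "the secondary diagnosis". `TOXICITY` matches both the
#' cytopenia and the other-toxicity categories.
#'
#' @inheritParams has_chemo_in_window
#' @param target_category `"INFECTION"` or `"TOXICITY"`.
#' @return List with `hit` and `evidence`.
#' @export
dx_trigger_lookup <- function(r, map, scheme,
                              target_category = c("INFECTION", "TOXICITY")) {
  target_category <- match.arg(target_category)
  adm <- as_admission(r)
  dc <- admission_dx_categories(adm, map, scheme)
  dx_trigger_check(dc$category, adm$dx_codes, target_category)
}

dx_trigger_check <- function(cats, codes, target_category) {
  matches <- function(cat) {
    if (is.na(cat)) return(FALSE)
    if (target_category == "INFECTION") cat == "INFECTION"
    else cat %in% c("TOX_CYTOPENIA", "TOX_OTHER")
  }
  if (length(cats) >= 1 && matches(cats[1L])) {
    return(list(hit = TRUE,
                evidence = list(code = codes[1L], slot = 1L, day = NA_real_)))
  }
  substitutable <- length(cats) >= 2 && !is.na(cats[1L]) &&
    cats[1L] %in% c("MALIGNANCY", "CHEMOTHERAPY", "TOX_CYTOPENIA")
  if (substitutable && matches(cats[2L])) {
    return(list(hit = TRUE,
                evidence = list(code = codes[2L], slot = 2L, day = NA_real_)))
  }
  list(hit = FALSE, evidence = no_evidence())
}

# ---- classification ---------------------------------------------------------

classify_core <- function(adm, map, scheme, window_last_day) {
  dc <- admission_dx_categories(adm, map, scheme)
  pc <- admission_proc_categories(adm, map, scheme)
  n_unmapped <- sum(is.na(dc$group) & !is.na(adm$dx_codes)) +
    sum(is.na(pc$group) & !is.na(adm$proc_codes))

  chemo <- chemo_window_check(pc$category, adm$proc_codes, adm$proc_days,
                              window_last_day)
  res <- if (chemo$hit) {
    list(intent = "CHEMO",
         rule_fired = if (chemo$rescue) "chemo_primary_proc_no_days"
                      else "chemo_window",
         evidence = chemo$evidence)
  } else {
    proc <- procedure_window_check(pc$category, adm$proc_codes,
                                   adm$proc_days, window_last_day)
    if (proc$hit) {
      list(intent = "PROCEDURE", rule_fired = "procedure_window",
           evidence = proc$evidence)
    } else {
      inf <- dx_trigger_check(dc$category, adm$dx_codes, "INFECTION")
      if (inf$hit) {
        list(intent = "INFECTION",
             rule_fired = if (inf$evidence$slot == 1L) "infection_primary"
                          else "infection_secondary",
             evidence = inf$evidence)
      } else {
        tox <- dx_trigger_check(dc$category, adm$dx_codes, "TOXICITY")
        if (tox$hit) {
          list(intent = "TOXICITY",
               rule_fired = if (tox$evidence$slot == 1L) "toxicity_primary"
                            else "toxicity_secondary",
               evidence = tox$evidence)
        } else {
          list(intent = "UNDEFINED", rule_fired = "undefined",
               evidence = no_evidence())
        }
      }
    }
  }
  res$negative_day_flag <- chemo$negative_day_flag
  res$n_unmapped <- n_unmapped
  res
}

#' Classify one admission
#'
#' Applies the stepwise algorithm to a single record already known to be in
#' the cancer cohort. Every record receives exactly one intent; records
#' matching no rule are `UNDEFINED`.
#'
#' @inheritParams has_chemo_in_window
#' @return List with `id`, `intent`, `rule_fired`, `evidence`
#'   (code/slot/day) and `negative_day_flag`.
#' @export
classify_admission <- function(r, map, scheme, window_last_day = 2) {
  adm <- as_admission(r)
  res <- classify_core(adm, map, scheme, window_last_day)
  list(id = adm$id, intent = res$intent, rule_fired = res$rule_fired,
       evidence = res$evidence, negative_day_flag = res$negative_day_flag)
}

#' Classify a cohort of admissions
#'
#' Runs [classify_admission()] over every row of a cohort table. Intents are
#' mutually exclusive and exhaustive: the per-intent counts always sum to
#' the cohort size.
#'
#' @param records Cohort table (rows typically from
#'   [identify_cancer_cohort()]).
#' @param map,scheme CCS map and category scheme.
#' @param window_last_day Last qualifying procedure day, default 2, so the
#'   window is days 0, 1 and 2 of the stay.
#' @return Data frame with one row per admission: `id`, `intent`,
#'   `rule_fired`, `evidence_code`, `evidence_slot`, `evidence_day`,
#'   `negative_day_flag`; attributes `intent_counts` (named integer vector
#'   over the five intents) and `n_unmapped_codes`.
#' @export
classify_cohort <- function(records, map, scheme, window_last_day = 2) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  intent <- character(n)
  rule <- character(n)
  ev_code <- character(n)
  ev_slot <- integer(n)
  ev_day <- numeric(n)
  negflag <- logical(n)
  n_unmapped <- 0L
  for (i in seq_len(n)) {
    adm <- as_admission(records, i)
    res <- classify_core(adm, map, scheme, window_last_day)
    intent[i] <- res$intent
    rule[i] <- res$rule_fired
    ev_code[i] <- res$evidence$code
    ev_slot[i] <- res$evidence$slot
    ev_day[i] <- res$evidence$day
    negflag[i] <- res$negative_day_flag
    n_unmapped <- n_unmapped + res$n_unmapped
  }
  out <- data.frame(
    id = if (n) records$id else character(),
    intent = factor(intent, levels = INTENTS),
    rule_fired = rule,
    evidence_code = ev_code,
    evidence_slot = ev_slot,
    evidence_day = ev_day,
    negative_day_flag = negflag,
    stringsAsFactors = FALSE)
  attr(out, "intent_counts") <- intent_counts(out)
  attr(out, "n_unmapped_codes") <- n_unmapped
  out
}

#' Per-intent counts of a classified cohort
#'
#' @param classified Output of [classify_cohort()].
#' @return Named integer vector over the five intents.
#' @export
intent_counts <- function(classified) {
  tab <- table(factor(classified$intent, levels = INTENTS))
  stats::setNames(as.integer(tab), INTENTS)
}
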