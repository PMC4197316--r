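# Resource-utilization measures per admission and per intent: cost estimated
# from billed charges via hospital cost-to-charge ratios, inflated to 2009
# dollars with a consumer-price-index table; length of stay; cost per day;
# and flags for stem-cell transplant, intensive-care-level diagnoses, and
# in-hospital death. Intents are compared by one-way ANOVA.

#' Cost tables: cost-to-charge ratios and CPI inflation factors
#'
#' @param ccr Data frame with columns `id` (record or hospital identifier)
#'   and `ratio` (cost-to-charge ratio, strictly positive).
#' @param cpi Data frame with columns `year` and `factor_to_2009`
#'   (multiplier converting that year's dollars to 2009 dollars; the 2009
#'   factor must be 1).
#' @return A `cost_tables` object.
#' @export
cost_tables <- function(ccr, cpi) {
  stopifnot(all(c("id", "ratio") %in% names(ccr)),
            all(c("year", "factor_to_2009") %in% names(cpi)))
  if (any(!is.na(ccr$ratio) & ccr$ratio <= 0)) {
    stop("cost-to-charge ratios must be strictly positive")
  }
  if (any(cpi$factor_to_2009 <= 0)) stop("CPI factors must be positive")
  if (2009 %in% cpi$year && abs(cpi$factor_to_2009[cpi$year == 2009] - 1) > 1e-9) {
    stop("the 2009 CPI factor must equal 1")
  }
  structure(list(
    ccr = stats::setNames(ccr$ratio, as.character(ccr$id)),
    cpi = stats::setNames(cpi$factor_to_2009, as.character(cpi$year))),
    class = "cost_tables")
}

cpi_factor <- function(year, tables) {
  unname(tables$cpi[as.character(year)])
}

#' Estimated admission cost in 2009 dollars
#'
#' `charge * cost-to-charge ratio * CPI factor(year)`. A missing ratio or a
#' year absent from the CPI table yields `NA` (the admission is excluded
#' from cost means downstream) rather than an error.
#'
#' @param charge Total billed charge in nominal dollars (vectorized).
#' @param ratio Cost-to-charge ratio for the admitting hospital.
#' @param year Admission year.
#' @param tables A `cost_tables` object supplying the CPI factors.
#' @return Estimated cost in 2009 US dollars.
#' @examples
#' tabs <- cost_tables(data.frame(id = "a", ratio = 0.5),
#'                     data.frame(year = c(2003, 2009),
#'                                factor_to_2009 = c(1.17, 1)))
#' admission_cost(10000, 0.5, 2009, tabs)  # 5000
#' admission_cost(10000, 0.5, 2003, tabs)  # 5850
#' @export
admission_cost <- function(charge, ratio, year, tables) {
  if (any(!is.na(charge) & charge < 0)) stop("charges must be non-negative")
  if (any(!is.na(ratio) & ratio <= 0)) stop("ratios must be strictly positive")
  charge * ratio * cpi_factor(year, tables)
}

#' Cost per hospital day
#'
#' Total cost divided by length of stay, with same-day discharges (LOS 0)
#' treated as one day so the quotient stays defined.
#'
#' @param cost Admission cost (vectorized).
#' @param los_days Length of stay in whole days.
#' @return Cost per day.
#' @export
cost_per_day <- function(cost, los_days) {
  if (any(!is.na(cost) & cost < 0)) stop("costs must be non-negative")
  cost / pmax(los_days, 1)
}

#' Flag resource-intense events on admissions
#'
#' Hematopoietic stem-cell transplantation (HCT) is flagged when any
#' procedure maps to the scheme's HCT procedure group (CCS 64 by default),
#' with the earliest recorded procedure day reported when available.
#' Intensive-care-level illness is proxied by diagnosis codes for
#' respiratory arrest/failure, cardiac arrest, or shock (CCS diagnostic
#' groups 131, 107, 249 by default) in any slot.
#'
#' @param records Wide admission table.
#' @param map,scheme CCS map and category scheme.
#' @return Data frame aligned with `records`: `id`, `hct`, `hct_day`, `icu`.
#' @export
flag_events <- function(records, map, scheme) {
  n <- nrow(records)
  hct <- icu <- logical(n)
  hct_day <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    adm <- as_admission(records, i)
    pg <- ccs_group(adm$proc_codes, map, "proc", strict = FALSE)
    is_hct <- !is.na(pg) & pg == scheme$hct_proc_group
    hct[i] <- any(is_hct)
    if (hct[i]) {
      d <- adm$proc_days[is_hct]
      if (any(!is.na(d))) hct_day[i] <- min(d, na.rm = TRUE)
    }
    dg <- ccs_group(adm$dx_codes, map, "dx", strict = FALSE)
    icu[i] <- any(!is.na(dg) & dg %in% scheme$icu_dx_groups)
  }
  data.frame(id = records$id, hct = hct, hct_day = hct_day, icu = icu,
             stringsAsFactors = FALSE)
}

#' Utilization summary by admission intent
#'
#' One row per intent (including UNDEFINED): admission count, mean length of
#' stay, mean cost in 2009 dollars, mean cost per day, and the percentage of
#' admissions with HCT, ICU-level diagnoses, and in-hospital death, plus the
#' mean hospital day of HCT. Admissions whose cost cannot be computed
#' (missing ratio or uncovered year) are excluded from the cost means only;
#' they still contribute to LOS and event rates.
#'
#' @param classified Output of [classify_cohort()].
#' @param records The cohort table that was classified; must carry `los`,
#'   `totchg`, `year`, `died`, and a `ccr` column (per-record cost-to-charge
#'   ratio) unless ratios are supplied via `tables$ccr` keyed by `id`.
#' @param map,scheme CCS map and category scheme (for the event flags).
#' @param tables A `cost_tables` object.
#' @return Data frame of per-intent utilization rows; `n` sums to the cohort
#'   size. Carries attribute `n_missing_cost`.
#' @export
summarize_by_intent <- function(classified, records, map, scheme, tables) {
  idx <- match(classified$id, records$id)
  if (anyNA(idx)) stop("classified ids missing from records")
  rec <- records[idx, , drop = FALSE]
  ratio <- if ("ccr" %in% names(rec)) rec$ccr
           else unname(tables$ccr[as.character(rec$id)])
  cost <- admission_cost(rec$totchg, ratio, rec$year, tables)
  cpd <- cost_per_day(cost, rec$los)
  ev <- flag_events(rec, map, scheme)
  intent <- factor(classified$intent, levels = INTENTS)

  mean_or_na <- function(x) if (length(x) && any(!is.na(x)))
    mean(x, na.rm = TRUE) else NA_real_
  rows <- lapply(INTENTS, function(lev) {
    sel <- intent == lev
    data.frame(
      intent = lev,
      n = sum(sel),
      mean_los_days = mean_or_na(rec$los[sel]),
      mean_cost_2009usd = mean_or_na(cost[sel]),
      mean_cost_per_day = mean_or_na(cpd[sel]),
      pct_hct = if (any(sel)) 100 * mean(ev$hct[sel]) else NA_real_,
      mean_hct_day = mean_or_na(ev$hct_day[sel & ev$hct]),
      pct_icu = if (any(sel)) 100 * mean(ev$icu[sel]) else NA_real_,
      pct_died = if (any(sel)) 100 * mean(as.logical(rec$died[sel])) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_missing_cost") <- sum(is.na(cost))
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: the F statistic on `(k - 1, N - k)`
#' degrees of freedom for `k` groups and `N` observations. Degenerate inputs
#' are resolved explicitly rather than returned as `NaN`: when the
#' between-group sum of squares is (numerically) zero the result is
#' `F = 0, p = 1`; when groups are separated but within-group variance is
#' zero, the within sum of squares is floored at a small epsilon and a large
#' finite F is returned.
#'
#' @param groups A list of numeric vectors (one per group), or a numeric
#'   vector when `g` supplies group labels.
#' @param g Optional grouping vector aligned with a numeric `groups`.
#' @param log_transform If `TRUE`, analyse `log(x + 1)` -- an option for
#'   right-skewed cost data.
#' @return List: `f`, `p`, `df1`, `df2`, `n`.
#' @examples
#' anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(5, 6, 7)))
#' @export
anova_oneway <- function(groups, g = NULL, log_transform = FALSE) {
  if (!is.null(g)) groups <- split(as.numeric(groups), g)
  groups <- lapply(groups, function(x) as.numeric(x[!is.na(x)]))
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  if (k < 2) stop("need at least two non-empty groups")
  if (log_transform) groups <- lapply(groups, function(x) log(x + 1))
  n_i <- lengths(groups)
  n <- sum(n_i)
  if (n - k < 1) stop("need at least one group with two or more values")
  means <- vapply(groups, mean, 0)
  grand <- sum(n_i * means) / n
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  df1 <- k - 1L
  df2 <- n - k
  scale <- sum(vapply(groups, function(x) sum(x^2), 0))
  eps <- max(scale, 1) * .Machine$double.eps
  if (ss_between <= eps) {
    return(list(f = 0, p = 1, df1 = df1, df2 = df2, n = n))
  }
  f <- (ss_between / df1) / (max(ss_within, eps) / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, n = n)
}
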