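# Accuracy arithmetic for rule-based phenotyping: PPV, sensitivity, and
# simple asymptotic (Wald) confidence intervals, plus confusion matrices
# against ground-truth labels. These are the statistics a chart review of
# assigned admissions yields: tp + fp = records reviewed in a category,
# fn = records of that category the algorithm put elsewhere.

#' Positive predictive value
#'
#' Fraction of admissions assigned to a category whose codes genuinely
#' support that category: `tp / (tp + fp)`.
#'
#' @param tp,fp Non-negative counts of true and false positives.
#' @return Proportion in `[0, 1]`.
#' @examples
#' ppv(53932, 193) # 0.9964
#' @export
ppv <- function(tp, fp) {
  check_counts(tp, fp)
  if (any(tp + fp == 0)) stop("undefined proportion: tp + fp = 0")
  tp / (tp + fp)
}

#' Sensitivity (recall)
#'
#' `tp / (tp + fn)`: the fraction of all admissions of a category that the
#' algorithm actually assigned to it.
#'
#' @param tp,fn Non-negative counts of true positives and false negatives.
#' @return Proportion in `[0, 1]`.
#' @export
sensitivity <- function(tp, fn) {
  check_counts(tp, fn)
  if (any(tp + fn == 0)) stop("undefined proportion: tp + fn = 0")
  tp / (tp + fn)
}

check_counts <- function(...) {
  v <- c(...)
  if (any(is.na(v)) || any(v < 0)) stop("counts must be non-negative")
  invisible(TRUE)
}

#' Confidence interval for a proportion
#'
#' Default is the simple asymptotic (Wald) interval
#' `p +/- z * sqrt(p (1 - p) / n)`, clipped to `[0, 1]`; appropriate here
#' because review denominators run to tens of thousands. It degenerates to
#' zero width at `p = 0` or `p = 1`; the Wilson score interval is available
#' as an alternative for small-sample or boundary use.
#'
#' @param p Observed proportion in `[0, 1]`.
#' @param n Denominator (number of Bernoulli trials), `> 0`.
#' @param level Confidence level, default 0.95.
#' @param method `"wald"` (default) or `"wilson"`.
#' @return List of class `proportion_ci`: `p`, `lo`, `hi`, `n`, `level`,
#'   `method`.
#' @examples
#' asymptotic_ci(0.5, 100)           # 0.402 -- 0.598
#' asymptotic_ci(53932 / 54125, 54125)
#' @export
asymptotic_ci <- function(p, n, level = 0.95, method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (length(n) != 1 || is.na(n) || n <= 0) stop("n must be a positive count")
  if (is.na(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- max(0, p - half)
    hi <- min(1, p + half)
  } else {
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- max(0, centre - half)
    hi <- min(1, centre + half)
  }
  structure(list(p = p, lo = lo, hi = hi, n = n, level = level,
                 method = method),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%.1f%% (%s %.0f%% CI %.1f-%.1f%%, n = %d)\n",
              100 * x$p, x$method, 100 * x$level, 100 * x$lo, 100 * x$hi,
              as.integer(x$n)))
  invisible(x)
}

#' Confusion matrix of assigned versus true intents
#'
#' Rows are truth, columns are the assigned intent; `tp` is the diagonal,
#' `fp` the rest of a column, `fn` the rest of a row. Classified rows and
#' truth labels are matched by `id`.
#'
#' @param classified Output of [classify_cohort()].
#' @param truth Data frame with columns `id` and `intent` (truth labels over
#'   the five intents), or a vector of labels aligned with `classified`.
#' @return List with `matrix` (5x5 integer) and `counts` (data frame:
#'   intent, tp, fp, fn, n_reviewed).
#' @export
confusion_matrix <- function(classified, truth) {
  assigned <- as.character(classified$intent)
  if (is.data.frame(truth)) {
    idx <- match(classified$id, truth$id)
    if (anyNA(idx)) stop("id mismatch between classified records and truth")
    true_lab <- as.character(truth$intent)[idx]
  } else {
    if (length(truth) != length(assigned)) {
      stop("truth labels must align with classified records")
    }
    true_lab <- as.character(truth)
  }
  if (!all(true_lab %in% INTENTS)) {
    stop("truth labels must be one of: ", paste(INTENTS, collapse = ", "))
  }
  m <- table(factor(true_lab, levels = INTENTS),
             factor(assigned, levels = INTENTS))
  m <- matrix(as.integer(m), nrow = length(INTENTS),
              dimnames = list(truth = INTENTS, assigned = INTENTS))
  tp <- diag(m)
  counts <- data.frame(
    intent = INTENTS,
    tp = as.integer(tp),
    fp = as.integer(colSums(m) - tp),
    fn = as.integer(rowSums(m) - tp),
    n_reviewed = as.integer(colSums(m)),
    stringsAsFactors = FALSE)
  list(matrix = m, counts = counts)
}

#' Per-intent validation report
#'
#' Turns tp/fp/fn tallies into PPV and sensitivity with confidence
#' intervals, one row per intent. Intents with no reviewed records (or no
#' true cases) report `NA` for the undefined proportion rather than failing
#' the whole report.
#'
#' @param counts Data frame with columns `intent`, `tp`, `fp`, `fn`
#'   (e.g. `confusion_matrix(...)$counts`, or review tallies read from a
#'   file). `fn` may be `NA` where misclassification was not tallied.
#' @param level Confidence level for the intervals.
#' @param percent If `TRUE`, report proportions as percentages rounded to
#'   one decimal, the conventional presentation; raw proportions otherwise.
#' @return Data frame: intent, n_reviewed, tp, fp, fn, ppv, ppv_lo, ppv_hi,
#'   sensitivity, sens_lo, sens_hi.
#' @export
validation_report <- function(counts, level = 0.95, percent = FALSE) {
  stopifnot(all(c("intent", "tp", "fp", "fn") %in% names(counts)))
  one <- function(tp, fp, fn) {
    p_ci <- s_ci <- list(p = NA_real_, lo = NA_real_, hi = NA_real_)
    if (!is.na(tp) && !is.na(fp) && tp + fp > 0) {
      p_ci <- asymptotic_ci(ppv(tp, fp), tp + fp, level)
    }
    if (!is.na(tp) && !is.na(fn) && tp + fn > 0) {
      s_ci <- asymptotic_ci(sensitivity(tp, fn), tp + fn, level)
    }
    c(ppv = p_ci$p, ppv_lo = p_ci$lo, ppv_hi = p_ci$hi,
      sensitivity = s_ci$p, sens_lo = s_ci$lo, sens_hi = s_ci$hi)
  }
  stats <- t(mapply(one, counts$tp, counts$fp, counts$fn))
  if (percent) stats <- round(100 * stats, 1)
  out <- data.frame(
    intent = counts$intent,
    n_reviewed = counts$tp + counts$fp,
    tp = counts$tp, fp = counts$fp, fn = counts$fn,
    stats,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Published chart-review tallies
#'
#' Loads the bundled per-intent review tallies (true positives, false
#' positives and, where tallied, false negatives) from the original manual
#' review of the algorithm's assignments on the 2003/2006/2009 KID cancer
#' cohort. Useful as a worked example for [validation_report()] and as the
#' reference point for the validation arithmetic.
#'
#' @return Data frame: intent, reviewed, tp, fp, fn.
#' @export
published_review_tallies <- function() {
  utils::read.csv(system.file("extdata", "review_tallies.csv",
                              package = "admitintent", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}
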