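# CSV readers/writers and the end-to-end pipeline.
#
# CSV dialect throughout: UTF-8, comma-separated, header row required,
# empty cell = missing value.

REQUIRED_RECORD_COLS <- c("id", "year", "dx1", "los", "totchg", "died")

#' Read an admission records CSV
#'
#' Expected columns: `id`, `year`, diagnosis slots `dx1..dxK` (K <= 25,
#' `dx1` required), procedure slots `pr1..prM` and matching `prday1..prdayM`
#' (M <= 15, optional), `los`, `totchg`, `died`, optional demographics
#' (`age_group`, `sex`, `payer`, `race`), optional `prday_reported` and
#' `ccr`. Empty cells are missing values.
#'
#' @param path Path to the CSV.
#' @return The validated admission table.
#' @export
read_admissions <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = TRUE))
  # code slots must never be parsed as numbers ("047.9" is not 47.9)
  classes <- rep(NA_character_, length(hdr))
  classes[grepl("^(dx|pr)[0-9]+$", hdr) | hdr == "id"] <- "character"
  classes[grepl("^prday[0-9]+$", hdr)] <- "numeric"
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             na.strings = c("", "NA"),
                             colClasses = classes)
  missing_cols <- setdiff(REQUIRED_RECORD_COLS, names(records))
  if (length(missing_cols)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in slot_cols(records, "dx")) records[[col]] <- as.character(records[[col]])
  for (col in slot_cols(records, "pr")) records[[col]] <- as.character(records[[col]])
  for (col in slot_cols(records, "prday")) records[[col]] <- as.numeric(records[[col]])
  records$id <- as.character(records$id)
  if (anyDuplicated(records$id)) stop("schema error: duplicate record ids")
  records$year <- as.integer(records$year)
  records$los <- as.integer(records$los)
  if (any(!is.na(records$los) & records$los < 0)) {
    stop("schema error: negative length of stay")
  }
  records$totchg <- as.numeric(records$totchg)
  records$died <- as.logical(records$died)
  if (!"prday_reported" %in% names(records)) {
    records$prday_reported <- TRUE
  } else {
    records$prday_reported <- as.logical(records$prday_reported)
  }
  records
}

#' Write a table as CSV (empty cell = missing)
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a classified-admissions CSV
#'
#' @param path Path written by [write_table_csv()] from [classify_cohort()]
#'   output.
#' @return Data frame with the `intent` column restored as a factor over the
#'   five intents.
#' @export
read_classified <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"),
                       colClasses = c(id = "character",
                                      evidence_code = "character"))
  x$intent <- factor(x$intent, levels = INTENTS)
  x$evidence_code <- as.character(x$evidence_code)
  x
}

#' Read cost tables from CSV
#'
#' @param ccr_path CSV with columns `id,ratio`.
#' @param cpi_path CSV with columns `year,factor_to_2009`.
#' @return A `cost_tables` object.
#' @export
read_cost_tables <- function(ccr_path, cpi_path) {
  cost_tables(utils::read.csv(ccr_path, stringsAsFactors = FALSE),
              utils::read.csv(cpi_path, stringsAsFactors = FALSE))
}

#' Run the full pipeline on files
#'
#' Reads the inputs, identifies the cancer cohort, classifies it, and writes
#' `classified.csv`, `utilization.csv`, a `manifest.json` with stage counts,
#' and -- when ground-truth labels are supplied -- `validation.csv` with the
#' per-intent confusion-matrix statistics.
#'
#' @param records_path Admission records CSV.
#' @param out_dir Output directory (created if absent).
#' @param map_path CCS mapping CSV; default is the bundled compact map.
#' @param scheme_path Category scheme YAML; default is the built-in scheme.
#' @param ccr_path,cpi_path Cost tables; `ccr_path` may be `NULL` when the
#'   records carry a `ccr` column, and `cpi_path` defaults to the bundled
#'   2003/2006/2009 CPI factors.
#' @param truth_path Optional CSV of ground-truth labels (`id,intent`).
#' @param window_last_day Last qualifying procedure day.
#' @return The run manifest (invisibly), a list of input paths, settings and
#'   stage counts; also serialized as JSON alongside the outputs.
#' @export
run_pipeline <- function(records_path, out_dir,
                         map_path = NULL, scheme_path = NULL,
                         ccr_path = NULL, cpi_path = NULL,
                         truth_path = NULL, window_last_day = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_admissions(records_path)
  map <- if (is.null(map_path)) synthetic_ccs_map() else read_ccs_map(map_path)
  scheme <- load_category_scheme(scheme_path)
  cpi <- if (is.null(cpi_path)) default_cpi_table()
         else utils::read.csv(cpi_path, stringsAsFactors = FALSE)
  ccr <- if (!is.null(ccr_path)) {
    utils::read.csv(ccr_path, stringsAsFactors = FALSE)
  } else if ("ccr" %in% names(records)) {
    data.frame(id = records$id, ratio = records$ccr, stringsAsFactors = FALSE)
  } else {
    stop("no cost-to-charge ratios: supply ccr_path or a ccr column")
  }
  tables <- cost_tables(ccr, cpi)

  cohort <- identify_cancer_cohort(records, map, scheme)
  classified <- classify_cohort(cohort, map, scheme, window_last_day)
  write_table_csv(classified, file.path(out_dir, "classified.csv"))

  util <- summarize_by_intent(classified, cohort, map, scheme, tables)
  write_table_csv(util, file.path(out_dir, "utilization.csv"))

  validation <- NULL
  if (!is.null(truth_path)) {
    truth <- utils::read.csv(truth_path, stringsAsFactors = FALSE)
    truth <- truth[truth$intent %in% INTENTS, , drop = FALSE]
    in_cohort <- classified$id %in% truth$id
    cm <- confusion_matrix(classified[in_cohort, , drop = FALSE], truth)
    validation <- validation_report(cm$counts)
    write_table_csv(validation, file.path(out_dir, "validation.csv"))
  }

  counts <- intent_counts(classified)
  manifest <- list(
    inputs = list(records = records_path, map = map_path,
                  scheme = scheme_path, ccr = ccr_path, cpi = cpi_path,
                  truth = truth_path),
    window_last_day = window_last_day,
    n_records = nrow(records),
    n_cohort = nrow(cohort),
    n_excluded_non_cancer = attr(cohort, "n_excluded_non_cancer"),
    n_unmapped_dx_codes_cohort_scan = attr(cohort, "n_unmapped_dx_codes"),
    n_unmapped_codes_classification = attr(classified, "n_unmapped_codes"),
    intent_counts = as.list(counts),
    n_missing_cost = attr(util, "n_missing_cost"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
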