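# ICD-9-CM -> CCS group -> clinical category machinery.
#
# The classifier never reasons about raw ICD-9 codes except through two
# lookups: (1) a CCS map collapsing ~12,000 diagnosis codes into 260
# diagnostic groups and ~3,500 procedure codes into 231 procedure groups,
# and (2) a category scheme collapsing CCS groups into the handful of
# clinical categories the admission-indication rules consume.

DX_CATEGORIES <- c("MALIGNANCY", "CHEMOTHERAPY", "INFECTION",
                   "TOX_CYTOPENIA", "TOX_OTHER", "OTHER")
PROC_CATEGORIES <- c("CHEMOTHERAPY", "CANCER_PROCEDURE", "OTHER")
INTENTS <- c("CHEMO", "PROCEDURE", "INFECTION", "TOXICITY", "UNDEFINED")

N_DX_GROUPS <- 260L
N_PROC_GROUPS <- 231L

#' Normalize an ICD-9-CM code
#'
#' Collapses the formatting variants seen in claims extracts (decimal points,
#' lower-case V/E prefixes, stray whitespace) onto a single canonical form:
#' upper case, no dot. Normalization is idempotent, so already-normalized
#' codes pass through unchanged.
#'
#' @param x Character vector of raw ICD-9-CM codes. `NA` entries are
#'   preserved (a missing code slot is not an error); empty or blank strings
#'   are.
#' @return Character vector of normalized codes, same length as `x`.
#' @examples
#' normalize_icd9(c("999.31", "v58.1", "99931"))
#' @export
normalize_icd9 <- function(x) {
  if (!is.character(x)) {
    if (is.factor(x)) x <- as.character(x) else stop("ICD-9 codes must be character")
  }
  out <- toupper(gsub(".", "", trimws(x), fixed = TRUE))
  bad <- !is.na(out) & (out == "" | !grepl("^[VE0-9][0-9]*$", out))
  if (any(bad)) {
    stop("invalid ICD-9 code(s): ",
         paste(sQuote(unique(x[bad])), collapse = ", "))
  }
  out[!is.na(out) & out == ""] <- NA_character_
  out
}

#' Read an ICD-9 to CCS mapping table
#'
#' The mapping file is a CSV with columns `icd9`, `ccs_group`, `kind`
#' (`dx` or `proc`). Codes are normalized on load. Because CCS definitions
#' are revised between dataset years, the map carries the year it applies to
#' and is loaded per dataset rather than hard-coded.
#'
#' @param path Path to the mapping CSV.
#' @param year Dataset year the map applies to.
#' @return A `ccs_map` object: named integer vectors `dx_map` and `proc_map`
#'   keyed by normalized ICD-9 code, plus `year`.
#' @seealso [synthetic_ccs_map()] for the compact map bundled for examples
#'   and synthetic data.
#' @export
read_ccs_map <- function(path, year = NA_integer_) {
  tab <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("icd9", "ccs_group", "kind")
  if (!all(need %in% names(tab))) {
    stop("CCS map must have columns ", paste(need, collapse = ", "))
  }
  tab$icd9 <- normalize_icd9(tab$icd9)
  tab$ccs_group <- as.integer(tab$ccs_group)
  if (anyNA(tab$ccs_group)) stop("non-integer ccs_group in ", path)
  if (!all(tab$kind %in% c("dx", "proc"))) stop("kind must be 'dx' or 'proc'")
  ccs_map(dx = tab[tab$kind == "dx", c("icd9", "ccs_group")],
          proc = tab[tab$kind == "proc", c("icd9", "ccs_group")],
          year = year)
}

#' Construct a CCS map from diagnosis and procedure tables
#'
#' @param dx,proc Data frames with columns `icd9` (normalized) and
#'   `ccs_group`.
#' @param year Dataset year.
#' @return A `ccs_map` object.
#' @export
ccs_map <- function(dx, proc, year = NA_integer_) {
  build <- function(tab, n_groups, what) {
    if (anyDuplicated(tab$icd9)) {
      dup <- unique(tab$icd9[duplicated(tab$icd9)])
      stop("duplicate ", what, " codes in CCS map: ",
           paste(dup, collapse = ", "))
    }
    grp <- as.integer(tab$ccs_group)
    if (any(grp < 1L | grp > n_groups)) {
      stop(what, " CCS groups must lie in 1..", n_groups)
    }
    stats::setNames(grp, tab$icd9)
  }
  structure(
    list(dx_map = build(dx, N_DX_GROUPS, "dx"),
         proc_map = build(proc, N_PROC_GROUPS, "proc"),
         year = as.integer(year)),
    class = "ccs_map")
}

#' @export
print.ccs_map <- function(x, ...) {
  cat("CCS map (year ", ifelse(is.na(x$year), "unspecified", x$year), "): ",
      length(x$dx_map), " diagnosis codes, ",
      length(x$proc_map), " procedure codes\n", sep = "")
  invisible(x)
}

#' Bundled compact CCS map
#'
#' Loads the small synthetic mapping table shipped with the package
#' (`extdata/ccs_map_synthetic.csv`). It covers the real ICD-9 codes used by
#' the synthetic record generator plus category fillers; it is a partial,
#' reconstructed stand-in for the official HCUP CCS tables (which ship with
#' licensed HCUP data), not a faithful copy of them.
#'
#' @param year Dataset year recorded on the map.
#' @return A `ccs_map` object.
#' @export
synthetic_ccs_map <- function(year = 2009L) {
  read_ccs_map(system.file("extdata", "ccs_map_synthetic.csv",
                           package = "admitintent", mustWork = TRUE),
               year = year)
}

#' Look up CCS groups for ICD-9 codes
#'
#' @param codes Character vector of ICD-9 codes (normalized on the fly).
#' @param map A `ccs_map`.
#' @param kind `"dx"` or `"proc"`.
#' @param strict If `TRUE` (default) an unmapped code is an error; if
#'   `FALSE` it yields `NA`, which the classifier treats as non-qualifying.
#' @return Integer vector of CCS group ids (with `NA` for missing slots).
#' @export
ccs_group <- function(codes, map, kind = c("dx", "proc"), strict = TRUE) {
  kind <- match.arg(kind)
  stopifnot(inherits(map, "ccs_map"))
  lut <- if (kind == "dx") map$dx_map else map$proc_map
  codes <- normalize_icd9(codes)
  out <- unname(lut[codes])
  unmapped <- !is.na(codes) & is.na(out)
  if (strict && any(unmapped)) {
    stop("unmapped ", kind, " ICD-9 code(s): ",
         paste(unique(codes[unmapped]), collapse = ", "))
  }
  out
}

# ---- category scheme --------------------------------------------------------

default_dx_assignments <- function() {
  dx <- rep("OTHER", N_DX_GROUPS)
  dx[11:43] <- "MALIGNANCY"
  dx[45] <- "CHEMOTHERAPY"
  # Definitive or presumed infection by any microbe, fever, or shock.
  dx[c(1:9, 76, 77, 122, 123, 126, 135, 159, 197, 246, 249)] <- "INFECTION"
  # Cytopenias: insufficient reason for admission on their own, so they
  # trigger the secondary-diagnosis substitution like malignancy does.
  dx[c(59, 60, 62, 63, 64)] <- "TOX_CYTOPENIA"
  # Non-infectious treatment- or disease-related toxicity.
  dx[c(55, 83, 95, 107, 131, 152, 153, 157, 237, 238, 250, 251, 252, 253)] <-
    "TOX_OTHER"
  dx
}

default_proc_assignments <- function() {
  pr <- rep("OTHER", N_PROC_GROUPS)
  pr[224] <- "CHEMOTHERAPY"
  # Operative and diagnostic procedures directed at the malignancy or its
  # treatment-related complications. Imaging and blood-product transfusion
  # groups stay OTHER deliberately: they accompany nearly every oncology
  # admission and carry no signal about why the child was admitted.
  pr[c(1, 2, 3, 9, 61, 64, 66, 67, 89, 99, 170)] <- "CANCER_PROCEDURE"
  pr
}

#' Default category scheme
#'
#' Builds the category scheme used throughout the package: CCS diagnostic
#' groups 11-43 are malignancy, group 45 is a chemotherapy encounter,
#' infection groups cover microbial infection, fever and shock, cytopenias
#' are groups 59, 60 and 62-64, and a named set of toxicity groups covers
#' non-infectious complications. Diagnostic group 237 ("complication of
#' device, implant or graft") mixes infectious and non-infectious codes, so
#' it is split at the ICD-9 level: 999.31, 996.62, 996.67 and 996.69 are
#' infections, every other 237 code is a non-infectious toxicity. Procedure
#' group 224 is chemotherapy; a set of operative groups are cancer-directed
#' procedures; all other groups (including imaging and transfusion) are
#' OTHER.
#'
#' The full group-by-group table used with licensed hospital data is a
#' clinical consensus product; this default is a reconstruction of its
#' stated rules that covers every group the classifier and the synthetic
#' generator reference. Unlisted groups fall to OTHER, which pushes
#' ambiguous admissions toward UNDEFINED rather than mislabelling them.
#'
#' @return A `category_scheme` object.
#' @export
default_category_scheme <- function() {
  new_category_scheme(
    dx_categories = default_dx_assignments(),
    proc_categories = default_proc_assignments(),
    dx_overrides = data.frame(
      ccs_group = 237L,
      icd9 = c("99931", "99662", "99667", "99669"),
      category = "INFECTION",
      stringsAsFactors = FALSE),
    hct_proc_group = 64L,
    icu_dx_groups = c(131L, 107L, 249L),
    cytopenia_groups = c(59L, 60L, 62L, 63L, 64L),
    excluded_cancer_groups = 44L)
}

new_category_scheme <- function(dx_categories, proc_categories, dx_overrides,
                                hct_proc_group, icu_dx_groups,
                                cytopenia_groups, excluded_cancer_groups) {
  stopifnot(length(dx_categories) == N_DX_GROUPS,
            length(proc_categories) == N_PROC_GROUPS,
            all(dx_categories %in% DX_CATEGORIES),
            all(proc_categories %in% PROC_CATEGORIES))
  dx_overrides$icd9 <- normalize_icd9(dx_overrides$icd9)
  if (anyDuplicated(dx_overrides[c("ccs_group", "icd9")])) {
    stop("duplicate (group, code) pair in dx_overrides")
  }
  if (!all(dx_overrides$category %in% DX_CATEGORIES)) {
    stop("unknown category in dx_overrides")
  }
  structure(
    list(dx_categories = dx_categories,
         proc_categories = proc_categories,
         dx_overrides = dx_overrides,
         hct_proc_group = as.integer(hct_proc_group),
         icu_dx_groups = as.integer(icu_dx_groups),
         cytopenia_groups = as.integer(cytopenia_groups),
         excluded_cancer_groups = as.integer(excluded_cancer_groups),
         malignancy_groups = which(dx_categories == "MALIGNANCY")),
    class = "category_scheme")
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("Category scheme\n")
  cat("  dx groups:   ", paste(sprintf("%s=%d", names(table(x$dx_categories)),
                                       table(x$dx_categories)),
                               collapse = ", "), "\n")
  cat("  proc groups: ", paste(sprintf("%s=%d", names(table(x$proc_categories)),
                                       table(x$proc_categories)),
                               collapse = ", "), "\n")
  cat("  dx overrides:", nrow(x$dx_overrides), "code(s) in group(s)",
      paste(unique(x$dx_overrides$ccs_group), collapse = ", "), "\n")
  invisible(x)
}

#' Load a category scheme from a YAML config
#'
#' The config lists CCS groups per category (see
#' `extdata/scheme_default.yaml` for the bundled default). Sections:
#' `dx_categories` and `proc_categories` map category names to group-id
#' vectors; `dx_overrides` is a list of `{ccs_group, icd9, category}`
#' entries; scalar/set fields `hct_proc_group`, `icu_dx_groups`,
#' `cytopenia_groups`, `excluded_cancer_groups`. A group assigned to two
#' categories is a configuration error. Groups the config leaves unassigned
#' default to OTHER with a warning, the conservative direction: unknown
#' diagnoses push an admission toward UNDEFINED instead of into a category.
#'
#' @param path Path to the YAML config, or `NULL` for the built-in default
#'   scheme (no file read, no warning).
#' @param quiet Suppress the unassigned-group warning.
#' @return A `category_scheme` object.
#' @export
load_category_scheme <- function(path = NULL, quiet = FALSE) {
  if (is.null(path)) return(default_category_scheme())
  cfg <- yaml::read_yaml(path)

  fill <- function(section, n_groups, valid, what) {
    out <- rep(NA_character_, n_groups)
    for (cat_name in names(section)) {
      if (!cat_name %in% valid) {
        stop("unknown ", what, " category in config: ", cat_name)
      }
      groups <- as.integer(unlist(section[[cat_name]]))
      if (any(groups < 1L | groups > n_groups)) {
        stop(what, " group id out of range 1..", n_groups)
      }
      clash <- groups[!is.na(out[groups]) & out[groups] != cat_name]
      if (length(clash)) {
        stop("configuration error: ", what, " group(s) ",
             paste(clash, collapse = ", "), " assigned to two categories")
      }
      out[groups] <- cat_name
    }
    n_missing <- sum(is.na(out))
    if (n_missing > 0 && !quiet) {
      warning(n_missing, " ", what,
              " group(s) not assigned in config; defaulting to OTHER",
              call. = FALSE)
    }
    out[is.na(out)] <- "OTHER"
    out
  }

  ov <- cfg$dx_overrides
  dx_overrides <- if (length(ov)) {
    data.frame(ccs_group = as.integer(vapply(ov, `[[`, 0, "ccs_group")),
               icd9 = vapply(ov, `[[`, "", "icd9"),
               category = vapply(ov, `[[`, "", "category"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(ccs_group = integer(), icd9 = character(),
               category = character(), stringsAsFactors = FALSE)
  }

  pick <- function(field, default) {
    if (is.null(cfg[[field]])) default else as.integer(unlist(cfg[[field]]))
  }

  new_category_scheme(
    dx_categories = fill(cfg$dx_categories, N_DX_GROUPS,
                         DX_CATEGORIES, "dx"),
    proc_categories = fill(cfg$proc_categories, N_PROC_GROUPS,
                           PROC_CATEGORIES, "proc"),
    dx_overrides = dx_overrides,
    hct_proc_group = pick("hct_proc_group", 64L),
    icu_dx_groups = pick("icu_dx_groups", c(131L, 107L, 249L)),
    cytopenia_groups = pick("cytopenia_groups", c(59L, 60L, 62L, 63L, 64L)),
    excluded_cancer_groups = pick("excluded_cancer_groups", 44L))
}

#' Diagnostic category of a CCS group / ICD-9 code pair
#'
#' Consults the ICD-9-level override table (which houses the group-237
#' infection split) before the group-level assignment.
#'
#' @param group Integer vector of CCS diagnostic group ids.
#' @param code Character vector of ICD-9 codes (recycled if length 1); only
#'   consulted for groups that carry overrides.
#' @param scheme A `category_scheme`.
#' @return Character vector of diagnostic categories.
#' @examples
#' sch <- default_category_scheme()
#' dx_category(237, "999.31", sch)  # INFECTION (central line infection)
#' dx_category(237, "996.4", sch)   # TOX_OTHER (mechanical complication)
#' @export
dx_category <- function(group, code = NA_character_, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  group <- as.integer(group)
  if (anyNA(group) || any(group < 1L | group > N_DX_GROUPS)) {
    stop("lookup error: unmapped or out-of-range CCS diagnostic group")
  }
  code <- normalize_icd9(rep_len(as.character(code), length(group)))
  out <- scheme$dx_categories[group]
  ov <- scheme$dx_overrides
  if (nrow(ov)) {
    key <- paste(group, code, sep = ":")
    hit <- match(key, paste(ov$ccs_group, ov$icd9, sep = ":"))
    out[!is.na(hit)] <- ov$category[hit[!is.na(hit)]]
  }
  unname(out)
}

#' Procedure category of a CCS procedure group
#'
#' @param group Integer vector of CCS procedure group ids.
#' @param scheme A `category_scheme`.
#' @return Character vector of procedure categories.
#' @export
proc_category <- function(group, scheme) {
  stopifnot(inherits(scheme, "category_scheme"))
  group <- as.integer(group)
  if (anyNA(group) || any(group < 1L | group > N_PROC_GROUPS)) {
    stop("lookup error: unmapped or out-of-range CCS procedure group")
  }
  unname(scheme$proc_categories[group])
}
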