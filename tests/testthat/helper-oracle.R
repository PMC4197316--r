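# Independent brute-force reference classifier. Deliberately naive: it
# re-derives code normalization, the 237 split, and the rule cascade with
# plain loops and if-chains, sharing no code path with the package's
# classifier beyond the map/scheme containers it reads fields from.

oracle_classify <- function(records, map, scheme, window = 2) {
  norm <- function(x) toupper(gsub(".", "", trimws(x), fixed = TRUE))
  dx_cat_of <- function(code) {
    g <- unname(map$dx_map[code])
    if (is.na(g)) return(NA_character_)
    ov <- scheme$dx_overrides
    hit <- which(ov$ccs_group == g & ov$icd9 == code)
    if (length(hit)) return(ov$category[hit[1]])
    scheme$dx_categories[g]
  }
  proc_cat_of <- function(code) {
    g <- unname(map$proc_map[code])
    if (is.na(g)) NA_character_ else scheme$proc_categories[g]
  }

  out <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    dxs <- character()
    for (k in 1:25) {
      v <- records[[paste0("dx", k)]][i]
      if (!is.null(v) && !is.na(v) && nzchar(v)) dxs <- c(dxs, norm(v))
    }
    prs <- list()
    for (k in 1:15) {
      v <- records[[paste0("pr", k)]][i]
      if (!is.null(v) && !is.na(v) && nzchar(v)) {
        d <- records[[paste0("prday", k)]][i]
        prs[[length(prs) + 1]] <- list(code = norm(v), day = as.numeric(d))
      }
    }

    any_day <- FALSE
    for (p in prs) if (!is.na(p$day)) any_day <- TRUE

    chemo <- FALSE
    for (p in prs) {
      if (identical(proc_cat_of(p$code), "CHEMOTHERAPY") &&
          !is.na(p$day) && p$day >= 0 && p$day <= window) chemo <- TRUE
    }
    if (!chemo && !any_day && length(prs) >= 1 &&
        identical(proc_cat_of(prs[[1]]$code), "CHEMOTHERAPY")) chemo <- TRUE
    if (chemo) { out[i] <- "CHEMO"; next }

    proc <- FALSE
    for (p in prs) {
      if (identical(proc_cat_of(p$code), "CANCER_PROCEDURE") &&
          !is.na(p$day) && p$day >= 0 && p$day <= window) proc <- TRUE
    }
    if (proc) { out[i] <- "PROCEDURE"; next }

    c1 <- if (length(dxs) >= 1) dx_cat_of(dxs[1]) else NA_character_
    c2 <- if (length(dxs) >= 2) dx_cat_of(dxs[2]) else NA_character_
    substitutable <- !is.na(c1) &&
      c1 %in% c("MALIGNANCY", "CHEMOTHERAPY", "TOX_CYTOPENIA")
    is_tox <- function(cc) !is.na(cc) && cc %in% c("TOX_CYTOPENIA", "TOX_OTHER")

    if (identical(c1, "INFECTION") ||
        (substitutable && identical(c2, "INFECTION"))) {
      out[i] <- "INFECTION"
    } else if (is_tox(c1) || (substitutable && is_tox(c2))) {
      out[i] <- "TOXICITY"
    } else {
      out[i] <- "UNDEFINED"
    }
  }
  out
}
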