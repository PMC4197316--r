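# In-code fixtures: one-row wide admission records with the full KID-like
# slot layout (25 dx, 15 proc, 15 proc-day columns).

make_record <- function(id = "r1", dx = "204.00", pr = character(),
                        prday = numeric(), year = 2009L, los = 3L,
                        totchg = 10000, died = FALSE, prday_reported = TRUE,
                        ccr = 0.5) {
  rec <- data.frame(id = id, year = year, stringsAsFactors = FALSE)
  for (k in 1:25) {
    rec[[paste0("dx", k)]] <- if (k <= length(dx)) dx[k] else NA_character_
  }
  for (k in 1:15) {
    rec[[paste0("pr", k)]] <- if (k <= length(pr)) pr[k] else NA_character_
  }
  for (k in 1:15) {
    rec[[paste0("prday", k)]] <- if (k <= length(prday)) prday[k] else NA_real_
  }
  rec$los <- los
  rec$totchg <- totchg
  rec$died <- died
  rec$age_group <- "5-9"
  rec$sex <- "M"
  rec$payer <- "private"
  rec$race <- "white"
  rec$prday_reported <- prday_reported
  rec$ccr <- ccr
  rec
}

bind_records <- function(...) do.call(rbind, list(...))

test_map <- synthetic_ccs_map()
test_scheme <- default_category_scheme()
test_tables <- cost_tables(
  data.frame(id = "x", ratio = 0.5),
  default_cpi_table())
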