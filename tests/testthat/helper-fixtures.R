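# Shared fixture builders: everything is constructed in code, no data files.

the_instrument <- assist_instrument()

usage_using <- function() {
  list(pattern = "Most or every day", times_weekday = 2L,
       times_weekend = 3L, hours = "Within 1 hour")
}

usage_denying <- function() {
  list(pattern = "I do not use cannabis", times_weekday = 0L,
       times_weekend = 0L, hours = "I do not use cannabis")
}

# a moderate-risk response: item2 Weekly, items 3,4 Once or Twice,
# item5 Never, items 6,7 endorsed-past-3-months; total 4+3+4+0+6+6 = 23
moderate_response <- function(instrument = the_instrument) {
  response_from_ordinals(instrument, c(3, 1, 1, 0, 1, 1))
}

# one fully eligible, consenting, consistent record
consistent_record <- function(id = "R1", instrument = the_instrument) {
  r <- moderate_response(instrument)
  u <- usage_using()
  df <- data.frame(id = id, age = 30L, male = TRUE, postsec = TRUE,
                   married = FALSE, employed = TRUE, income_low = FALSE,
                   days_past30 = 25L, used_cannabis = TRUE,
                   consented = TRUE, duplicate = FALSE, withdrew = FALSE,
                   baseline_complete = TRUE, stringsAsFactors = FALSE)
  for (k in names(r)) {
    df[[paste0("scr_", k)]] <- r[[k]]
    df[[paste0("bl_", k)]] <- r[[k]]
  }
  df$usage_pattern <- u$pattern
  df$usage_times_weekday <- u$times_weekday
  df$usage_times_weekend <- u$times_weekend
  df$usage_hours <- u$hours
  df
}

# small cohort with per-record fates chosen deterministically
fated_cohort <- function(n = 20) {
  stopifnot(n >= 8)
  rows <- lapply(seq_len(n), function(i) consistent_record(sprintf("F%03d", i)))
  df <- do.call(rbind, rows)
  df$age[1] <- 17L                      # ineligible_age
  df$used_cannabis[2] <- FALSE          # ineligible_never_used
  for (k in paste0("scr_item", 2:7))    # ineligible_low_score
    df[[k]][3] <- the_instrument$items[[sub("scr_", "", k)]]$options[1]
  for (k in paste0("bl_item", 2:7))
    df[[k]][3] <- the_instrument$items[[sub("bl_", "", k)]]$options[1]
  df$consented[4] <- FALSE              # no_consent
  df$duplicate[5] <- TRUE               # duplicate_excluded
  df$withdrew[6] <- TRUE                # withdrew
  df$baseline_complete[7] <- FALSE      # baseline_incomplete
  df$bl_item4[8] <- "Never"             # screened_out (item-4 regression)
  df
}
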