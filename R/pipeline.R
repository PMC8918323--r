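#' @keywords internal
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Vectorized ASSIST totals over a records table
#'
#' Sums the scored-item weights across columns `<prefix>item2` ...
#' `<prefix>item7` of a records table; rows with a missing or unknown
#' selection get `NA` (they are routed to the baseline-incomplete exit by
#' [run_flow()], never scored partially).
#'
#' @param instrument an `assist_instrument`.
#' @param records data.frame.
#' @param prefix `"scr_"` or `"bl_"`.
#' @return integer vector of totals (NA where incomplete).
#' @export
score_responses <- function(instrument, records, prefix = "scr_") {
  ids <- scored_items(instrument)
  total <- rep(0L, nrow(records))
  for (id in ids) {
    it <- get_item(instrument, id)
    labels <- as.character(records[[paste0(prefix, "item", id)]])
    total <- total + unname(it$weights[labels])
  }
  as.integer(total)
}

exit_stages <- c("ineligible_age", "ineligible_never_used",
                 "ineligible_low_score", "no_consent", "duplicate_excluded",
                 "withdrew", "baseline_incomplete")

#' Consort-flow table
#'
#' A conserving stage-count table for the two-stage recruitment flow. The
#' constructor enforces conservation: every screener completer is accounted
#' for by exactly one exit or by the consistency assessment, and the
#' assessment splits exactly into screened out and screened in.
#'
#' @param counts named numeric vector or list with entries
#'   `screener_completed`, the seven exit stages (`ineligible_age`,
#'   `ineligible_never_used`, `ineligible_low_score`, `no_consent`,
#'   `duplicate_excluded`, `withdrew`, `baseline_incomplete`),
#'   `consistency_assessed`, `screened_out`, `screened_in`.
#' @return object of class `consort_table`.
#' @export
consort_table <- function(counts) {
  counts <- unlist(counts)
  stages <- c("screener_completed", exit_stages, "consistency_assessed",
              "screened_out", "screened_in")
  missing <- setdiff(stages, names(counts))
  if (length(missing))
    stop("missing consort stages: ", paste(missing, collapse = ", "),
         call. = FALSE)
  counts <- counts[stages]
  if (any(counts < 0))
    stop("accounting error: negative stage count", call. = FALSE)
  if (counts["screener_completed"] !=
      sum(counts[exit_stages]) + counts["consistency_assessed"])
    stop("accounting error: exits + assessed do not conserve screener count",
         call. = FALSE)
  if (counts["consistency_assessed"] !=
      counts["screened_out"] + counts["screened_in"])
    stop("accounting error: screened_out + screened_in != assessed",
         call. = FALSE)
  structure(as.list(as.integer(counts)) |>
              stats::setNames(stages), class = "consort_table")
}

#' Replay a consort flow from aggregate stage exits
#'
#' Aggregate-replay mode of the recruitment flow: given per-stage exit counts
#' (as printed in a consort chart), derives the number of assessable cases
#' and the in/out split, with full conservation checking. This lets printed
#' recruitment flows be verified without record-level data.
#'
#' @param completed screener completers entering the flow.
#' @param ineligible_age,ineligible_never_used,ineligible_low_score
#'   eligibility exits (tested in this order; each person counted once).
#' @param no_consent consent-stage exits.
#' @param duplicate_excluded duplicate-enrolment exclusions.
#' @param withdrew voluntary withdrawals.
#' @param baseline_incomplete did not complete the second administration.
#' @param screened_out consistency-stage exclusions (default 0).
#' @return a [consort_table()].
#' @examples
#' ct <- replay_consort(4452, 19, 60, 220, 2304, 207, 6, 255,
#'                      screened_out = 626)
#' ct$consistency_assessed
#' @export
replay_consort <- function(completed, ineligible_age, ineligible_never_used,
                           ineligible_low_score, no_consent,
                           duplicate_excluded, withdrew, baseline_incomplete,
                           screened_out = 0L) {
  exits <- c(ineligible_age = ineligible_age,
             ineligible_never_used = ineligible_never_used,
             ineligible_low_score = ineligible_low_score,
             no_consent = no_consent,
             duplicate_excluded = duplicate_excluded,
             withdrew = withdrew,
             baseline_incomplete = baseline_incomplete)
  assessed <- completed - sum(exits)
  consort_table(c(screener_completed = completed, exits,
                  consistency_assessed = assessed,
                  screened_out = screened_out,
                  screened_in = assessed - screened_out))
}

#' Eligibility decision for one respondent
#'
#' Applies the three eligibility criteria in a fixed order — age at least 18,
#' cannabis use in the previous three months, ASSIST screener total at least
#' the moderate-risk minimum — and returns the first failed criterion, so a
#' respondent failing several is attributed to exactly one exit (consort
#' counts stay single-count-per-person).
#'
#' @param record one-row data.frame with `age`, `used_cannabis` and screener
#'   selections `scr_item2` ... `scr_item7`.
#' @param instrument an `assist_instrument`.
#' @return `"eligible"`, `"ineligible_age"`, `"ineligible_never_used"` or
#'   `"ineligible_low_score"`.
#' @export
eligibility_check <- function(record, instrument = assist_instrument()) {
  if (is.null(record$age) || is.null(record$scr_item2))
    stop("malformed record: missing age or screener response", call. = FALSE)
  if (record$age < 18) return("ineligible_age")
  if (!isTRUE(as.logical(record$used_cannabis)))
    return("ineligible_never_used")
  total <- score_responses(instrument, record, "scr_")
  if (is.na(total))
    stop("malformed record: incomplete screener", call. = FALSE)
  if (total < instrument$thresholds$min_total)
    return("ineligible_low_score")
  "eligible"
}

#' Run records through the two-stage recruitment flow
#'
#' Routes every record through screener eligibility, consent, duplicate
#' exclusion, withdrawal, baseline completion and — for those who survive —
#' the consistency assessment, assigning exactly one terminal stage per
#' record and maintaining a conserving [consort_table()].
#'
#' Stage order per record: `ineligible_age` / `ineligible_never_used` /
#' `ineligible_low_score` (first failure wins), then `no_consent`,
#' `duplicate_excluded`, `withdrew`, `baseline_incomplete` (a missing or
#' partial baseline, including missing usage probes, exits here — partial
#' responses are never scored), then `screened_out` / `screened_in` from
#' [evaluate_pair()].
#'
#' For replaying printed aggregate exits without record-level data, see
#' [replay_consort()].
#'
#' @param records data.frame following [records_schema()]; ids must be
#'   unique.
#' @param instrument an `assist_instrument`.
#' @param ... threshold overrides passed to [screen_cohort()].
#' @return list with `records` (input plus a `terminal_stage` column),
#'   `reports` (check matrix for assessed records; `NULL` if none), and
#'   `consort` (a `consort_table`).
#' @export
run_flow <- function(records, instrument = assist_instrument(), ...) {
  if (anyDuplicated(records$id))
    stop("integrity error: duplicate record ids", call. = FALSE)

  n <- nrow(records)
  stage <- rep(NA_character_, n)

  scr_total <- score_responses(instrument, records, "scr_")
  if (anyNA(scr_total))
    stop("malformed record: incomplete screener response", call. = FALSE)

  stage[records$age < 18] <- "ineligible_age"
  stage[is.na(stage) & !records$used_cannabis] <- "ineligible_never_used"
  stage[is.na(stage) & scr_total < instrument$thresholds$min_total] <-
    "ineligible_low_score"
  stage[is.na(stage) & !records$consented] <- "no_consent"
  stage[is.na(stage) & records$duplicate] <- "duplicate_excluded"
  stage[is.na(stage) & records$withdrew] <- "withdrew"

  ids <- scored_items(instrument)
  bl_cols <- c(paste0("bl_item", ids), "usage_pattern",
               "usage_times_weekday", "usage_times_weekend", "usage_hours")
  bl_missing <- !records$baseline_complete |
    Reduce(`|`, lapply(bl_cols, function(cl) is.na(records[[cl]])))
  stage[is.na(stage) & bl_missing] <- "baseline_incomplete"

  assess <- is.na(stage)
  reports <- NULL
  if (any(assess)) {
    reports <- screen_cohort(records[assess, , drop = FALSE], instrument, ...)
    stage[assess] <- reports$decision
  }

  records$terminal_stage <- stage
  tab <- table(factor(stage, levels = c(exit_stages, "screened_out",
                                        "screened_in")))
  counts <- c(screener_completed = n, as.list(tab),
              consistency_assessed = sum(assess))
  list(records = records, reports = reports,
       consort = consort_table(unlist(counts)))
}

#' Summarize a consort table
#'
#' Reports the stage counts and the share of assessable cases that were
#' screened out, rounded half-up to one decimal (reporting convention for
#' percentages throughout the package).
#'
#' @param table a [consort_table()].
#' @return list with `counts` (named integer vector) and
#'   `screened_out_pct`; printed as a flow report.
#' @examples
#' consort_summary(replay_consort(4452, 19, 60, 220, 2304, 207, 6, 255,
#'                                screened_out = 626))
#' @export
consort_summary <- function(table) {
  stopifnot(inherits(table, "consort_table"))
  pct <- if (table$consistency_assessed > 0)
    round_half_up(100 * table$screened_out / table$consistency_assessed, 1)
  else NA_real_
  structure(list(counts = unlist(table), screened_out_pct = pct),
            class = "consort_summary")
}

#' @export
print.consort_summary <- function(x, ...) {
  cnt <- x$counts
  cat("Recruitment flow\n")
  cat(sprintf("  completed screener      %6d\n", cnt["screener_completed"]))
  cat(sprintf("  ineligible (age/use/score) %3d + %d + %d = %d\n",
              cnt["ineligible_age"], cnt["ineligible_never_used"],
              cnt["ineligible_low_score"],
              cnt["ineligible_age"] + cnt["ineligible_never_used"] +
                cnt["ineligible_low_score"]))
  for (s in c("no_consent", "duplicate_excluded", "withdrew",
              "baseline_incomplete"))
    cat(sprintf("  %-22s %6d\n", s, cnt[s]))
  cat(sprintf("  consistency assessed    %6d\n", cnt["consistency_assessed"]))
  cat(sprintf("  screened out            %6d (%.1f%%)\n",
              cnt["screened_out"], x$screened_out_pct))
  cat(sprintf("  screened in             %6d\n", cnt["screened_in"]))
  invisible(x)
}

#' @export
print.consort_table <- function(x, ...) {
  print(consort_summary(x))
  invisible(x)
}
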