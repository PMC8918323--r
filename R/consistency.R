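#' Catalogue of the eleven atomic consistency checks
#'
#' The rule engine compares the screener and baseline administrations of the
#' ASSIST cannabis subscale with eleven atomic checks in three families:
#'
#' * `total_score` (2 checks): baseline total dropped below the moderate-risk
#'   minimum; total changed by more than the allowed bound in either
#'   direction.
#' * `item_regression` (5 checks): items 3--7 changed from endorsed at
#'   screener to "never" at baseline.
#' * `usage_report` (4 checks): the baseline denies cannabis use outright —
#'   on ASSIST item 2, on the weekly-pattern probe, on times-per-day (zero on
#'   both weekday and weekend), or on the hours-after-waking probe.
#'
#' Item 2 regressing to "Never" is classified in the `usage_report` family
#' (it is a denial of use, not a symptom-item regression), so the
#' `item_regression` family covers items 3--7 only.
#'
#' @return data.frame with columns `check`, `family`, `label` (11 rows).
#' @export
check_catalogue <- function() {
  data.frame(
    check = c("TOTAL_BELOW_MIN", "TOTAL_DELTA_GT10",
              "ITEM3_TO_NEVER", "ITEM4_TO_NEVER", "ITEM5_TO_NEVER",
              "ITEM6_TO_NEVER", "ITEM7_TO_NEVER",
              "USE_ITEM2_NEVER", "USE_PATTERN_NONE", "USE_TIMES_ZERO",
              "USE_HOURS_NONE"),
    family = c("total_score", "total_score",
               rep("item_regression", 5), rep("usage_report", 4)),
    label = c(
      "Baseline total score below eligibility minimum",
      "Difference in total score of more than the allowed bound",
      "Item 3 (strong desire or urge to use) changed to never",
      "Item 4 (use led to health, social, legal, or financial problems) changed to never",
      "Item 5 (failed to do what was normally expected) changed to never",
      "Item 6 (anyone ever expressed concern) changed to never",
      "Item 7 (ever tried to control, cut down or stop) changed to never",
      "Baseline ASSIST item 2 reports never using cannabis",
      "Weekly usage pattern reports no cannabis use",
      "Zero times per day on both weekday and weekend",
      "Hours-after-waking probe reports no cannabis use"),
    stringsAsFactors = FALSE)
}

.pkg_cache <- new.env(parent = emptyenv())

catalogue_cached <- function() {
  if (is.null(.pkg_cache$cat)) .pkg_cache$cat <- check_catalogue()
  .pkg_cache$cat
}

check_result <- function(check, fired, screener_value = NA,
                         baseline_value = NA, applicable = TRUE) {
  cat_ <- catalogue_cached()
  data.frame(check = check,
             family = cat_$family[match(check, cat_$check)],
             applicable = applicable,
             fired = fired & applicable,
             screener_value = as.character(screener_value),
             baseline_value = as.character(baseline_value),
             stringsAsFactors = FALSE)
}

#' Check: baseline total below the eligibility minimum
#'
#' Fires when the second-administration total falls below the moderate-risk
#' minimum (default 4) that eligibility required at screening.
#'
#' @param baseline_total integer baseline total.
#' @param min_total eligibility minimum (default 4).
#' @return one-row check-result data.frame.
#' @export
check_total_below_min <- function(baseline_total, min_total = 4L) {
  check_result("TOTAL_BELOW_MIN", baseline_total < min_total,
               NA, baseline_total)
}

#' Check: total score changed by more than the allowed bound
#'
#' Symmetric and strict: fires when `|baseline - screener|` strictly exceeds
#' `delta_bound` (default 10); a change of exactly 10 points passes.
#'
#' @param screener_total,baseline_total integer totals.
#' @param delta_bound allowed absolute change (default 10).
#' @return one-row check-result data.frame.
#' @export
check_total_delta <- function(screener_total, baseline_total,
                              delta_bound = 10L) {
  check_result("TOTAL_DELTA_GT10",
               abs(baseline_total - screener_total) > delta_bound,
               screener_total, baseline_total)
}

#' Check: an endorsed item regressed to "never" at baseline
#'
#' Fires when the screener selection was endorsed (any option other than the
#' first-listed "Never"/"No, never") and the baseline selection is the
#' "never" option. A mere reduction (e.g. "Weekly" to "Monthly") does not
#' fire. Only items 3--7 belong to this family; item 2 regressing to "Never"
#' is a usage-report check.
#'
#' @param instrument an `assist_instrument`.
#' @param item_id integer in 3..7.
#' @param screener_option,baseline_option option labels for that item.
#' @return one-row check-result data.frame.
#' @export
check_item_regression <- function(instrument, item_id, screener_option,
                                  baseline_option) {
  item_id <- as.integer(item_id)
  if (!item_id %in% 3:7)
    stop("item regression checks cover items 3-7 only (item 2 denial of use",
         " is a usage-report check)", call. = FALSE)
  so <- ordinal_of(instrument, item_id, screener_option)
  bo <- ordinal_of(instrument, item_id, baseline_option)
  if (anyNA(c(so, bo)))
    stop("unknown option for item ", item_id, call. = FALSE)
  check_result(paste0("ITEM", item_id, "_TO_NEVER"),
               so > 0L && bo == 0L, screener_option, baseline_option)
}

#' Checks: baseline denial of cannabis use
#'
#' Evaluates the four usage-report probes. Each fires independently when its
#' answer denotes non-use: ASSIST item 2 = "Never"; the weekly-pattern probe
#' at its declared non-use option; zero times per day on both weekday and
#' weekend; the hours-after-waking probe at its declared non-use option.
#' Probes passed as `NULL` are marked not applicable (reduced instruments).
#'
#' @param instrument an `assist_instrument`.
#' @param baseline_item2 baseline item-2 option label, or `NULL`.
#' @param pattern weekly-pattern answer, or `NULL`.
#' @param times_weekday,times_weekend times-per-day answers, or `NULL`.
#' @param hours hours-after-waking answer, or `NULL`.
#' @return four-row check-result data.frame.
#' @export
check_usage_report <- function(instrument, baseline_item2 = NULL,
                               pattern = NULL, times_weekday = NULL,
                               times_weekend = NULL, hours = NULL) {
  probes <- instrument$usage_probes
  rows <- list()

  if (is.null(baseline_item2)) {
    rows$item2 <- check_result("USE_ITEM2_NEVER", FALSE, applicable = FALSE)
  } else {
    o <- ordinal_of(instrument, 2, baseline_item2)
    if (is.na(o)) stop("unknown option for item 2", call. = FALSE)
    rows$item2 <- check_result("USE_ITEM2_NEVER", o == 0L, NA, baseline_item2)
  }

  if (is.null(pattern)) {
    rows$pattern <- check_result("USE_PATTERN_NONE", FALSE, applicable = FALSE)
  } else {
    if (!pattern %in% probes$pattern$options)
      stop("unknown usage-pattern answer ", sQuote(pattern), call. = FALSE)
    rows$pattern <- check_result("USE_PATTERN_NONE",
                                 pattern == probes$pattern$nonuse, NA, pattern)
  }

  if (is.null(times_weekday) || is.null(times_weekend)) {
    rows$times <- check_result("USE_TIMES_ZERO", FALSE, applicable = FALSE)
  } else {
    rows$times <- check_result(
      "USE_TIMES_ZERO", times_weekday == 0 && times_weekend == 0,
      NA, paste0(times_weekday, "/", times_weekend))
  }

  if (is.null(hours)) {
    rows$hours <- check_result("USE_HOURS_NONE", FALSE, applicable = FALSE)
  } else {
    if (!hours %in% probes$hours$options)
      stop("unknown hours-after-waking answer ", sQuote(hours), call. = FALSE)
    rows$hours <- check_result("USE_HOURS_NONE",
                               hours == probes$hours$nonuse, NA, hours)
  }

  do.call(rbind, unname(rows))
}

#' Evaluate all consistency checks on one screener/baseline pair
#'
#' Runs every applicable check of the eleven-check catalogue on a pair of
#' administrations and returns a complete report: one result per catalogue
#' check (non-applicable checks are recorded unfired), the number fired, the
#' families involved, and the screen-in/screen-out decision. The engine never
#' short-circuits: all fired checks are reported, which is what makes
#' per-check frequency tables and the fired-count distribution meaningful.
#'
#' The decision is `screened_out` when at least `decision_threshold` checks
#' fired (default 1, i.e. any single inconsistency screens the respondent
#' out).
#'
#' @param screener,baseline named option-label vectors (see [total_score()]).
#' @param usage list with elements `pattern`, `times_weekday`,
#'   `times_weekend`, `hours`, or `NULL` when the usage probes were not
#'   administered. An empty list enables only the item-2 denial check.
#' @param instrument an `assist_instrument`.
#' @param participant_id optional identifier carried into the report.
#' @param min_total,delta_bound,decision_threshold threshold overrides;
#'   default to the instrument's declared thresholds.
#' @return object of class `consistency_report`: a list with
#'   `participant_id`, `results` (11-row data.frame), `screener_total`,
#'   `baseline_total`, `n_fired`, `families_fired`, `decision`.
#' @examples
#' instr <- assist_instrument()
#' scr <- response_from_ordinals(instr, c(3, 1, 1, 0, 1, 1))
#' evaluate_pair(scr, scr, usage = list(pattern = "Most or every day",
#'   times_weekday = 2, times_weekend = 3, hours = "Within 1 hour"),
#'   instrument = instr)$decision
#' @export
evaluate_pair <- function(screener, baseline, usage = NULL,
                          instrument = assist_instrument(),
                          participant_id = NA_character_,
                          min_total = NULL, delta_bound = NULL,
                          decision_threshold = NULL) {
  thr <- instrument$thresholds
  min_total <- if (is.null(min_total)) thr$min_total else min_total
  delta_bound <- if (is.null(delta_bound)) thr$delta_bound else delta_bound
  decision_threshold <- if (is.null(decision_threshold))
    thr$decision_threshold else decision_threshold

  st <- total_score(instrument, screener)
  bt <- total_score(instrument, baseline)
  ids <- scored_items(instrument)

  rows <- list(check_total_below_min(bt, min_total),
               check_total_delta(st, bt, delta_bound))
  for (id in 3:7) {
    key <- paste0("item", id)
    if (id %in% ids) {
      rows[[key]] <- check_item_regression(instrument, id,
                                           screener[[key]], baseline[[key]])
    } else {
      rows[[key]] <- check_result(paste0("ITEM", id, "_TO_NEVER"), FALSE,
                                  applicable = FALSE)
    }
  }
  if (is.null(usage)) {
    rows$usage <- check_usage_report(instrument)
  } else {
    rows$usage <- check_usage_report(
      instrument,
      baseline_item2 = if (2L %in% ids) baseline[["item2"]],
      pattern = usage$pattern,
      times_weekday = usage$times_weekday,
      times_weekend = usage$times_weekend,
      hours = usage$hours)
  }

  results <- do.call(rbind, unname(rows))
  results <- results[match(catalogue_cached()$check, results$check), ]
  rownames(results) <- NULL
  n_fired <- sum(results$fired)

  structure(
    list(participant_id = participant_id,
         results = results,
         screener_total = st, baseline_total = bt,
         n_fired = n_fired,
         families_fired = unique(results$family[results$fired]),
         decision = if (n_fired >= decision_threshold) "screened_out"
                    else "screened_in"),
    class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("consistency report%s: totals %d -> %d, %d check(s) fired, %s\n",
              if (is.na(x$participant_id)) "" else
                paste0(" [", x$participant_id, "]"),
              x$screener_total, x$baseline_total, x$n_fired, x$decision))
  if (x$n_fired > 0) {
    f <- x$results[x$results$fired, c("check", "screener_value",
                                      "baseline_value")]
    print(f, row.names = FALSE)
  }
  invisible(x)
}

#' Screen a cohort of paired administrations
#'
#' Vectorized front end to [evaluate_pair()] over a records table. Records
#' must carry screener selections in columns `scr_item2` ... `scr_item7`,
#' baseline selections in `bl_item2` ... `bl_item7`, and the usage probes in
#' `usage_pattern`, `usage_times_weekday`, `usage_times_weekend`,
#' `usage_hours` (see [records_schema()]).
#'
#' @param records data.frame of assessable records (one row per respondent).
#' @param instrument an `assist_instrument`.
#' @param ... threshold overrides passed to [evaluate_pair()].
#' @return a check matrix: data.frame with `id`, one logical column per
#'   catalogue check, `screener_total`, `baseline_total`, `n_fired`,
#'   `decision`.
#' @export
screen_cohort <- function(records, instrument = assist_instrument(), ...) {
  checks <- check_catalogue()$check
  ids <- scored_items(instrument)
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    scr <- stats::setNames(unlist(r[paste0("scr_item", ids)]),
                           paste0("item", ids))
    bl <- stats::setNames(unlist(r[paste0("bl_item", ids)]),
                          paste0("item", ids))
    usage <- list(pattern = r$usage_pattern,
                  times_weekday = r$usage_times_weekday,
                  times_weekend = r$usage_times_weekend,
                  hours = r$usage_hours)
    rep_ <- evaluate_pair(scr, bl, usage, instrument,
                          participant_id = as.character(r$id), ...)
    out[[i]] <- c(list(id = r$id),
                  stats::setNames(as.list(rep_$results$fired), checks),
                  list(screener_total = rep_$screener_total,
                       baseline_total = rep_$baseline_total,
                       n_fired = rep_$n_fired, decision = rep_$decision))
  }
  do.call(rbind, lapply(out, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
}

#' Distribution of fired-check counts among screened-out respondents
#'
#' Tallies, over the screened-out respondents only, how many atomic checks
#' fired per respondent — the granularity at which multi-reason exclusions
#' are reported (e.g. what share of exclusions rested on a single data
#' issue).
#'
#' @param reports a check matrix from [screen_cohort()], or a list of
#'   `consistency_report` objects.
#' @return named integer vector mapping fired-count to frequency.
#' @export
count_distribution <- function(reports) {
  if (inherits(reports, "consistency_report")) reports <- list(reports)
  if (is.data.frame(reports)) {
    if (nrow(reports) == 0) stop("empty report collection", call. = FALSE)
    n_fired <- reports$n_fired[reports$decision == "screened_out"]
  } else {
    if (length(reports) == 0) stop("empty report collection", call. = FALSE)
    n_fired <- vapply(reports, function(r) r$n_fired, numeric(1))
    dec <- vapply(reports, function(r) r$decision, character(1))
    n_fired <- n_fired[dec == "screened_out"]
  }
  tab <- table(n_fired)
  stats::setNames(as.integer(tab), names(tab))
}
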