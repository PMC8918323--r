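test_that("the catalogue enumerates 11 checks in families of 2/5/4", {
  cat_ <- check_catalogue()
  expect_identical(nrow(cat_), 11L)
  expect_identical(anyDuplicated(cat_$check), 0L)
  fam <- table(cat_$family)
  expect_identical(as.integer(fam[c("total_score", "item_regression",
                                    "usage_report")]), c(2L, 5L, 4L))
})

test_that("baseline-total minimum fires strictly below the threshold", {
  expect_true(check_total_below_min(3)$fired)
  expect_false(check_total_below_min(4)$fired)
  expect_true(check_total_below_min(0)$fired)
})

test_that("total-delta check is strict at the bound and symmetric", {
  expect_true(check_total_delta(19, 30)$fired)    # +11
  expect_true(check_total_delta(30, 19)$fired)    # -11
  expect_false(check_total_delta(19, 29)$fired)   # exactly 10 passes
  for (a in seq(0, 39, by = 3)) for (b in seq(0, 39, by = 3))
    expect_identical(check_total_delta(a, b)$fired,
                     check_total_delta(b, a)$fired)
})

test_that("item regression fires only on endorsed-to-never changes", {
  instr <- the_instrument
  expect_true(check_item_regression(instr, 4, "Monthly", "Never")$fired)
  expect_false(check_item_regression(instr, 4, "Never", "Never")$fired)
  expect_false(check_item_regression(instr, 3, "Weekly", "Monthly")$fired)
  expect_true(check_item_regression(instr, 6, "Yes, in the past 3 months",
                                    "No, never")$fired)
  expect_error(check_item_regression(instr, 2, "Weekly", "Never"),
               "items 3-7")
  expect_error(check_item_regression(instr, 4, "Wekly", "Never"),
               "unknown option")
})

test_that("each usage probe fires independently (all 16 probe patterns)", {
  instr <- the_instrument
  for (bits in 0:15) {
    deny <- as.logical(bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0)
    res <- check_usage_report(
      instr,
      baseline_item2 = if (deny[1]) "Never" else "Weekly",
      pattern = if (deny[2]) "I do not use cannabis" else "Weekends only",
      times_weekday = if (deny[3]) 0L else 2L,
      times_weekend = if (deny[3]) 0L else 1L,
      hours = if (deny[4]) "I do not use cannabis" else "Within 1 hour")
    expect_identical(
      res$fired[match(c("USE_ITEM2_NEVER", "USE_PATTERN_NONE",
                        "USE_TIMES_ZERO", "USE_HOURS_NONE"), res$check)],
      deny, label = paste("probe pattern", bits))
  }
  # zero on one day only is not a denial of use
  expect_false(check_usage_report(instr, "Weekly", "Weekends only",
                                  0L, 3L, "Within 1 hour")$fired[3])
  expect_error(check_usage_report(instr, "Weekly", "sometimes", 1L, 1L,
                                  "Within 1 hour"), "unknown usage-pattern")
})

test_that("a perfectly repeated eligible administration fires nothing", {
  r <- moderate_response()
  rep_ <- evaluate_pair(r, r, usage_using(), the_instrument)
  expect_identical(rep_$n_fired, 0L)
  expect_identical(rep_$decision, "screened_in")
  expect_identical(nrow(rep_$results), 11L)
  expect_identical(rep_$families_fired, character(0))
})

test_that("a single item-4 regression fires exactly its own check", {
  scr <- moderate_response()
  scr[["item4"]] <- "Monthly"           # endorsed at screener, total 24
  bl <- scr
  bl[["item4"]] <- "Never"              # total 19: delta 5, above minimum
  rep_ <- evaluate_pair(scr, bl, usage_using(), the_instrument)
  expect_identical(rep_$results$check[rep_$results$fired], "ITEM4_TO_NEVER")
  expect_identical(rep_$n_fired, 1L)
  expect_identical(rep_$decision, "screened_out")
  expect_identical(rep_$families_fired, "item_regression")
})

test_that("an all-never baseline fires every applicable predicate", {
  scr <- moderate_response()            # total 23, items 2,3,4,6,7 endorsed
  bl <- response_from_ordinals(the_instrument, 0)
  rep_ <- evaluate_pair(scr, bl, usage_denying(), the_instrument)
  fired <- rep_$results$check[rep_$results$fired]
  expect_setequal(fired, c("TOTAL_BELOW_MIN", "TOTAL_DELTA_GT10",
                           "ITEM3_TO_NEVER", "ITEM4_TO_NEVER",
                           "ITEM6_TO_NEVER", "ITEM7_TO_NEVER",
                           "USE_ITEM2_NEVER", "USE_PATTERN_NONE",
                           "USE_TIMES_ZERO", "USE_HOURS_NONE"))
  # item 5 was "Never" at screener: nothing was endorsed, no regression
  expect_false("ITEM5_TO_NEVER" %in% fired)
  expect_identical(sort(rep_$families_fired),
                   c("item_regression", "total_score", "usage_report"))
})

test_that("evaluate_pair is deterministic and complete", {
  scr <- moderate_response()
  bl <- scr
  bl[["item3"]] <- "Never"
  a <- evaluate_pair(scr, bl, usage_using(), the_instrument)
  b <- evaluate_pair(scr, bl, usage_using(), the_instrument)
  expect_identical(a$results, b$results)
  expect_identical(a$decision, b$decision)
  expect_identical(sort(a$results$check), sort(check_catalogue()$check))
})

test_that("decision threshold is configurable away from any-one-check", {
  scr <- moderate_response()
  bl <- scr
  bl[["item4"]] <- "Never"              # exactly one check fires
  strict <- evaluate_pair(scr, bl, usage_using(), the_instrument)
  lenient <- evaluate_pair(scr, bl, usage_using(), the_instrument,
                           decision_threshold = 2)
  expect_identical(strict$decision, "screened_out")
  expect_identical(lenient$decision, "screened_in")
})

test_that("reduced-instrument decisions match exhaustive enumeration", {
  red <- subset_instrument(the_instrument, c(2, 5))
  w2 <- red$items$item2$weights[red$items$item2$options]
  w5 <- red$items$item5$weights[red$items$item5$options]
  grid <- expand.grid(o2 = 0:4, o5 = 0:4)
  grid$total <- w2[grid$o2 + 1] + w5[grid$o5 + 1]
  elig <- grid[grid$total >= 4, ]

  n_flagged <- 0L
  n_pairs <- 0L
  for (i in seq_len(nrow(elig))) for (j in seq_len(nrow(grid))) {
    scr <- response_from_ordinals(red, c(elig$o2[i], elig$o5[i]))
    bl <- response_from_ordinals(red, c(grid$o2[j], grid$o5[j]))
    rep_ <- evaluate_pair(scr, bl, usage = list(), instrument = red)
    # independent predicate evaluation, straight from the rule definitions
    expected <- grid$total[j] < 4 ||
      abs(grid$total[j] - elig$total[i]) > 10 ||
      (elig$o5[i] > 0 && grid$o5[j] == 0) ||
      grid$o2[j] == 0
    expect_identical(rep_$decision == "screened_out", expected,
                     label = sprintf("pair (%d,%d)x(%d,%d)", elig$o2[i],
                                     elig$o5[i], grid$o2[j], grid$o5[j]))
    n_flagged <- n_flagged + (rep_$decision == "screened_out")
    n_pairs <- n_pairs + 1L
  }
  oracle <- random_flag_oracle(red, "exhaustive", usage = "item2")
  expect_identical(oracle$n, n_pairs)
  expect_equal(oracle$probability, n_flagged / n_pairs)
})

test_that("count distribution tallies screened-out reports only", {
  df <- fated_cohort(8)
  checks <- screen_cohort(df[c(1, 2, 4, 5), ], the_instrument)
  # identical pairs fire nothing: the screened-out map is empty
  expect_length(count_distribution(checks), 0)
  expect_error(count_distribution(checks[0, ]), "empty")

  df2 <- rbind(consistent_record("A"), consistent_record("B"),
               consistent_record("C"))
  df2$bl_item4[2] <- "Never"
  df2$bl_item4[3] <- "Never"
  checks2 <- screen_cohort(df2, the_instrument)
  expect_identical(count_distribution(checks2), c("1" = 2L))
})

test_that("fired counts agree with a naive per-report recount", {
  coh <- generate_cohort(population_spec(n = 120, seed = 9))
  flow <- run_flow(coh$records)
  checks <- flow$reports
  ids_ <- check_catalogue()$check
  recount <- rowSums(as.matrix(checks[, ids_]))
  expect_identical(as.integer(checks$n_fired), as.integer(recount))
  expect_identical(count_distribution(checks),
                   {
                     t <- table(recount[checks$decision == "screened_out"])
                     stats::setNames(as.integer(t), names(t))
                   })
})
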