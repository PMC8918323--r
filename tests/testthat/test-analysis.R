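test_that("cohen_kappa agrees with an independent implementation", {
  set.seed(31)
  for (rep in 1:5) {
    x <- sample(0:4, 300, replace = TRUE)
    y <- ifelse(runif(300) < 0.6, x, sample(0:4, 300, replace = TRUE))
    ref <- e1071::classAgreement(table(factor(x, 0:4),
                                       factor(y, 0:4)))$kappa
    expect_equal(cohen_kappa(x, y), ref, tolerance = 1e-12)
  }
})

test_that("summary t-test matches t.test on moment-matched samples", {
  # exact-moment samples: scale a fixed vector to the target mean and sd
  mk <- function(n, m, s) {
    z <- scale(seq_len(n))
    as.numeric(m + s * z)
  }
  a <- mk(40, 12.3, 4.1)
  b <- mk(55, 10.9, 5.6)
  ours <- summary_ttest(12.3, 4.1, 40, 10.9, 5.6, 55)
  ref <- t.test(a, b)
  expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)

  pooled <- summary_ttest(12.3, 4.1, 40, 10.9, 5.6, 55, pooled = TRUE)
  refp <- t.test(a, b, var.equal = TRUE)
  expect_equal(pooled$statistic, unname(refp$statistic), tolerance = 1e-9)

  same <- summary_ttest(10, 2, 30, 10, 2, 30)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)

  expect_error(summary_ttest(1, 0, 10, 2, 1, 10), "positive sds")
  expect_error(summary_ttest(1, 1, 1, 2, 1, 10), "at least 2")
})

test_that("published group-comparison cells reproduce their significance", {
  # age: 39.5 (13.9) n=626 vs 35.7 (12.9) n=755
  age <- summary_ttest(39.5, 13.9, 626, 35.7, 12.9, 755)
  expect_lt(age$p_value, 0.001)
  # screener ASSIST 19.3 (8.0) vs 23.8 (10.4); baseline 17.5 (7.9) vs 23.3 (10.3)
  expect_lt(summary_ttest(19.3, 8.0, 626, 23.8, 10.4, 755)$p_value, 0.001)
  expect_lt(summary_ttest(17.5, 7.9, 626, 23.3, 10.3, 755)$p_value, 0.001)
  # days of use 23.3 (9.7) vs 24.8 (11.3): significant at the 0.01 level
  days <- summary_ttest(23.3, 9.7, 626, 24.8, 11.3, 755)
  expect_lt(days$p_value, 0.01)
  expect_gt(days$p_value, 0.001)

  # income row from its 2x2 counts: 365/626 vs 400/755, uncorrected
  g <- rep(c(TRUE, FALSE), c(626, 755))
  x <- c(rep(c(TRUE, FALSE), c(365, 626 - 365)),
         rep(c(TRUE, FALSE), c(400, 755 - 400)))
  row <- compare_groups(data.frame(income_low = x), g,
                        categorical = "income_low")
  expect_identical(round(row$p_value, 3), 0.047)
})

test_that("compare_groups formats both variable kinds and flags degeneracy", {
  set.seed(41)
  df <- data.frame(male = runif(80) < 0.4, age = rnorm(80, 35, 10),
                   flat = rep(5, 80))
  g <- rep(c(TRUE, FALSE), 40)
  out <- compare_groups(df, g, categorical = "male",
                        continuous = c("age", "flat"))
  expect_identical(out$test_kind, c("chi_square", "two_sample_t",
                                    "two_sample_t"))
  expect_true(all(out$p_value <= 1 | is.na(out$p_value)))
  expect_match(out$note[out$variable == "flat"], "zero variance")
  expect_true(is.na(out$statistic[out$variable == "flat"]))

  # identical proportions give statistic 0, p = 1
  df2 <- data.frame(v = c(rep(c(TRUE, FALSE), 25), rep(c(TRUE, FALSE), 25)))
  g2 <- rep(c(TRUE, FALSE), each = 50)
  row <- compare_groups(df2, g2, categorical = "v")
  expect_equal(row$statistic, 0)
  expect_equal(row$p_value, 1)

  expect_error(compare_groups(df, rep(TRUE, 80), categorical = "male"),
               "degenerate")
})

test_that("inconsistency table counts checks and unions per family", {
  base <- consistent_record("Z0")
  rows <- do.call(rbind, lapply(1:50, function(i) {
    r <- consistent_record(sprintf("Z%02d", i))
    if (i <= 10) r$bl_item4 <- "Never"          # 10 item-4 regressions
    if (i %in% 6:15) r$bl_item3 <- "Never"      # overlap on 6..10
    r
  }))
  checks <- screen_cohort(rows, the_instrument)
  tab <- inconsistency_table(checks)
  n_out <- attr(tab, "n_screened_out")
  expect_identical(n_out, 15L)
  expect_identical(tab$n[tab$check == "ITEM4_TO_NEVER"], 10L)
  expect_identical(tab$n[tab$check == "ITEM3_TO_NEVER"], 10L)
  # union, not sum: 15 distinct respondents, member counts total 20
  expect_identical(tab$n[tab$check == "ANY_ITEM_REGRESSION"], 15L)
  expect_identical(tab$pct[tab$check == "ITEM4_TO_NEVER"],
                   round(100 * 10 / 15, 1))
})

test_that("family union rows never exceed the sum of their members", {
  coh <- generate_cohort(population_spec(n = 150, seed = 23))
  flow <- run_flow(coh$records)
  tab <- inconsistency_table(flow$reports)
  cat_ <- check_catalogue()
  for (fam in unique(cat_$family)) {
    members <- cat_$check[cat_$family == fam]
    any_n <- tab$n[tab$check == paste0("ANY_", toupper(fam))]
    expect_lte(any_n, sum(tab$n[tab$check %in% members]))
    expect_gte(any_n, max(tab$n[tab$check %in% members]))
  }
})

test_that("printed-count replay reproduces a published frequency table", {
  tab <- inconsistency_table_from_counts(
    check_counts = c(TOTAL_BELOW_MIN = 16, TOTAL_DELTA_GT10 = 71,
                     ITEM3_TO_NEVER = 128, ITEM4_TO_NEVER = 215,
                     ITEM5_TO_NEVER = 209, ITEM6_TO_NEVER = 151,
                     ITEM7_TO_NEVER = 177,
                     USE_ITEM2_NEVER = 6, USE_PATTERN_NONE = 14,
                     USE_TIMES_ZERO = 13, USE_HOURS_NONE = 15),
    any_counts = c(total_score = 86, item_regression = 613,
                   usage_report = 20),
    n_screened_out = 626)
  pct <- function(ck) tab$pct[tab$check == ck]
  expect_identical(pct("ANY_ITEM_REGRESSION"), 97.9)
  expect_identical(pct("ANY_TOTAL_SCORE"), 13.7)
  expect_identical(pct("ANY_USAGE_REPORT"), 3.2)
  expect_identical(pct("TOTAL_BELOW_MIN"), 2.6)
  expect_identical(pct("TOTAL_DELTA_GT10"), 11.3)
  expect_identical(pct("ITEM3_TO_NEVER"), 20.4)
  expect_identical(pct("ITEM4_TO_NEVER"), 34.3)
  expect_identical(pct("ITEM5_TO_NEVER"), 33.4)
  expect_identical(pct("ITEM6_TO_NEVER"), 24.1)
  expect_identical(pct("ITEM7_TO_NEVER"), 28.3)
  expect_identical(pct("USE_ITEM2_NEVER"), 1.0)

  expect_error(inconsistency_table_from_counts(
    c(TOTAL_BELOW_MIN = 700), c(total_score = 700), 626), "exceeds")
})

test_that("per-family descriptives allow overlapping membership", {
  rows <- do.call(rbind, lapply(1:12, function(i)
    consistent_record(sprintf("D%02d", i))))
  # respondent 1 fires in two families: item regression + usage denial
  for (k in paste0("bl_item", 2:7))
    rows[[k]][1] <- the_instrument$items[[sub("bl_", "", k)]]$options[1]
  rows$usage_pattern[1] <- "I do not use cannabis"
  rows$usage_times_weekday[1] <- 0L
  rows$usage_times_weekend[1] <- 0L
  rows$usage_hours[1] <- "I do not use cannabis"
  rows$bl_item4[2] <- "Never"
  checks <- screen_cohort(rows, the_instrument)
  tab <- per_type_descriptives(rows, checks)
  n_row <- tab[tab$variable == "n", ]
  expect_identical(n_row$item_regression, "2")
  expect_identical(n_row$usage_report, "1")
  expect_identical(n_row$total_score, "1")   # all-never baseline: total 0

  none <- screen_cohort(rows[3:4, ], the_instrument)
  tab0 <- per_type_descriptives(rows[3:4, ], none)
  expect_true(all(is.na(tab0$item_regression)))
})

test_that("detection performance scores behaviours against ground truth", {
  spec <- population_spec(
    n = 120, seed = 8, p_agree = 1,
    mixture = c(faithful = 1, random_uniform = 0, straightliner = 0,
                fraud_inflator = 0, bot = 0),
    rates = list(consent = 1, duplicate = 0, withdraw = 0,
                 baseline_complete = 1),
    demographics = list(underage_rate = 0, never_used_rate = 0))
  coh <- generate_cohort(spec)
  flow <- run_flow(coh$records)
  perf <- detection_performance(coh$truth, flow$reports)
  expect_identical(perf$specificity, 1)
  expect_true(is.na(perf$sensitivity))

  straight <- population_spec(
    n = 80, seed = 9,
    mixture = c(faithful = 0, random_uniform = 0, straightliner = 1,
                fraud_inflator = 0, bot = 0),
    straight_ordinal = 3,
    rates = list(consent = 1, duplicate = 0, withdraw = 0,
                 baseline_complete = 1),
    demographics = list(underage_rate = 0, never_used_rate = 0))
  coh2 <- generate_cohort(straight)
  flow2 <- run_flow(coh2$records)
  perf2 <- detection_performance(coh2$truth, flow2$reports)
  expect_identical(perf2$sensitivity, 0)   # the method's blind spot

  expect_error(detection_performance(coh$truth[-1, ], flow$reports),
               "join error")
})

test_that("the oracle is exact, reproducible, and guards its modes", {
  red <- subset_instrument(the_instrument, c(2, 5))
  ex <- random_flag_oracle(red, "exhaustive", usage = "item2")
  expect_identical(ex$se, 0)
  mc1 <- random_flag_oracle(red, "monte_carlo", n_draws = 2e4, seed = 5,
                            usage = "item2")
  mc2 <- random_flag_oracle(red, "monte_carlo", n_draws = 2e4, seed = 5,
                            usage = "item2")
  expect_identical(mc1$probability, mc2$probability)
  expect_lt(abs(mc1$probability - ex$probability), 3 * mc1$se)

  # single item, delta bound above max attainable, no usage checks:
  # only the below-minimum rule can fire; closed form is 3/5
  red2 <- subset_instrument(the_instrument, 2)
  ex2 <- random_flag_oracle(red2, "exhaustive", usage = "none")
  expect_equal(ex2$probability, 3 / 5)

  expect_error(random_flag_oracle(red, "exhaustive", usage = "full"),
               "mode error")
  expect_error(random_flag_oracle(the_instrument, "exhaustive",
                                  usage = "item2"), "mode error")
})

test_that("random-cohort sensitivity converges to the oracle probability", {
  spec <- population_spec(
    n = 1200, seed = 14,
    mixture = c(faithful = 0, random_uniform = 1, straightliner = 0,
                fraud_inflator = 0, bot = 0),
    rates = list(consent = 1, duplicate = 0, withdraw = 0,
                 baseline_complete = 1),
    demographics = list(underage_rate = 0, never_used_rate = 0))
  coh <- generate_cohort(spec)
  flow <- run_flow(coh$records)
  perf <- detection_performance(coh$truth, flow$reports)
  n_assessed <- flow$consort$consistency_assessed

  oracle <- random_flag_oracle(the_instrument, "monte_carlo",
                               n_draws = 1e5, seed = 15, usage = "full")
  se <- sqrt(oracle$probability * (1 - oracle$probability) / n_assessed)
  expect_lt(abs(perf$sensitivity - oracle$probability), 3.5 * se)
})
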