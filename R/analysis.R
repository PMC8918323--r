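#' Cohen's kappa for two categorical vectors
#'
#' Unweighted chance-corrected agreement, the statistic in which the
#' instrument's test--retest reliability is quoted (per-item kappas 0.43 to
#' 0.72, mean 0.64, in the international reliability study).
#'
#' @param x,y equal-length vectors of category codes.
#' @return numeric kappa.
#' @export
cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y))
  lev <- union(unique(x), unique(y))
  x <- factor(x, levels = lev)
  y <- factor(y, levels = lev)
  po <- mean(x == y)
  pe <- sum(prop.table(table(x)) * prop.table(table(y)))
  (po - pe) / (1 - pe)
}

#' Per-item test--retest kappa of simulated administration pairs
#'
#' @param pairs data.frame from [simulate_retest()] (ordinal columns
#'   `scr_item<k>`, `bl_item<k>`).
#' @param instrument an `assist_instrument`.
#' @return named numeric vector, one kappa per scored item.
#' @export
retest_kappa <- function(pairs, instrument = assist_instrument()) {
  ids <- scored_items(instrument)
  stats::setNames(vapply(ids, function(id)
    cohen_kappa(pairs[[paste0("scr_item", id)]],
                pairs[[paste0("bl_item", id)]]), numeric(1)),
    paste0("item", ids))
}

format_p <- function(p) ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))

#' Bivariate comparison of two respondent groups
#'
#' Compares the screened-in and screened-out groups (or any two-level
#' partition) variable by variable: binary categorical variables with a
#' 2x2 chi-square test (no continuity correction by default, appropriate at
#' these group sizes), continuous variables with a two-sample t-test
#' (Welch's unequal-variance form by default; `pooled = TRUE` for the
#' classical pooled test). Two-sided throughout, no multiplicity adjustment.
#'
#' @param records data.frame of respondents.
#' @param group name of a logical column, or a logical vector, defining the
#'   partition; `TRUE` is group A.
#' @param categorical character vector of logical-column names to compare.
#' @param continuous character vector of numeric-column names to compare.
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @param correct apply Yates continuity correction to the chi-square.
#' @return data.frame with one row per variable: formatted group summaries
#'   (`n (pct)` or `mean (sd)`), `statistic`, `p_value`, `p_display`,
#'   `test_kind`, and a `note` column flagging undefined statistics
#'   (zero-variance continuous variables).
#' @export
compare_groups <- function(records, group, categorical = character(),
                           continuous = character(), pooled = FALSE,
                           correct = FALSE) {
  g <- if (is.character(group) && length(group) == 1)
    records[[group]] else group
  g <- as.logical(g)
  if (sum(g) == 0 || sum(!g) == 0)
    stop("degenerate partition: both groups must be non-empty",
         call. = FALSE)

  rows <- list()
  for (v in categorical) {
    x <- as.logical(records[[v]])
    tab <- table(factor(g, c(TRUE, FALSE)), factor(x, c(TRUE, FALSE)))
    ht <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    fmt <- function(keep) sprintf("%d (%.1f)", sum(x[keep]),
                                  round_half_up(100 * mean(x[keep]), 1))
    rows[[v]] <- data.frame(
      variable = v, group_a_summary = fmt(g), group_b_summary = fmt(!g),
      statistic = unname(ht$statistic), p_value = ht$p.value,
      p_display = format_p(ht$p.value), test_kind = "chi_square",
      note = "", stringsAsFactors = FALSE)
  }
  for (v in continuous) {
    x <- as.numeric(records[[v]])
    fmt <- function(keep) sprintf("%.1f (%.1f)", mean(x[keep]),
                                  stats::sd(x[keep]))
    if (stats::sd(x[g]) == 0 && stats::sd(x[!g]) == 0) {
      rows[[v]] <- data.frame(
        variable = v, group_a_summary = fmt(g), group_b_summary = fmt(!g),
        statistic = NA_real_, p_value = NA_real_, p_display = NA_character_,
        test_kind = "two_sample_t", note = "undefined: zero variance",
        stringsAsFactors = FALSE)
    } else {
      ht <- stats::t.test(x[g], x[!g], var.equal = pooled)
      rows[[v]] <- data.frame(
        variable = v, group_a_summary = fmt(g), group_b_summary = fmt(!g),
        statistic = unname(ht$statistic), p_value = ht$p.value,
        p_display = format_p(ht$p.value), test_kind = "two_sample_t",
        note = "", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-sample t-test from summary statistics
#'
#' Welch's unequal-variance t (or the pooled form) computed directly from
#' group means, standard deviations and sizes — the form needed to verify
#' published group-comparison cells when raw data are unavailable.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summaries.
#' @param pooled use the pooled-variance form.
#' @return list with `statistic`, `df`, `p_value` (two-sided).
#' @examples
#' summary_ttest(39.5, 13.9, 626, 35.7, 12.9, 755)
#' @export
summary_ttest <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                          pooled = FALSE) {
  if (sd_a <= 0 || sd_b <= 0 || n_a < 2 || n_b < 2)
    stop("need positive sds and group sizes of at least 2", call. = FALSE)
  if (pooled) {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    va <- sd_a^2 / n_a
    vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  list(statistic = t, df = df,
       p_value = 2 * stats::pt(-abs(t), df))
}

#' Frequency table of inconsistency checks among the screened out
#'
#' Per-check firing counts and percentages over the screened-out
#' respondents, with an "any" row per family computed as the union of its
#' member checks (a respondent firing two member checks counts once), never
#' as the sum — member counts can overlap, so the family row is bounded
#' above by, and usually below, the member sum.
#'
#' @param reports check matrix from [screen_cohort()].
#' @return data.frame with columns `check`, `family`, `label`, `n`, `pct`
#'   (percent of screened-out, half-up to one decimal); family rows carry
#'   check ids like `ANY_TOTAL_SCORE`.
#' @export
inconsistency_table <- function(reports) {
  stopifnot(nrow(reports) > 0)
  out_rows <- reports[reports$decision == "screened_out", , drop = FALSE]
  denom <- nrow(out_rows)
  cat_ <- check_catalogue()
  rows <- list()
  for (fam in unique(cat_$family)) {
    members <- cat_$check[cat_$family == fam]
    for (ck in members) {
      n <- sum(out_rows[[ck]])
      rows[[ck]] <- data.frame(
        check = ck, family = fam,
        label = cat_$label[cat_$check == ck], n = n,
        pct = if (denom > 0) round_half_up(100 * n / denom, 1) else NA_real_,
        stringsAsFactors = FALSE)
    }
    any_n <- if (denom > 0)
      sum(Reduce(`|`, lapply(members, function(ck) out_rows[[ck]]))) else 0L
    rows[[paste0("any_", fam)]] <- data.frame(
      check = paste0("ANY_", toupper(fam)), family = fam,
      label = paste0("Any ", gsub("_", " ", fam), " inconsistency"),
      n = any_n,
      pct = if (denom > 0) round_half_up(100 * any_n / denom, 1)
            else NA_real_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_screened_out") <- denom
  out
}

#' Frequency table from pre-tallied check counts
#'
#' Builds the same table shape as [inconsistency_table()] from aggregate
#' per-check and per-family counts (as printed in a published frequency
#' table), when record-level reports are unavailable. Family "any" counts
#' must be supplied — they are unions and cannot be recovered from member
#' counts.
#'
#' @param check_counts named integer vector over (a subset of) the
#'   catalogue's check ids.
#' @param any_counts named integer vector over families (`total_score`,
#'   `item_regression`, `usage_report`).
#' @param n_screened_out denominator.
#' @return data.frame as in [inconsistency_table()].
#' @export
inconsistency_table_from_counts <- function(check_counts, any_counts,
                                            n_screened_out) {
  cat_ <- check_catalogue()
  rows <- list()
  for (fam in unique(cat_$family)) {
    for (ck in cat_$check[cat_$family == fam]) {
      if (!ck %in% names(check_counts)) next
      n <- check_counts[[ck]]
      if (n > n_screened_out)
        stop("check count exceeds screened-out denominator", call. = FALSE)
      rows[[ck]] <- data.frame(
        check = ck, family = fam, label = cat_$label[cat_$check == ck],
        n = n, pct = round_half_up(100 * n / n_screened_out, 1),
        stringsAsFactors = FALSE)
    }
    if (fam %in% names(any_counts)) {
      n <- any_counts[[fam]]
      members <- intersect(cat_$check[cat_$family == fam],
                           names(check_counts))
      if (length(members) && n > sum(check_counts[members]))
        stop("family union count exceeds the sum of its member counts",
             call. = FALSE)
      rows[[paste0("any_", fam)]] <- data.frame(
        check = paste0("ANY_", toupper(fam)), family = fam,
        label = paste0("Any ", gsub("_", " ", fam), " inconsistency"),
        n = n, pct = round_half_up(100 * n / n_screened_out, 1),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_screened_out") <- n_screened_out
  out
}

#' Descriptives of screened-out respondents by inconsistency family
#'
#' One column per check family; a respondent appears in every family in
#' which at least one of their checks fired, so column memberships overlap
#' and column sizes can sum to more than the screened-out count.
#'
#' @param records records data.frame (demographics per [records_schema()]).
#' @param reports check matrix from [screen_cohort()].
#' @return data.frame: rows are descriptive variables (`n`, percentages of
#'   logical demographics, mean (SD) of continuous ones, screener and
#'   baseline totals), columns are the three families.
#' @export
per_type_descriptives <- function(records, reports) {
  cat_ <- check_catalogue()
  out_rows <- reports[reports$decision == "screened_out", , drop = FALSE]
  merged <- merge(out_rows, records, by = "id")
  fams <- unique(cat_$family)
  cols <- lapply(fams, function(fam) {
    members <- cat_$check[cat_$family == fam]
    infam <- Reduce(`|`, lapply(members, function(ck) merged[[ck]]))
    m <- merged[infam, , drop = FALSE]
    pctn <- function(v) sprintf("%.1f (%d)",
                                round_half_up(100 * mean(v), 1), sum(v))
    msd <- function(v) sprintf("%.1f (%.1f)", mean(v), stats::sd(v))
    if (nrow(m) == 0) return(stats::setNames(
      rep(NA_character_, 9),
      c("n", "male", "postsec", "married", "employed", "income_low", "age",
        "screener_total", "baseline_total")))
    c(n = as.character(nrow(m)),
      male = pctn(m$male), postsec = pctn(m$postsec),
      married = pctn(m$married), employed = pctn(m$employed),
      income_low = pctn(m$income_low), age = msd(m$age),
      screener_total = msd(m$screener_total),
      baseline_total = msd(m$baseline_total))
  })
  out <- as.data.frame(stats::setNames(cols, fams),
                       stringsAsFactors = FALSE)
  out <- cbind(variable = rownames(out), out)
  rownames(out) <- NULL
  out
}

#' Detection performance against simulated ground truth
#'
#' Joins consistency decisions to the simulator's behaviour labels and
#' reports the flagged fraction per behaviour, sensitivity (flagged share of
#' non-faithful respondents) and specificity (unflagged share of faithful
#' respondents). Only computable on simulated cohorts — real recruitment
#' data carry no ground truth.
#'
#' @param truth data.frame `id`, `behavior` (or the list returned by
#'   [generate_cohort()]).
#' @param reports check matrix from [screen_cohort()] or [run_flow()].
#' @return list with `per_behavior_flag_rate`, `n_per_behavior`,
#'   `sensitivity`, `specificity`.
#' @export
detection_performance <- function(truth, reports) {
  if (is.list(truth) && !is.data.frame(truth) && !is.null(truth$truth))
    truth <- truth$truth
  if (!all(reports$id %in% truth$id))
    stop("join error: some assessed records lack a truth label",
         call. = FALSE)
  m <- merge(reports, truth, by = "id")
  flagged <- m$decision == "screened_out"
  rate <- tapply(flagged, m$behavior, mean)
  nb <- tapply(flagged, m$behavior, length)
  invalid <- m$behavior != "faithful"
  list(per_behavior_flag_rate = rate,
       n_per_behavior = nb,
       sensitivity = if (any(invalid)) mean(flagged[invalid]) else NA_real_,
       specificity = if (any(!invalid)) mean(!flagged[!invalid])
                     else NA_real_)
}

#' Flag probability of a uniform-random responder
#'
#' Independent verification oracle for the rule engine: computes the
#' probability that a uniformly random respondent who passes screener
#' eligibility is flagged by the consistency rules, without going through
#' [evaluate_pair()] — the predicates are re-evaluated directly on ordinal
#' matrices. `exhaustive` mode enumerates every eligible screener x
#' baseline combination (exact; available when the paired space is at most
#' 10^7 and the usage probes are restricted to at most the item-2 denial);
#' `monte_carlo` mode estimates the probability with a reported standard
#' error and can additionally draw the three usage probes uniformly
#' (`usage = "full"`).
#'
#' @param instrument an `assist_instrument` (typically reduced via
#'   [subset_instrument()] for exhaustive mode).
#' @param mode `"exhaustive"` or `"monte_carlo"`.
#' @param n_draws Monte Carlo sample size.
#' @param seed RNG seed (Monte Carlo).
#' @param usage `"item2"` (baseline item-2 denial check only, the default),
#'   `"none"` (no usage-report checks), or `"full"` (all four probes, drawn
#'   uniformly; Monte Carlo only).
#' @param min_total,delta_bound threshold overrides.
#' @return list with `probability`, `se` (0 in exhaustive mode), `n`
#'   (pairs enumerated or drawn), `mode`.
#' @export
random_flag_oracle <- function(instrument,
                               mode = c("exhaustive", "monte_carlo"),
                               n_draws = 1e5, seed = 1L,
                               usage = c("item2", "none", "full"),
                               min_total = NULL, delta_bound = NULL) {
  mode <- match.arg(mode)
  usage <- match.arg(usage)
  thr <- instrument$thresholds
  min_total <- if (is.null(min_total)) thr$min_total else min_total
  delta_bound <- if (is.null(delta_bound)) thr$delta_bound else delta_bound

  ids <- scored_items(instrument)
  wvec <- lapply(ids, function(id) {
    it <- get_item(instrument, id)
    unname(it$weights[it$options])   # weight by display ordinal
  })
  nopt <- vapply(wvec, length, integer(1))
  totals <- function(M) {
    t <- numeric(nrow(M))
    for (j in seq_along(ids)) t <- t + wvec[[j]][M[, j] + 1L]
    t
  }
  reg_cols <- which(ids %in% 3:7)
  item2_col <- which(ids == 2L)
  flag <- function(S, B, probes = NULL) {
    st <- totals(S)
    bt <- totals(B)
    f <- bt < min_total | abs(bt - st) > delta_bound
    for (j in reg_cols) f <- f | (S[, j] > 0L & B[, j] == 0L)
    if (usage %in% c("item2", "full") && length(item2_col))
      f <- f | (B[, item2_col] == 0L)
    if (usage == "full" && !is.null(probes))
      f <- f | probes$pattern == 0L | probes$hours == 0L |
        (probes$tw == 0L & probes$te == 0L)
    f
  }

  if (mode == "exhaustive") {
    if (usage == "full")
      stop("mode error: exhaustive enumeration does not cover the",
           " usage-probe space", call. = FALSE)
    grid <- as.matrix(expand.grid(lapply(nopt, function(k)
      0:(k - 1L))))
    elig <- grid[totals(grid) >= min_total, , drop = FALSE]
    n_pairs <- nrow(elig) * nrow(grid)
    if (n_pairs > 1e7)
      stop("mode error: paired response space too large for exhaustive",
           " enumeration", call. = FALSE)
    S <- elig[rep(seq_len(nrow(elig)), each = nrow(grid)), , drop = FALSE]
    B <- grid[rep(seq_len(nrow(grid)), times = nrow(elig)), , drop = FALSE]
    return(list(probability = mean(flag(S, B)), se = 0, n = n_pairs,
                mode = mode))
  }

  set.seed(seed)
  draw <- function(n) {
    M <- matrix(0L, n, length(ids))
    for (j in seq_along(ids))
      M[, j] <- sample.int(nopt[j], n, replace = TRUE) - 1L
    M
  }
  S <- matrix(0L, 0, length(ids))
  while (nrow(S) < n_draws) {
    cand <- draw(2L * n_draws)
    cand <- cand[totals(cand) >= min_total, , drop = FALSE]
    S <- rbind(S, cand)
  }
  S <- S[seq_len(n_draws), , drop = FALSE]
  B <- draw(n_draws)
  probes <- if (usage == "full") {
    pr <- instrument$usage_probes
    list(pattern = sample.int(length(pr$pattern$options), n_draws,
                              replace = TRUE) - 1L,
         hours = sample.int(length(pr$hours$options), n_draws,
                            replace = TRUE) - 1L,
         tw = sample.int(pr$times$max_per_day + 1L, n_draws,
                         replace = TRUE) - 1L,
         te = sample.int(pr$times$max_per_day + 1L, n_draws,
                         replace = TRUE) - 1L)
  }
  p <- mean(flag(S, B, probes))
  list(probability = p, se = sqrt(p * (1 - p) / n_draws), n = n_draws,
       mode = mode)
}
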