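rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 1000003) %% 2147483647)
}

max_ordinals <- function(instrument) {
  ids <- scored_items(instrument)
  stats::setNames(vapply(ids, function(id)
    length(get_item(instrument, id)$options) - 1L, integer(1)),
    paste0("item", ids))
}

#' Realize a latent severity as an item-level response
#'
#' Allocates a target total score across the instrument's scored items by
#' iteratively incrementing items (visited in randomized order) along their
#' weight-increasing option sequence until the target is reached or
#' bracketed within one step. Totals therefore approximately match the
#' latent severity while item patterns stay variable — there is no
#' item-level generative model to borrow, so variability is injected through
#' the randomized allocation order.
#'
#' @param instrument an `assist_instrument`.
#' @param target latent total in \[0, `max_attainable(instrument)`\].
#' @param ensure_item2 when `TRUE` and `target` is at least the first
#'   endorsed weight of item 2, item 2 starts at its first endorsed option:
#'   anyone with genuine use frequency reports non-"Never" on the frequency
#'   item, so faithful profiles never deny use while endorsing symptoms.
#' @return named character vector of option labels for the scored items.
#' @export
allocate_severity <- function(instrument, target, ensure_item2 = FALSE) {
  ids <- scored_items(instrument)
  keys <- paste0("item", ids)
  # per item, options sorted by ascending weight (display order and weight
  # order differ on items 6-7)
  lv <- lapply(ids, function(id) {
    it <- get_item(instrument, id)
    it$options[order(it$weights[it$options])]
  })
  names(lv) <- keys
  rank_ <- stats::setNames(rep(1L, length(ids)), keys)  # index into lv
  total <- 0
  open <- keys
  if (ensure_item2 && "item2" %in% keys) {
    it2 <- get_item(instrument, 2)
    w1 <- it2$weights[[lv$item2[2]]]
    if (target >= w1) {
      rank_["item2"] <- 2L
      total <- w1
    }
  }
  while (total < target && length(open)) {
    k <- if (length(open) == 1) open else sample(open, 1)
    it <- get_item(instrument, sub("item", "", k))
    w <- it$weights[lv[[k]]]
    gain <- w[[rank_[k] + 1L]] - w[[rank_[k]]]
    if (total + gain <= target) {
      rank_[k] <- rank_[k] + 1L
      total <- total + gain
      if (rank_[k] == length(lv[[k]])) open <- setdiff(open, k)
    } else if ((total + gain - target) < (target - total)) {
      rank_[k] <- rank_[k] + 1L   # overshoot, but closer: bracket and stop
      break
    } else {
      open <- setdiff(open, k)    # stepping this item overshoots too far
    }
  }
  stats::setNames(mapply(function(k, r) lv[[k]][r], keys, rank_), keys)
}

drift_one_step <- function(instrument, response, protect_item2 = TRUE) {
  ids <- scored_items(instrument)
  for (id in ids) {
    k <- paste0("item", id)
    opts <- get_item(instrument, id)$options
    o <- match(response[[k]], opts) - 1L
    step <- sample(c(-1L, 1L), 1)
    o2 <- o + step
    if (o2 < 0L || o2 > length(opts) - 1L) o2 <- o - step  # reflect
    # a faithful user does not flip to denying use outright
    if (protect_item2 && id == 2L && o2 == 0L && o > 0L) o2 <- o + 1L
    if (o2 > length(opts) - 1L) o2 <- length(opts) - 1L
    response[[k]] <- opts[o2 + 1L]
  }
  response
}

#' Simulate a faithful respondent's screener/baseline pair
#'
#' The screener realizes the latent severity via [allocate_severity()]; the
#' baseline repeats each screener selection with probability `p_agree` and
#' otherwise drifts one display position (reflecting at the ends), the local
#' retest noise expected from remembering or forgetting details between
#' administrations. A faithful user with positive severity never drifts item
#' 2 down to "Never" (they do use cannabis; denial is not retest noise).
#' With `p_agree = 1` the pair is identical.
#'
#' @param instrument an `assist_instrument`.
#' @param severity latent total score.
#' @param p_agree per-item probability of repeating the screener selection.
#'   The default 0.75 is calibrated so simulated per-item test--retest kappas
#'   fall in the 0.43--0.72 range reported for the instrument.
#' @return list with `screener` and `baseline` label vectors.
#' @export
sample_faithful <- function(instrument, severity, p_agree = 0.75) {
  scr <- allocate_severity(instrument, severity, ensure_item2 = severity > 0)
  bl <- scr
  keep <- stats::runif(length(scr)) < p_agree
  if (!all(keep)) {
    drifted <- drift_one_step(instrument, scr,
                              protect_item2 = severity > 0)
    bl[!keep] <- drifted[!keep]
  }
  list(screener = scr, baseline = bl)
}

#' Simulate a uniform-random responder (or bot)
#'
#' Every option of every scored item is equiprobable and the two
#' administrations are drawn independently — the canonical model of a
#' respondent (or automatic program) for whom every answer has an equal
#' likelihood of being selected.
#'
#' @param instrument an `assist_instrument`.
#' @return list with `screener` and `baseline` label vectors.
#' @export
sample_random <- function(instrument) {
  ids <- scored_items(instrument)
  draw <- function() {
    sel <- vapply(ids, function(id) {
      opts <- get_item(instrument, id)$options
      opts[sample.int(length(opts), 1)]
    }, character(1))
    stats::setNames(sel, paste0("item", ids))
  }
  list(screener = draw(), baseline = draw())
}

#' Simulate a straightlining respondent
#'
#' Selects the same display position on every item of both administrations
#' (clamped where an item has fewer options). Straightliners are perfectly
#' consistent across administrations, so cross-administration checks never
#' flag them — a documented blind spot of the method.
#'
#' @param instrument an `assist_instrument`.
#' @param ordinal 0-based display position to straightline on.
#' @return list with `screener` and `baseline` label vectors.
#' @export
sample_straightliner <- function(instrument, ordinal = 3L) {
  r <- response_from_ordinals(instrument, ordinal)
  list(screener = r, baseline = r)
}

#' Simulate an eligibility-seeking (fraudulent inflator) respondent
#'
#' Models someone who misreports at screening to secure enrolment: the
#' baseline reflects their true (typically low) severity, while the screener
#' inflates every item by `inflate_steps` display positions (capped at each
#' item's last option). Low true severity plus inflation produces exactly
#' the signatures the rule engine hunts: endorsed-to-never regressions,
#' large negative score deltas, and baseline denial of use.
#'
#' @param instrument an `assist_instrument`.
#' @param true_severity latent total actually lived.
#' @param inflate_steps display positions added per item at screening
#'   (default 2).
#' @return list with `screener` and `baseline` label vectors.
#' @export
sample_fraud_inflator <- function(instrument, true_severity,
                                  inflate_steps = 2L) {
  base <- allocate_severity(instrument, true_severity)
  ids <- scored_items(instrument)
  scr <- base
  if (inflate_steps > 0) {
    for (id in ids) {
      k <- paste0("item", id)
      opts <- get_item(instrument, id)$options
      o <- match(base[[k]], opts) - 1L
      scr[[k]] <- opts[min(o + inflate_steps, length(opts) - 1L) + 1L]
    }
  }
  list(screener = scr, baseline = base)
}

#' Population specification for a synthetic cohort
#'
#' Bundles everything [generate_cohort()] needs: the behaviour mixture, the
#' latent-severity distribution, faithful retest noise, demographic
#' marginals and stage-attrition rates. Defaults emulate the recruitment
#' population of an online cannabis brief-intervention trial: mean age 37.5
#' (SD 13.5, truncated at 18 with a small under-age sliver), 36.7% male,
#' near-daily cannabis use, screener totals centred in the high-moderate
#' band, and attrition rates matching a consent-stage dropout of roughly
#' 55%, 11% duplicate enrolment, and 16% baseline non-completion.
#'
#' @param n cohort size (screener completers).
#' @param mixture named weights over behaviours `faithful`,
#'   `random_uniform`, `straightliner`, `fraud_inflator`, `bot`; must be
#'   non-negative and sum to 1 (within 1e-8).
#' @param severity list `mean`, `sd` of the latent total, truncated to the
#'   attainable range.
#' @param p_agree faithful per-item retest agreement probability.
#' @param inflate_steps fraud-inflator screener inflation.
#' @param straight_ordinal straightliner display position.
#' @param demographics list of marginals: `age_mean` / `age_sd` (location
#'   and scale of the parent normal; the default location 34.7 is calibrated
#'   so the age distribution truncated at 18 realizes a mean of 37.5),
#'   `underage_rate`, `male`, `postsec`, `married`, `employed`,
#'   `income_low`, `days30_daily_prob` / `days30_daily` / `days30_light`
#'   (near-daily-use mixture for days of use in the past 30),
#'   `never_used_rate`.
#' @param rates list of stage probabilities: `consent`, `duplicate`,
#'   `withdraw`, `baseline_complete`.
#' @param seed integer; the cohort RNG seed. Per-record substreams are
#'   derived from it, so subsetting a cohort never changes a record.
#' @return object of class `population_spec`.
#' @export
population_spec <- function(
    n,
    mixture = c(faithful = 0.55, random_uniform = 0.15, straightliner = 0.05,
                fraud_inflator = 0.15, bot = 0.10),
    severity = list(mean = 21, sd = 9.5),
    p_agree = 0.75,
    inflate_steps = 2L,
    straight_ordinal = 3L,
    demographics = list(),
    rates = list(),
    seed = 1L) {
  # age_mean is the location of the parent normal; truncation at 18 shifts
  # the realized mean up to ~37.5, the marginal the cohort should exhibit.
  # days-of-use is a near-daily majority plus a lighter-use tail.
  dem <- list(age_mean = 34.7, age_sd = 13.5, underage_rate = 19 / 4452,
              male = 0.367, postsec = 0.578, married = 0.450,
              employed = 0.527, income_low = 0.554,
              days30_daily_prob = 0.75, days30_daily = c(29, 3),
              days30_light = c(10, 8),
              never_used_rate = 60 / 4452)
  dem[names(demographics)] <- demographics
  rt <- list(consent = 1849 / 4153, duplicate = 207 / 1849,
             withdraw = 6 / 1642, baseline_complete = 1 - 255 / 1636)
  rt[names(rates)] <- rates

  kinds <- c("faithful", "random_uniform", "straightliner",
             "fraud_inflator", "bot")
  if (!all(names(mixture) %in% kinds))
    stop("unknown behaviour kind in mixture", call. = FALSE)
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8)
    stop("mixture weights must be non-negative and sum to 1", call. = FALSE)
  if (any(unlist(rt) < 0 | unlist(rt) > 1))
    stop("attrition rates must be probabilities", call. = FALSE)

  structure(list(n = as.integer(n), mixture = mixture, severity = severity,
                 p_agree = p_agree, inflate_steps = as.integer(inflate_steps),
                 straight_ordinal = as.integer(straight_ordinal),
                 demographics = dem, rates = rt, seed = as.integer(seed)),
            class = "population_spec")
}

sample_usage_answers <- function(instrument, baseline, behavior) {
  pr <- instrument$usage_probes
  if (behavior %in% c("random_uniform", "bot")) {
    return(list(
      pattern = sample(pr$pattern$options, 1),
      times_weekday = sample.int(pr$times$max_per_day + 1L, 1) - 1L,
      times_weekend = sample.int(pr$times$max_per_day + 1L, 1) - 1L,
      hours = sample(pr$hours$options, 1)))
  }
  denies <- ordinal_of(instrument, 2, baseline[["item2"]]) == 0L
  if (denies) {
    list(pattern = pr$pattern$nonuse, times_weekday = 0L, times_weekend = 0L,
         hours = pr$hours$nonuse)
  } else {
    use_pat <- setdiff(pr$pattern$options, pr$pattern$nonuse)
    use_hrs <- setdiff(pr$hours$options, pr$hours$nonuse)
    list(pattern = sample(use_pat, 1),
         times_weekday = sample.int(4L, 1),
         times_weekend = sample.int(6L, 1),
         hours = sample(use_hrs, 1))
  }
}

#' Generate a synthetic screener/baseline cohort
#'
#' Draws `spec$n` respondent records — demographics, behaviour label, paired
#' ASSIST administrations, usage probes and stage-attrition fates — ready
#' for [run_flow()]. Every record is generated from its own RNG substream
#' derived from `spec$seed` and the record index, so the same seed
#' reproduces the cohort byte-for-byte and subsetting leaves individual
#' records unchanged.
#'
#' The ground-truth behaviour label of every record is returned alongside;
#' every kind except `faithful` counts as invalid when scoring detection
#' performance. Real screened-out cohorts have no such labels — the
#' simulator exists precisely to supply them.
#'
#' @param spec a [population_spec()].
#' @param instrument an `assist_instrument`.
#' @return list with `records` (data.frame per [records_schema()]) and
#'   `truth` (data.frame `id`, `behavior`).
#' @export
generate_cohort <- function(spec, instrument = assist_instrument()) {
  stopifnot(inherits(spec, "population_spec"))
  dem <- spec$demographics
  rt <- spec$rates
  kinds <- names(spec$mixture)
  maxtot <- max_attainable(instrument)

  n <- spec$n
  ids <- scored_items(instrument)
  chr <- function() character(n)
  col <- list(
    id = sprintf("P%05d", seq_len(n)), age = integer(n),
    male = logical(n), postsec = logical(n), married = logical(n),
    employed = logical(n), income_low = logical(n),
    days_past30 = integer(n), used_cannabis = logical(n),
    consented = logical(n), duplicate = logical(n), withdrew = logical(n),
    baseline_complete = logical(n), behavior = chr())
  for (id in ids) {
    col[[paste0("scr_item", id)]] <- chr()
    col[[paste0("bl_item", id)]] <- chr()
  }
  col$usage_pattern <- chr()
  col$usage_times_weekday <- integer(n)
  col$usage_times_weekend <- integer(n)
  col$usage_hours <- chr()

  for (i in seq_len(n)) {
    set.seed(derive_seed(spec$seed, i))
    behavior <- sample(kinds, 1, prob = spec$mixture)

    underage <- stats::runif(1) < dem$underage_rate
    col$age[i] <- if (underage) sample(16:17, 1) else
      round(rtruncnorm1(1, dem$age_mean, dem$age_sd, lower = 18))
    severity <- round(rtruncnorm1(1, spec$severity$mean, spec$severity$sd,
                                  lower = 0, upper = maxtot))

    pair <- switch(behavior,
      faithful = sample_faithful(instrument, severity, spec$p_agree),
      random_uniform = sample_random(instrument),
      bot = sample_random(instrument),
      straightliner = sample_straightliner(instrument,
                                           spec$straight_ordinal),
      fraud_inflator = sample_fraud_inflator(
        instrument, round(severity / 4), spec$inflate_steps))

    usage <- sample_usage_answers(instrument, pair$baseline, behavior)

    col$male[i] <- stats::runif(1) < dem$male
    col$postsec[i] <- stats::runif(1) < dem$postsec
    col$married[i] <- stats::runif(1) < dem$married
    col$employed[i] <- stats::runif(1) < dem$employed
    col$income_low[i] <- stats::runif(1) < dem$income_low
    days_par <- if (stats::runif(1) < dem$days30_daily_prob)
      dem$days30_daily else dem$days30_light
    col$days_past30[i] <- min(30, max(0, round(rtruncnorm1(
      1, days_par[1], days_par[2], lower = 0, upper = 30))))
    col$used_cannabis[i] <- !(stats::runif(1) < dem$never_used_rate)
    col$consented[i] <- stats::runif(1) < rt$consent
    col$duplicate[i] <- stats::runif(1) < rt$duplicate
    col$withdrew[i] <- stats::runif(1) < rt$withdraw
    col$baseline_complete[i] <- stats::runif(1) < rt$baseline_complete
    col$behavior[i] <- behavior
    for (id in ids) {
      col[[paste0("scr_item", id)]][i] <- pair$screener[[paste0("item", id)]]
      col[[paste0("bl_item", id)]][i] <- pair$baseline[[paste0("item", id)]]
    }
    col$usage_pattern[i] <- usage$pattern
    col$usage_times_weekday[i] <- usage$times_weekday
    col$usage_times_weekend[i] <- usage$times_weekend
    col$usage_hours[i] <- usage$hours
  }
  records <- as.data.frame(col, stringsAsFactors = FALSE)
  truth <- records[, c("id", "behavior")]
  records$behavior <- NULL
  list(records = records, truth = truth)
}

#' Simulate repeated faithful administrations for reliability analysis
#'
#' Draws `n` faithful screener/baseline pairs, with each pair's latent
#' severity drawn from the eligible population (truncated normal on the
#' moderate-and-above range by default), and returns the display positions
#' selected on each administration — the input for per-item test--retest
#' agreement ([retest_kappa()]).
#'
#' @param n number of pairs.
#' @param p_agree per-item retest agreement probability.
#' @param severity fixed latent total, or `NULL` to draw per pair from
#'   `severity_dist`.
#' @param severity_dist list `mean`, `sd`, `lower` for the latent draw.
#' @param instrument an `assist_instrument`.
#' @param seed RNG seed.
#' @return data.frame with columns `scr_item<k>` / `bl_item<k>` holding
#'   display ordinals.
#' @export
simulate_retest <- function(n, p_agree = 0.75, severity = NULL,
                            severity_dist = list(mean = 21, sd = 9.5,
                                                 lower = 4),
                            instrument = assist_instrument(), seed = 1L) {
  set.seed(seed)
  ids <- scored_items(instrument)
  maxtot <- max_attainable(instrument)
  sev <- if (is.null(severity))
    round(rtruncnorm1(n, severity_dist$mean, severity_dist$sd,
                      lower = severity_dist$lower, upper = maxtot))
  else rep(severity, n)
  out <- matrix(NA_integer_, n, 2 * length(ids))
  colnames(out) <- c(paste0("scr_item", ids), paste0("bl_item", ids))
  for (i in seq_len(n)) {
    pair <- sample_faithful(instrument, sev[i], p_agree)
    out[i, ] <- c(
      vapply(ids, function(id)
        ordinal_of(instrument, id, pair$screener[[paste0("item", id)]]),
        integer(1)),
      vapply(ids, function(id)
        ordinal_of(instrument, id, pair$baseline[[paste0("item", id)]]),
        integer(1)))
  }
  as.data.frame(out)
}
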