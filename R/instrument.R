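#' The ASSIST cannabis subscale instrument
#'
#' Constructs the default instrument definition for the cannabis subscale of
#' the WHO Alcohol, Smoking and Substance Involvement Screening Test (ASSIST
#' V3.0). The instrument carries the eight ASSIST items; items 2 to 7 are
#' scored and their weights sum to a total in \[0, 39\]. Item 1 (lifetime use)
#' and item 8 (injection) are carried for completeness but never scored.
#'
#' Scoring weights follow the published WHO V3.0 cannabis table:
#' item 2: 0/2/3/4/6; item 3: 0/3/4/5/6; item 4: 0/4/5/6/7; item 5: 0/5/6/7/8;
#' items 6 and 7: 0 ("No, never"), 6 ("Yes, in the past 3 months"),
#' 3 ("Yes, but not in the past 3 months"). Weights for items 6 and 7 attach
#' to option labels, not display positions, so weight is not monotone in the
#' displayed order for those two items. The constructor asserts the published
#' anchors ("Weekly" scores 4 on item 2 and 7 on item 5; the maximum
#' attainable total is 39, the upper bound of the high-risk category) and
#' refuses to build an instrument that violates them.
#'
#' Risk categories partition the total score: lower (0--3), moderate (4--26),
#' high (27--39). Brief intervention is indicated from the moderate band, so
#' the eligibility and consistency rules both pivot on the score-4 boundary.
#'
#' The instrument also declares the three cannabis usage-pattern probes asked
#' alongside the baseline re-administration (weekly pattern, times per day on
#' weekdays/weekends, hours after waking until first use) with one canonical
#' non-use option each, and the default rule thresholds (minimum baseline
#' total 4, total-change bound 10 points, decision threshold of 1 fired
#' check).
#'
#' @param thresholds optional named list overriding rule thresholds; any of
#'   `min_total`, `delta_bound`, `decision_threshold`.
#' @return an object of class `assist_instrument`.
#' @examples
#' instr <- assist_instrument()
#' score_item(instr, 2, "Weekly")
#' max_attainable(instr)
#' @export
assist_instrument <- function(thresholds = list()) {
  freq_options <- c("Never", "Once or Twice", "Monthly", "Weekly",
                    "Daily or Almost Daily")
  yn3_options <- c("No, never", "Yes, in the past 3 months",
                   "Yes, but not in the past 3 months")
  wt <- function(options, w) stats::setNames(as.integer(w), options)

  items <- list(
    item1 = list(id = 1L, prompt = "ever used cannabis in lifetime",
                 options = c("No", "Yes"), weights = NULL, scored = FALSE),
    item2 = list(id = 2L, prompt = "how often used cannabis (past 3 months)",
                 options = freq_options,
                 weights = wt(freq_options, c(0, 2, 3, 4, 6)), scored = TRUE),
    item3 = list(id = 3L, prompt = "strong desire or urge to use",
                 options = freq_options,
                 weights = wt(freq_options, c(0, 3, 4, 5, 6)), scored = TRUE),
    item4 = list(id = 4L, prompt = "use led to health, social, legal, or financial problems",
                 options = freq_options,
                 weights = wt(freq_options, c(0, 4, 5, 6, 7)), scored = TRUE),
    item5 = list(id = 5L, prompt = "failed to do what was normally expected because of use",
                 options = freq_options,
                 weights = wt(freq_options, c(0, 5, 6, 7, 8)), scored = TRUE),
    item6 = list(id = 6L, prompt = "friend or relative or anyone else ever expressed concern",
                 options = yn3_options,
                 weights = wt(yn3_options, c(0, 6, 3)), scored = TRUE),
    item7 = list(id = 7L, prompt = "ever tried to control, cut down or stop using",
                 options = yn3_options,
                 weights = wt(yn3_options, c(0, 6, 3)), scored = TRUE),
    item8 = list(id = 8L, prompt = "ever used by injection",
                 options = yn3_options, weights = NULL, scored = FALSE)
  )

  nonuse <- "I do not use cannabis"
  usage_probes <- list(
    pattern = list(
      prompt = "which best captures your pattern of cannabis use through the week",
      options = c(nonuse, "Weekends only", "Weekdays only",
                  "Spread evenly through the week", "Most or every day"),
      nonuse = nonuse),
    times = list(
      prompt = "times per day used on a typical weekday / weekend day",
      max_per_day = 10L),
    hours = list(
      prompt = "hours after waking until first cannabis use",
      options = c(nonuse, "Within 1 hour", "1 to 3 hours", "3 to 6 hours",
                  "More than 6 hours"),
      nonuse = nonuse)
  )

  thr <- list(min_total = 4L, delta_bound = 10L, decision_threshold = 1L)
  thr[names(thresholds)] <- lapply(thresholds, as.integer)

  instr <- structure(
    list(name = "ASSIST cannabis subscale (WHO V3.0 weights)",
         items = items,
         category_bounds = list(lower = c(0L, 3L), moderate = c(4L, 26L),
                                high = c(27L, 39L)),
         usage_probes = usage_probes,
         thresholds = thr),
    class = "assist_instrument")

  validate_instrument(instr)
  # published anchors for the cannabis subscale; a weight table that breaks
  # any of these is not the instrument this package screens with
  stopifnot(score_item(instr, 2, "Weekly") == 4L,
            score_item(instr, 5, "Weekly") == 7L,
            max_attainable(instr) == instr$category_bounds$high[2])
  instr
}

#' Validate the structural invariants of an instrument definition
#'
#' Checks that scored items have a complete weight map, that the first-listed
#' ("Never"/"No, never") option carries weight zero, that weights on the
#' frequency items (2--5) are strictly increasing in display order, and that
#' the risk categories partition \[0, upper bound\] without gap or overlap.
#' Reduced instruments (a subset of the scored items) are valid; the category
#' partition is checked against the declared bounds, not the item set.
#'
#' @param instrument an `assist_instrument`.
#' @return the instrument, invisibly; errors on violation.
#' @export
validate_instrument <- function(instrument) {
  stopifnot(inherits(instrument, "assist_instrument"))
  for (it in instrument$items) {
    if (!it$scored) next
    if (is.null(it$weights) || !all(it$options %in% names(it$weights)))
      stop("scored item ", it$id, " lacks a weight for some option",
           call. = FALSE)
    if (it$weights[[it$options[1]]] != 0)
      stop("item ", it$id, ": first-listed option must carry weight 0",
           call. = FALSE)
    if (it$id %in% 2:5 && any(diff(it$weights[it$options]) <= 0))
      stop("item ", it$id, ": weights must strictly increase with frequency",
           call. = FALSE)
  }
  cb <- instrument$category_bounds
  edges <- c(cb$lower, cb$moderate, cb$high)
  if (cb$lower[1] != 0 || any(c(cb$moderate[1], cb$high[1]) !=
                              c(cb$lower[2], cb$moderate[2]) + 1L))
    stop("category bounds must partition the score range", call. = FALSE)
  invisible(instrument)
}

item_key <- function(item) {
  if (is.character(item) && grepl("^item[1-8]$", item)) return(item)
  paste0("item", as.integer(item))
}

get_item <- function(instrument, item) {
  key <- item_key(item)
  it <- instrument$items[[key]]
  if (is.null(it))
    stop("instrument has no item '", key, "'", call. = FALSE)
  it
}

#' Scored item ids of an instrument
#' @param instrument an `assist_instrument`.
#' @return integer vector of scored item ids (2--7 for the full instrument).
#' @export
scored_items <- function(instrument) {
  ids <- vapply(instrument$items, function(it) it$id, integer(1))
  unname(ids[vapply(instrument$items, function(it) isTRUE(it$scored),
                    logical(1))])
}

#' Score one item response
#'
#' Looks up the weight of a selected option on a scored ASSIST item. The
#' first-listed option ("Never" / "No, never") always scores 0.
#'
#' @param instrument an `assist_instrument`.
#' @param item item id (2--7) or key like `"item3"`.
#' @param option option label(s); vectorized.
#' @return integer score(s).
#' @export
score_item <- function(instrument, item, option) {
  it <- get_item(instrument, item)
  if (!isTRUE(it$scored))
    stop("item ", it$id, " is not scored", call. = FALSE)
  bad <- setdiff(unique(option), it$options)
  if (length(bad))
    stop("unknown option for item ", it$id, ": ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  unname(it$weights[option])
}

#' Total ASSIST score of one administration
#'
#' Sums the item weights over the instrument's scored items (2--7 for the
#' full cannabis subscale). A missing or unknown selection for any scored
#' item is an error of class `assistscreen_incomplete`; the recruitment
#' pipeline maps such records to the baseline-incomplete attrition exit
#' rather than scoring a partial sum.
#'
#' @param instrument an `assist_instrument`.
#' @param response named character vector or list mapping `"item2"` ...
#'   `"item7"` to selected option labels.
#' @return integer total in \[0, `max_attainable(instrument)`\].
#' @export
total_score <- function(instrument, response) {
  response <- unlist(response)
  total <- 0L
  for (id in scored_items(instrument)) {
    key <- paste0("item", id)
    sel <- if (key %in% names(response)) response[[key]] else NULL
    if (is.null(sel) || is.na(sel))
      stop(structure(class = c("assistscreen_incomplete", "error", "condition"),
                     list(message = paste0("no selection for ", key),
                          call = NULL)))
    total <- total + score_item(instrument, id, sel)
  }
  total
}

#' Maximum attainable total score
#'
#' Sum of per-item maximum weights over the scored items; 39 for the default
#' cannabis subscale. Used as a consistency guard for custom weight tables.
#'
#' @param instrument an `assist_instrument`.
#' @return integer.
#' @export
max_attainable <- function(instrument) {
  sum(vapply(instrument$items, function(it)
    if (isTRUE(it$scored)) max(it$weights) else 0L, numeric(1)))
}

#' Categorize an ASSIST total score into a risk band
#'
#' @param total integer total score(s) in \[0, 39\] (or the instrument's
#'   attainable range).
#' @param instrument an `assist_instrument`.
#' @return factor with levels `lower`, `moderate`, `high`.
#' @examples
#' categorize_risk(c(0, 3, 4, 26, 27), assist_instrument())
#' @export
categorize_risk <- function(total, instrument = assist_instrument()) {
  cb <- instrument$category_bounds
  if (any(total < cb$lower[1] | total > cb$high[2]))
    stop("total score out of [", cb$lower[1], ", ", cb$high[2], "]",
         call. = FALSE)
  cut(total, breaks = c(cb$lower[1] - 1L, cb$lower[2], cb$moderate[2],
                        cb$high[2]),
      labels = c("lower", "moderate", "high"))
}

#' Restrict an instrument to a subset of its scored items
#'
#' Produces a reduced instrument containing only the requested scored items
#' (plus unscored carriers), optionally dropping the usage probes. Reduced
#' instruments drive the exhaustive-enumeration oracle, whose paired response
#' space must stay small.
#'
#' @param instrument an `assist_instrument`.
#' @param items integer ids of scored items to keep.
#' @param keep_probes keep the usage-probe declarations? Default `FALSE`.
#' @return an `assist_instrument`.
#' @export
subset_instrument <- function(instrument, items, keep_probes = FALSE) {
  keep <- paste0("item", sort(unique(as.integer(items))))
  stopifnot(all(keep %in% names(instrument$items)))
  instrument$items <- instrument$items[keep]
  if (!keep_probes) instrument$usage_probes <- NULL
  instrument$name <- paste0(instrument$name, " [items ",
                            paste(items, collapse = ","), "]")
  instrument
}

#' @export
print.assist_instrument <- function(x, ...) {
  cat(x$name, "\n")
  cat("scored items:", paste(scored_items(x), collapse = ", "),
      " max total:", max_attainable(x), "\n")
  cb <- x$category_bounds
  cat(sprintf("risk bands: lower %d-%d | moderate %d-%d | high %d-%d\n",
              cb$lower[1], cb$lower[2], cb$moderate[1], cb$moderate[2],
              cb$high[1], cb$high[2]))
  thr <- x$thresholds
  cat(sprintf("rule thresholds: min total %d, delta bound %d, decision >= %d check(s)\n",
              thr$min_total, thr$delta_bound, thr$decision_threshold))
  invisible(x)
}

#' Write an instrument definition to a YAML config file
#'
#' Serializes the items, weights, category bounds, usage-probe declarations
#' and rule thresholds so that alternative substances or weight tables can be
#' declared in configuration and read back with [read_instrument()].
#'
#' @param instrument an `assist_instrument`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instrument, path) {
  ser <- list(
    name = instrument$name,
    items = lapply(instrument$items, function(it) {
      list(id = it$id, prompt = it$prompt, options = as.list(it$options),
           weights = if (is.null(it$weights)) NULL else as.list(it$weights),
           scored = it$scored)
    }),
    category_bounds = lapply(instrument$category_bounds, as.list),
    usage_probes = instrument$usage_probes,
    thresholds = instrument$thresholds)
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' Read an instrument definition from a YAML config file
#'
#' @param path file written by [write_instrument()] (or hand-authored in the
#'   same layout).
#' @return a validated `assist_instrument`.
#' @export
read_instrument <- function(path) {
  ser <- yaml::read_yaml(path)
  items <- lapply(ser$items, function(it) {
    w <- if (is.null(it$weights)) NULL else
      stats::setNames(as.integer(unlist(it$weights)), names(it$weights))
    list(id = as.integer(it$id), prompt = it$prompt,
         options = as.character(unlist(it$options)),
         weights = w, scored = isTRUE(it$scored))
  })
  names(items) <- paste0("item", vapply(items, `[[`, integer(1), "id"))
  instr <- structure(
    list(name = ser$name, items = items,
         category_bounds = lapply(ser$category_bounds,
                                  function(b) as.integer(unlist(b))),
         usage_probes = ser$usage_probes,
         thresholds = lapply(ser$thresholds, as.integer)),
    class = "assist_instrument")
  validate_instrument(instr)
}

#' Build a complete response from per-item display positions
#'
#' Convenience constructor mapping 0-based ordinals (display positions) to
#' option labels for every scored item; ordinals beyond an item's option
#' count are clamped to the last option. Used heavily by the simulator and
#' by tests.
#'
#' @param instrument an `assist_instrument`.
#' @param ordinals integer vector, either length 1 (recycled) or one per
#'   scored item in id order.
#' @return named character vector of option labels (`item2` ... `item7`).
#' @export
response_from_ordinals <- function(instrument, ordinals) {
  ids <- scored_items(instrument)
  ordinals <- rep_len(as.integer(ordinals), length(ids))
  sel <- mapply(function(id, o) {
    opts <- get_item(instrument, id)$options
    opts[min(o, length(opts) - 1L) + 1L]
  }, ids, ordinals)
  stats::setNames(sel, paste0("item", ids))
}

ordinal_of <- function(instrument, item, option) {
  match(option, get_item(instrument, item)$options) - 1L
}
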