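# assistscreen

Real-time screening of invalid survey respondents in two-stage online
recruitment, using repeated administrations of the WHO ASSIST cannabis
subscale.

## The problem

Online studies that recruit through social media attract careless
responders, straightliners, bots, and people who deliberately inflate
their answers to qualify. Cleaning such cases *after* data collection can
leave a trial badly under-powered. `assistscreen` implements the
alternative: administer the same instrument twice — once at eligibility
screening and again at the start of baseline — compare the two
administrations automatically, and screen out inconsistent respondents
*before* randomization.

## The method

The ASSIST cannabis subscale scores items 2–7 with item-specific weights
("Weekly" is worth 4 points on item 2 and 7 on item 5) and sums them to a
total $T \in [0, 39]$, banded lower (0–3), moderate (4–26) and high
(27–39) risk. Given screener and baseline administrations with totals
$T_S$ and $T_B$, eleven atomic consistency checks run in three families:

| family | checks | fires when |
|---|---|---|
| total score | 2 | $T_B < 4$; $\lvert T_B - T_S \rvert > 10$ (strict) |
| item regression | 5 | any of items 3–7 endorsed at screener but "never" at baseline |
| usage report | 4 | the baseline denies cannabis use (item 2 "Never"; non-use pattern; 0 times/day on weekday *and* weekend; non-use hours-after-waking) |

Any fired check screens the respondent out (threshold configurable). A
conserving consort accounting tracks every record from screener completion
through eligibility, consent, duplicate exclusion, withdrawal, baseline
completion and the consistency decision.

Because real cohorts carry no ground truth, the package ships a
synthetic-respondent simulator (faithful responders with kappa-calibrated
retest noise, uniform-random responders, bots, straightliners,
eligibility-seeking inflators) plus an analysis layer: group comparisons
(Welch t, 2×2 chi-square), inconsistency frequency tables with
union-correct family rows, per-family descriptives, detection performance
against simulated truth, and an exhaustive-enumeration oracle for the
random-responder flag probability.

## Worked example

```r
library(assistscreen)
instr <- assist_instrument()

scr <- c(item2 = "Weekly", item3 = "Monthly", item4 = "Monthly",
         item5 = "Never", item6 = "Yes, in the past 3 months",
         item7 = "No, never")
total_score(instr, scr)
#> [1] 19

bl <- scr
bl[["item4"]] <- "Never"        # endorsed problem vanished
bl[["item6"]] <- "No, never"    # concern vanished
evaluate_pair(scr, bl,
  usage = list(pattern = "Most or every day", times_weekday = 2,
               times_weekend = 3, hours = "Within 1 hour"),
  instrument = instr)
#> consistency report: totals 19 -> 8, 3 check(s) fired, screened_out
#>             check            screener_value baseline_value
#>  TOTAL_DELTA_GT10                        19              8
#>    ITEM4_TO_NEVER                   Monthly          Never
#>    ITEM6_TO_NEVER Yes, in the past 3 months      No, never
```

The baseline dropped 11 points (more than the allowed 10), and two items
regressed from endorsed to "never": three checks fire, and the respondent
is screened out before randomization.

Simulating a contaminated cohort and running the whole pipeline:

```r
coh  <- generate_cohort(population_spec(n = 500, seed = 42))
flow <- run_flow(coh$records)
consort_summary(flow$consort)
#> Recruitment flow
#>   completed screener         500
#>   ineligible (age/use/score)   4 + 12 + 2 = 18
#>   no_consent                264
#>   duplicate_excluded         28
#>   withdrew                    0
#>   baseline_incomplete        26
#>   consistency assessed       164
#>   screened out                83 (50.6%)
#>   screened in                 81

perf <- detection_performance(coh$truth, flow$reports)
round(perf$per_behavior_flag_rate, 2)
#>            bot       faithful fraud_inflator random_uniform  straightliner
#>           0.92           0.23           1.00           0.79           0.00
```

Eligibility-seeking inflators are always caught, random responders and
bots usually, faithful responders occasionally (honest retest noise), and
straightliners never — they are perfectly consistent across
administrations, the method's documented blind spot.

A command-line interface wraps the same functions
(`inst/cli/assistscreen simulate | screen | report`), reading and writing
delimited text with a documented column dictionary (`records_schema()`).

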