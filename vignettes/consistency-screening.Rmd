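---
title: "Screening out inconsistent respondents with repeated ASSIST administrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening out inconsistent respondents with repeated ASSIST administrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assistscreen)
```

## The problem

Self-report surveys collected over the Internet are exposed to invalid
responding: careless or random answering, straightlining, automated bots,
and deliberate misreporting by people trying to qualify for a paid study.
Even a small contaminated fraction can distort correlations, group
differences and reliability estimates, and post-hoc data cleaning risks
under-powering the final sample. `assistscreen` implements a *real-time*
alternative for two-stage recruitment designs: administer the same
instrument twice — once in the eligibility screener and again at the start
of the baseline interview — and screen out, before randomization, anyone
whose two administrations are inconsistent.

The instrument is the cannabis subscale of the WHO Alcohol, Smoking and
Substance Involvement Screening Test (ASSIST V3.0). Items 2–7 are scored
with item-specific weights and summed to a total in $[0, 39]$, banded as
lower (0–3), moderate (4–26) and high (27–39) risk; brief interventions are
indicated from the moderate band, which is why eligibility and the
consistency rules both pivot on the score-4 boundary.

## The rule engine

For a screener administration $S$ and baseline administration $B$ with
totals $T_S, T_B$, the engine evaluates eleven atomic checks in three
families:

* **Total score** (2): $T_B < 4$ (the respondent no longer meets the
  moderate-risk floor), and $|T_B - T_S| > 10$ (strict: a change of exactly
  10 passes; a 10-point swing is the largest change compatible with
  expected retest error, since a one-step answer change moves the total by
  one to four points per item).
* **Item regression** (5): any of items 3–7 changed from *endorsed* at
  screener (anything other than "Never"/"No, never") to the "never" option
  at baseline. A mere reduction ("Weekly" to "Monthly") does not fire.
* **Usage report** (4): the baseline denies cannabis use outright — item 2
  = "Never", the weekly-pattern probe at its non-use option, zero times per
  day on *both* weekday and weekend, or the hours-after-waking probe at its
  non-use option.

Item 2 regressing to "Never" is grouped with the usage-report family: it is
a denial of use, not a symptom regression, so the item-regression family
covers items 3–7 only. All checks are always evaluated (no short-circuit),
which is what makes per-check frequency tables and the distribution of
fired-check counts meaningful. The default decision rule screens out on
*any* fired check; the threshold, the score floor and the delta bound are
all configurable but default to 4 / 10 / 1.

The weight table is the published WHO V3.0 cannabis table (item 2: 0/2/3/4/6;
item 3: 0/3/4/5/6; item 4: 0/4/5/6/7; item 5: 0/5/6/7/8; items 6–7: 0/3/6
attached to labels). The constructor asserts its anchors — "Weekly" scores
4 on item 2 and 7 on item 5, and the maximum attainable total equals 39 —
and refuses to build an instrument that breaks them. For items 6 and 7 the
displayed option order is not the weight order ("Yes, in the past 3 months"
outranks "Yes, but not in the past 3 months"), so weights attach to labels,
never to display positions.

The three usage-pattern probes are asked alongside the baseline
re-administration; their published stems do not come with fixed option
lists, so the option labels (and the one canonical non-use label each) are
instrument *configuration*, declared in the YAML config and replaceable.

## The recruitment pipeline

`run_flow()` routes each record through a fixed stage order — age ≥ 18,
cannabis use in the previous three months, screener total ≥ 4, consent,
duplicate exclusion, withdrawal, baseline completion, consistency
assessment — and assigns exactly one terminal stage per record. Eligibility
sub-criteria are tested age → use → score so that a record failing several
is attributed to the first; that convention is what makes per-stage exit
counts sum to the number of eligibility exits. The `consort_table`
constructor enforces conservation (entrants = exits + continuers at every
stage) and refuses non-conserving tables. `replay_consort()` runs the same
accounting from printed aggregate exits, so a published consort chart can
be verified without record-level data. Percentages are rounded half-up to
one decimal, the usual reporting convention.

Partial baselines (any missing baseline item or usage probe) are routed to
the baseline-incomplete exit and never partially scored — an incomplete
response is an error at scoring level by design.

## The simulator

Real screened-out cohorts carry no ground truth about *why* a respondent
was inconsistent. The simulator exists to supply that label. Five behaviour
profiles are implemented:

* **faithful** — the screener realizes a latent severity; the baseline
  repeats each item with probability `p_agree` and otherwise drifts one
  display position (reflecting at the ends). Drift is local rather than a
  resample because retest noise comes from remembering or forgetting
  details between administrations, not from answering anew. A faithful
  user with positive severity never flips item 2 to "Never": denial of use
  is not retest noise, so both the drift step and the severity allocation
  protect the endorsed state of item 2.
* **random_uniform / bot** — every option equiprobable, administrations
  independent.
* **straightliner** — the same display position everywhere on both
  administrations.
* **fraud_inflator** — baseline at true (typically low) severity, screener
  inflated by a fixed number of display positions per item: the
  eligibility-seeking profile the delta and regression rules target.

Latent severity is realized at item level by randomized incremental
allocation along each item's weight-sorted options until the target total
is reached or bracketed within one step; there is no published item-level
generative model, so this keeps totals close to the latent draw while
leaving item patterns variable.

**Noise calibration.** The instrument's cited test–retest reliability is a
per-item kappa range of 0.43–0.72 (mean 0.64). The default `p_agree` was
chosen by scanning candidate values on 6,000 simulated pairs (severity
drawn from the eligible population) and freezing the value whose per-item
kappas sit inside that band: `p_agree = 0.75` yields kappas of roughly
0.61–0.68 with mean ≈ 0.65. Higher agreement probabilities (0.85–0.90)
push kappa above the published ceiling because disagreement under local
drift always lands in an adjacent category.

**Demographics.** Marginals target the recruitment population of an online
cannabis brief-intervention trial: realized mean age 37.5 (the parent
normal uses location 34.7 and scale 13.5 because truncation at 18 shifts
the realized mean up by almost three years; truncation also narrows the
realized SD to ≈ 11.3), 36.7% male, 57.8% with post-secondary education,
55.4% low income, and days-of-use in the past 30 modelled as a near-daily
majority (75% at a truncated normal around 29) plus a lighter-use tail
(mean 10), realizing a mean of ≈ 23 days. Stage-attrition rates default to
the empirical fractions of the motivating recruitment flow (consent
≈ 44.5%, duplicates ≈ 11.2%, withdrawal ≈ 0.4%, baseline completion
≈ 84.4%).

**Reproducibility.** Each record draws from its own RNG substream derived
from the cohort seed and the record index, so a fixed seed reproduces a
cohort byte-for-byte and generating a smaller cohort with the same seed
yields a prefix of the larger one.

**What the simulator does not capture.** Behaviour labels are scenario
tools, not estimates of any real cohort's composition; the mixture default
is a plausible stress-test scenario, nothing more. Demographics are drawn
independently of behaviour and severity, whereas real invalid responding
correlates with age and usage patterns. Response times, recall dynamics,
and free-text answers are not modelled. Passing tests therefore
demonstrate that the *method* behaves as specified under controlled
contamination — not that any particular real cohort contains a given
fraction of invalid respondents.

## Verification design

Two independent routes check the rule engine:

* On a reduced instrument (items 2 and 5 plus the item-2 denial check) the
  paired response space is small enough to enumerate exhaustively;
  `random_flag_oracle()` re-evaluates the predicates directly on ordinal
  matrices, never through `evaluate_pair()`, and the test suite compares
  the two implementations decision-by-decision over every eligible pair.
* In Monte Carlo mode the oracle reports a standard error, and estimates
  at $n = 10^5$ agree with the exact enumeration within three standard
  errors; an all-random simulated cohort routed through the full pipeline
  converges to the same probability.

A known blind spot is asserted rather than hidden: straightliners are
perfectly consistent across administrations, so cross-administration
checks can never flag them (sensitivity 0 on an all-straightliner cohort).
Detecting them requires within-administration indices (longstring,
response-time), which are out of scope here.

## Statistical conventions

Group comparisons use Welch's unequal-variance t-test by default (group
sizes and SDs differ in screened-in/screened-out comparisons; a pooled
option exists) and 2×2 chi-square without continuity correction (group
sizes in the hundreds; Yates correction available by flag). Tests are
two-sided; no multiplicity adjustment is applied; p-values below 0.001 are
displayed as "< 0.001". `summary_ttest()` computes the same Welch test
from printed means/SDs/sizes so published table cells can be verified
without raw data. Under the null the type-I error of the comparison is
calibrated at the nominal 5% (checked over 1,000 replicates).

## Problem sizes used in the test suite

Kappa calibration uses 10,000 simulated pairs; Monte Carlo oracle checks
use $10^5$ draws; the p_agree monotonicity grid uses 5,000 pairs per
point; simulated cohorts in tests range from 100 to 4,000 records. These
sizes put Monte Carlo error well below every asserted margin while keeping
the default test run fast.

## Known limitations

* The consistency method flags *inconsistency*, not invalidity: faithful
  respondents with honest retest noise are sometimes flagged (the
  noiseless-faithful flag rate is exactly 0, but at kappa-calibrated noise
  a substantial minority of faithful respondents fire at least one check —
  the inherent sensitivity/specificity trade-off of any one-strike rule).
  The decision threshold is configurable for designs that prefer a
  two-strike rule.
* Straightliners and any other *consistent* invalid pattern are invisible
  by construction.
* Usage-probe option lists are configuration, not validated content; sites
  adapting the probes should keep exactly one canonical non-use option per
  probe.
* The scoring engine covers the cannabis subscale's weights; other ASSIST
  substances require their own validated weight tables, declared via the
  YAML instrument config.
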