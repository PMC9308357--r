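---
title: "Mirror-image analysis of psychiatric hospitalisations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mirror-image analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrorimage)
```

## The design

A mirror-image study evaluates an intervention from routine records by
comparing each service user's outcomes in a post-index period (during the
intervention) against a pre-index period of identical length immediately
before it. The index is the individual intervention start date. Because the
comparison is within-person, time-invariant characteristics — diagnosis,
sex, long-standing illness severity — cannot confound it; the price is
vulnerability to *time-varying* structure, above all regression toward the
mean when the intervention tends to start right after an outcome-related
event such as a hospital discharge.

This package implements that design for two outcomes per window: the number
of inpatient psychiatric admissions and the number of hospitalised
person-days. Both are pooled across users and compared as an incidence rate
ratio (IRR).

## Conventions and assumptions

**Half-open intervals.** Every date interval is `[start, end)` and a
duration is `end − start` days. The pre window `[index − L, index)` and
post window `[index, index + L)` therefore partition the timeline with no
double-counted day; the index day itself is post-index, since support is
active from the start date.

**Window lengths.** The primary ("utilisation period") analysis uses each
user's own episode length, censored administratively for episodes still
running at the study cut-off. Fixed 90-, 180-, 270- and 365-day windows are
analysed in addition; a user enters a fixed length only if their episode
covers it in full, so the eligible sets are nested (every 365-day user is
also a 90-day user).

**Event counting.** An admission is attributed to a window by its admission
date alone. Person-days are counted on the *union* of a user's stay
intervals clipped to the window: a stay admitted before the window (a
"censored stay") contributes its in-window days but no event; a stay
straddling the index contributes one pre-index event, pre-index days to the
pre window and post-index days to the post window. Stays with no recorded
discharge are closed at the censor date before clipping. We considered
counting both admission and discharge days as hospitalised (closed
intervals) but kept the half-open rule for consistency with the rest of the
arithmetic; absolute person-day totals shift by at most one day per stay
under the alternative, and ratios barely move.

**Cohort selection.** From all episodes starting in the study window, the
flow keeps per user the earliest episode (ties broken by smallest record
id, with a warning), drops all episodes of users with recorded service use
before the window, and drops episodes shorter than the minimum duration
(default 30 days; an exactly-30-day episode is included, reading "less
than" literally). Selection is idempotent, order-invariant, and conserving:
every extracted record lands either in the cohort or in the per-record
exclusion map.

## The estimator

For pooled counts $a$ (post) and $b$ (pre) over person-times $T_1, T_0$,

$$\widehat{\mathrm{IRR}} = \frac{a/T_1}{b/T_0},\qquad
\exp\!\left(\ln \widehat{\mathrm{IRR}} \pm z_{1-\alpha/2}\sqrt{1/a + 1/b}\right).$$

This is the simple pooled analysis conventional in self-controlled studies:
it treats both totals as independent Poisson counts and ignores that the
same individuals contribute to both sides. That exaggerates standard
errors (conservative) and sidesteps per-user zero counts. Person-days are
deliberately run through the same formula even though days within one stay
are far from independent — the package replicates the field's convention
rather than improving on it; no clustered or conditional variance
correction is applied by default. An exact conditional (binomial) interval
is available via `rate_ratio(..., method = "exact")`.

Zero-count policy: `pre = 0` leaves the ratio and interval undefined
(rendered "—" in text output, empty in CSV, `null` in JSON); `post = 0`
with `pre > 0` gives a point estimate of 0 with an undefined interval.
Significance is the CI excluding 1 at the chosen `alpha` (default 0.05;
`z = 1.959964`). Display rounding is two decimals; person-years use 365.25
days and one decimal.

## The lookback sensitivity analysis — and its own bias

`run_sensitivity()` removes every user with at least one admission *event*
in the half-open lookback `[index − 90, index)` and re-runs all analyses.
A stay that merely remains open inside the lookback does not trigger
exclusion. This targets regression toward the mean: if the intervention is
often arranged at discharge, pre-index rates are transiently elevated near
the index and a pre/post decline appears without any effect.

Two structural consequences are worth understanding:

1. *Zero pre-counts by construction.* With lookback $\ell$ and a mirror
   length $\ge \ell$, the filtered cohort has exactly zero admissions in
   the first $\ell$ pre-index days, so the $\ell$-day admissions IRR is
   undefined whenever it is computed at the lookback length itself.
2. *Upward bias of the sensitivity estimator.* The filter conditions on
   zero events in the lookback but keeps the full pre person-time, so even
   with no triggering mechanism at all the expected pre rate of the
   retained users is deflated by roughly $(\mathrm{dur} - \ell)/\mathrm{dur}$
   and the sensitivity IRR sits *above* the primary one. Our simulations
   measure this directly (truth 1.0 yields sensitivity means around 1.6 for
   typical episode lengths). The sensitivity estimate is therefore a
   deliberately conservative probe — "does the effect survive removing the
   users most exposed to regression toward the mean?" — not an unbiased
   re-estimate, and primary and sensitivity estimates should *not* be
   expected to agree even under a pure null.

The package's Monte-Carlo experiment (`bias_experiment()`) reproduces the
qualitative picture: with index triggering on and a true ratio of 1, the
primary admissions IRR is spuriously far below 1 while the sensitivity
estimate lies much closer to 1; pushing the trigger delay beyond the
lookback defeats the filter, since the triggering admission then predates
the lookback window entirely.

## The synthetic-cohort generator

`simulate_cohort()` exists so that every pipeline stage is testable without
patient records. Per user it draws:

- a utilisation duration from a log-normal distribution truncated to
  `[36, 960]` days with median ≈ 266 days and log-SD 0.55 — chosen so the
  realised duration distribution echoes a typical supported-housing
  caseload (mean ≈ 310 days, heavy right tail);
- a start date uniform over the study window, with administrative
  censoring of episodes running past the cut-off;
- admission events as homogeneous Poisson processes at 0.56 per
  person-year pre-index (about 68 admissions per 122 person-years) and at
  that rate times `effect_rate_ratio` (default 0.41) post-index;
- integer stay lengths (≥ 1 day) from a geometric distribution with mean
  31 days, scaled by `stay_effect_ratio` (default 0.92) post-index —
  geometric because no stay-length distribution is better motivated by the
  data the design consumes, and memorylessness keeps clipping analysis
  simple;
- optionally, with probability `trigger_probability` (default 0; a
  scenario switch, not a property of the null cohort), one extra pre-index
  stay whose discharge falls within `trigger_delay_days` before the index,
  modelling an intervention begun as follow-up to a hospitalisation.

Stays of one user never overlap: lengths are resampled against the gap to
the next admission and truncated as a last resort. Stays running past the
censor date are emitted with an empty discharge date, exercising the
open-stay clipping path. Output is byte-identical for a fixed seed.

What the generator does *not* emulate: seasonal and calendar structure,
diagnosis-specific admission dynamics, dependence between admission risk
and stay length, between-user heterogeneity in rates (no frailty), or
hospitalisations in facilities outside the record system. Passing tests on
synthetic cohorts therefore validate the *arithmetic and the estimator*,
not the epidemiology of any real caseload.

Two calibration facts from the generator, measured in the test suite: the
pooled admissions IRR recovers `effect_rate_ratio` well (mean over 100
replicates of 2,000 users within a few percent of truth), while the pooled
person-day IRR sits somewhat above `effect_rate_ratio × stay_effect_ratio`
because pre-index stays straddling the index spill days into the post
window whereas post-index stays ending past the post window lose theirs —
an asymmetry inherent to the counting rules, not a bug.

## Numerical and degenerate-input choices

- Dates are parsed strictly as ISO-8601 and held as `Date`; all interval
  arithmetic is integer day counts, so there is no floating-point drift.
- Empty cohorts, empty admission tables and empty eligible sets are legal
  everywhere and yield zero counts or undefined statistics, never errors.
- Ties between two episodes of one user starting the same day are broken
  by record id for determinism and warned about.
- The analysis path contains no randomness; two runs on identical inputs
  write byte-identical artifacts. Randomness lives only in the simulator,
  fully governed by its seed.
- Simulation problem sizes used in the shipped tests — up to 2,000 users
  and a few hundred replicates — were chosen as the point where Monte-Carlo
  error is small against the tolerances being asserted.

## Known limitations

- The pooled estimator's confidence intervals ignore within-person pairing
  and overdispersion of person-days; they are conservative by construction
  and should not be read as efficient.
- Admissions outside the supplied table are invisible; if out-of-system
  hospitalisations are common, both periods are undercounted and the
  direction of the net bias depends on how referral patterns change at the
  index.
- Ending observation at withdrawal can favour the intervention if
  withdrawal is outcome-related (e.g. episodes ending in a hospitalisation);
  the package measures, per cohort, how many censored and withdrawn
  episodes there are, but cannot correct for the mechanism.
- One utilisation episode per user is assumed after selection; concurrent
  episodes and sub-day resolution are out of scope.
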