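# mirrorimage

Mirror-image (self-controlled) analysis of inpatient psychiatric
hospitalisation around the start of a community mental-health intervention,
built for service evaluations that work from routinely collected utilisation
and admission records — for example Independent Supported Housing (ISH)
programmes for people with severe mental illness.

In a mirror-image design each service user's intervention start date is the
*index*, and outcomes in the post-index period are compared with an
immediately preceding pre-index period of equal length, so every user acts
as their own control and time-invariant confounding cancels. For an outcome
with pooled event counts $a$ (post) and $b$ (pre) observed over person-times
$T_1$ and $T_0$, the package estimates the incidence rate ratio

$$\mathrm{IRR} = \frac{a / T_1}{b / T_0}, \qquad
\mathrm{CI}_{95\%} = \exp\!\left(\ln \mathrm{IRR} \pm z_{0.975}
\sqrt{\tfrac{1}{a} + \tfrac{1}{b}}\right),$$

the simple pooled analysis conventional in self-controlled studies (it
ignores the pairing, which is conservative, and with equal person-time the
IRR reduces to $a/b$). Two outcomes are counted per mirror window: the
number of admissions (attributed by admission date) and hospitalised
person-days (stays clipped to the window, so "censored" stays straddling a
boundary contribute their in-window days). All intervals are half-open
`[start, end)`.

The package covers the whole pipeline:

- **Cohort selection** — `read_utilisations()`, `read_admissions()`,
  `select_cohort()`: first-episode-per-user rule, exclusion of users with
  prior service use, minimum-duration filter, administrative censoring of
  ongoing episodes, and a step-by-step selection report.
- **Mirror windows and counting** — `mirror_windows()`, variable-length and
  fixed 90/180/270/365-day variants (a user enters a fixed length only if
  their episode covers it), `count_admissions()`, `count_person_days()`.
- **Estimation** — `rate_ratio()`, `analyze_period()`, `analyze_periods()`,
  `quarterly_admission_proportions()`, `run_analysis()` (writes CSV/JSON
  artifacts).
- **Sensitivity analysis** — `exclude_recent_admitters()`,
  `run_sensitivity()`: drop every user with an admission in the 90 days
  before index and re-run everything, targeting regression toward the mean.
- **Synthetic cohorts** — `simulation_params()`, `simulate_cohort()`,
  `bias_experiment()`: per-user Poisson admission processes, geometric stay
  lengths, a post-index rate-ratio effect, optional index triggering after
  a discharge, and administrative censoring, so every stage is testable
  without patient records.

A thin command-line front end is installed as `exec/mirrorframe`
(subcommands `analyze`, `simulate`, `fixtures`).

## Worked example

`fixture_reference_cohort()` builds a deterministic synthetic cohort of 144 users
whose records aggregate to known pooled totals:

```r
library(mirrorimage)
fx <- fixture_reference_cohort()
res <- run_analysis(fx$utilisations, fx$admissions, cohort_config())
format_results_table(res$results[res$results$period == "utilisation period", ])
#> analysis    outcome      period                  n   pre  post    IRR     lo     hi
#> primary     admissions   utilisation period    144    68    28   0.41   0.27   0.64
#> primary     person_days  utilisation period    144  2113   802   0.38   0.35   0.41
#> sensitivity admissions   utilisation period    120    26    21   0.81   0.45   1.44
#> sensitivity person_days  utilisation period    120  1089   622   0.57   0.52   0.63
```

Reading: across the whole utilisation period, pooled admissions fall from
68 pre-index to 28 post-index over equal person-time — an IRR of 0.41
(95% CI 0.27–0.64), a significant reduction — and hospitalised person-days
fall by a factor 0.38. After excluding the 24 users with an admission in
the 90 days before index, the admissions IRR rises to 0.81 and is no longer
significant, the signature of regression toward the mean; the person-day
reduction (0.57) survives the filter.

Single statistics work directly from pooled counts:

```r
rate_ratio(28, 68, 1000, 1000)
#> IRR 0.41 (95% CI 0.27–0.64)  post 28 / pre 68 events
person_days_to_years(44690)
#> [1] 122.4
```

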