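# mmdews

Early-warning signals of physiological collapse from routine blood
panels: an R implementation of the **Moving Multivariate Distance
(MMD)** and the analysis pipeline around it.

## The problem and the statistic

Chronic hemodialysis patients give blood roughly every two weeks for
years, yet there is no reliable indicator of impending physiological
collapse. Critical-transition theory predicts that a system losing
resilience fluctuates more before it tips; most such early-warning work
is univariate, while physiology is a correlated network. MMD makes the
variance-increase signal multivariate: where classical Mahalanobis
distance measures how far a biomarker profile sits from a population
norm,

$$D(x) = \sqrt{(x-\mu)^\top S^{-1}(x-\mu)},$$

MMD measures the covariance-weighted size of the step an *individual*
takes between consecutive visits,

$$\mathrm{MMD}_t = \sqrt{(x_t - x_{t-1})^\top S^{-1}(x_t - x_{t-1})},$$

with $S$ the population covariance of the standardized biomarkers. A
rising MMD means rising intraindividual multivariate variability — an
early-warning signal that, in survival analysis, predicts death.

The package is written for biostatisticians and quantitative
epidemiologists working with longitudinal laboratory panels. It provides:

* **Cohort handling** — long-format CSV readers/writers, the sequential
  entry-filter cascade (initial-dialysis exclusion window, minimum
  visits, panel completeness) with an auditable exclusion report, plus
  loss-to-follow-up, kidney-transplant and 65+ subsets.
* **Biomarker sets** — the six built-in panels (blood-schedule sets at
  two-week/one-month/four-month intervals; O2-transport, kidney-health
  and mineral-bone-disease systems), variance-stabilizing transforms,
  whole-population z-scoring, and gap-window visit pairing.
* **MMD core** — pooled covariance plus three sensitivity variants
  (variance-only, near-death, far-from-death), vectorized distances,
  the half-minimum zero rule and log-MMD.
* **Survival analysis** — counting-process rows with log-MMD as a
  time-varying covariate, Cox models with cluster-robust variance, the
  scale-free **HR95** effect size (hazard ratio between the 97.5th and
  2.5th log-MMD percentiles), and Schoenfeld-residual PH diagnostics.
* **Trends and negative control** — half-year pre-event trend curves
  with confidence bands, and a shuffled-visit permutation null that
  destroys temporal ordering while preserving dates, profiles and the
  covariance model.
* **Synthetic cohorts** — a seeded hemodialysis-like simulator
  (correlated random-walk biomarkers, jittered bi-weekly visits,
  majority-death outcomes, optional pre-death variance inflation or a
  hazard-linked death mechanism) for calibration and power studies.

## Worked example

```r
library(mmdews)

sim    <- simulate_cohort(sim_config(n_patients = 120, seed = 42))
cohort <- apply_entry_filters(sim$cohort)
exclusion_report(cohort)
#> # A tibble: 3 × 4
#>   rule                       n_patients n_visits n_patients_remaining
#> 1 initial_exclusion_window           19     1376                  101
#> 2 min_visits                          4        6                    97
#> 3 incomplete_biomarker_panel          0        0                    97

set2w <- builtin_biomarker_sets()$two_weeks
tbl   <- compute_mmd_table(cohort, set2w)
fit   <- fit_cox_hr95(build_survival_rows(tbl, cohort))
fit
#> <hr95_fit> 97 patients, 61 events, 5572 intervals
#>   log-MMD beta = 3.3165 (robust SE 0.3038)
#>   HR95 = 272.48 [99.56, 745.73]  (percentile gap 1.691)
#>   PH global p = 0.001

trend_table(tbl, cohort, "deceased")
#> # A tibble: 10 × 6
#>   group      bin bin_mid_years mean_mmd ci_halfwidth     n
#> 1 deceased     1          0.25    0.595       0.0214   470
#> 2 deceased     2          0.75    0.410       0.0167   375
#> 3 deceased     3          1.25    0.341       0.0155   321
#> # …
```

The simulator's default cohort plants a two-fold inflation of step
variability over the last year before death, so the deceased group's
final half-year bin (mean MMD 0.60) sits well above the earlier bins
(~0.3), and log-MMD is a strong hazard predictor: HR95 = 272 means the
death hazard at the 97.5th percentile of log-MMD is ~272 times that at
the 2.5th percentile in this synthetic cohort. On null cohorts
(`inflation_factor = 1, hazard_beta = 0`) the HR95 confidence interval
covers 1 at the nominal rate. `run_analysis()` runs the whole
set-by-variant grid and `autoplot()` draws trend curves, shuffle-null
histograms and forest-style HR95 summaries; `tidy()`/`glance()` give
broom-style summaries. A command-line front end with `simulate`,
`analyze`, `trends` and `shuffle-null` subcommands ships in
`inst/cli/mmd.R`.

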