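---
title: "Moving Multivariate Distance: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moving Multivariate Distance: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(mmdews)
library(dplyr)
```

## The statistic

Classical Mahalanobis distance measures how far a biomarker profile $x$
sits from a population norm $\mu$ under the biomarker covariance $S$:

$$D(x) = \sqrt{(x - \mu)^\top S^{-1} (x - \mu)}.$$

The Moving Multivariate Distance (MMD) replaces the population norm with
the *same individual's previous visit*:

$$\mathrm{MMD}_t = \sqrt{(x_t - x_{t-1})^\top S^{-1} (x_t - x_{t-1})},$$

so it measures the size of the step an individual takes through
physiological space between consecutive visits, weighted by the
population correlation structure. A sustained rise in MMD is an
early-warning signal of the variance-increase type: a system losing
resilience recovers more slowly from perturbations and therefore
fluctuates more. $S$ is still estimated at the population level, from all
standardized visit vectors (*levels*, not differences), and is assumed
stationary — a strong assumption probed by the covariance variants below.

We use the square-root (distance) convention for both formulas. A squared
option exists (`squared = TRUE`), but after the log transform used in the
survival model the two differ only by a factor of 2 absorbed into the Cox
coefficient, so the choice is immaterial for inference; a regression test
asserts exactly that invariance.

## Data model and cohort filters

Input is a long table of visits (patient, date, biomarker, value) plus a
patient table (sex, diabetic status, birth date, outcome). Outcomes are
death, censoring (loss to follow-up or study end), or kidney transplant;
the event date is the death, last-contact or transplant date
respectively.

The entry filters mirror a chronic-hemodialysis study design:

* the first 183 days ("6 months") after dialysis initiation are discarded
  — initiation is a critical transition in its own right and would
  contaminate the signal;
* patients left with fewer than 3 visits are excluded;
* patients missing a required biomarker entirely are excluded.

The cascade is sequential and each patient is counted once, at the first
rule that removes it, so the exclusion report adds up. Loss-to-follow-up
subsets (last visit within 30/60/90/183/365 days of death — deceased
patients only), a 65+ subset (age at last data collection), and a
kidney-transplant subset (no dialysis visit and no death within 730 days
of transplant) reproduce the standard sensitivity analyses. Day
equivalents are fixed constants: 6 months = 183 d, 3 months = 92 d,
2 years = 730 d, half-year = 182.625 d — the source design specifies
month/year language only, so these are package conventions, chosen once.

When no first-dialysis date is supplied the first observed visit stands
in for it; the date actually used is written back to the patient table so
re-filtering is idempotent.

## Biomarker sets, transforms, standardization, pairing

Three blood-schedule panels (`two_weeks`, 11 markers, gap window 12–16 d;
`one_month`, 15 markers, 25–35 d; `four_months`, all 16 incl. albumin,
100–140 d) and three physiological panels (`o2_transport`,
`kidney_health`, `mbd`) are built in; each physiological panel uses the
window of its least frequently measured member. WBC, RDW and glucose are
log-transformed and platelet count square-rooted (variance
stabilization); natural log is used — the base is immaterial after
z-scoring. Every marker is then z-scored against the *entire population*
mean and SD (n−1), fitted once on the filtered cohort and reused for all
subsets so they stay comparable.

Pairing interprets "one visit to the next" as consecutive *eligible*
visits: a visit missing a required marker is skipped and the gap is
measured between the remaining neighbours, then filtered by the set's
window. This keeps the maximum amount of data while the window bounds the
realized time step. MCH/MCHC/MCV are arithmetic functions of hemoglobin,
RBC and hematocrit; `drop_redundant = TRUE` removes them, and the
covariance constructor refuses matrices with reciprocal condition number
below 1e-10 rather than silently regularizing.

## Covariance variants

* `pooled` — sample covariance of all standardized visit vectors (the
  correlation matrix, up to sampling error);
* `identity_offdiag` — off-diagonals zeroed, variances kept (MMD becomes
  a Euclidean norm on standardized differences);
* `near_death` — estimated only from deceased patients' visits within
  92 days of death;
* `far_from_death` — only visits at least 730 days before death.

The death-window variants are restricted to deceased patients (a death
date is required to position the window); including censored patients'
late visits would conflate administrative timing with physiology. The
n−1 denominator is used throughout; at cohort scale the choice is
immaterial and it matches the standardization convention.

## Zero MMD and the log transform

Identical consecutive profiles give MMD exactly 0, which has no
logarithm. Zeros are replaced by half the *individual's* minimum positive
MMD before logging; an individual whose MMDs are all zero has no positive
minimum and is dropped from the survival input with a warning.

## Survival model and HR95

Each log-MMD observation becomes a counting-process row: the interval
opens at its visit (years since the patient's first retained visit) and
closes at the next observation or the event/censoring date, with the
event flag only on a deceased patient's final interval. The Cox model
adjusts for sex, diabetic status and a cubic B-spline of age (default
4 df, `splines::bs`), uses Efron ties, and a cluster-robust sandwich
variance over patients since each patient contributes many rows.

The time axis deserves a note: "years before death or last contact" can
be read as reverse time or as forward follow-up time. We use forward
follow-up time with delayed entry, which reproduces the described
structure (repeated observations, per-patient clustering) without the
pathologies of reverse-time risk sets; this is a deliberate design
choice.

The effect size is HR95 $= \exp\{\hat\beta\,(q_{97.5} - q_{2.5})\}$, the
hazard ratio between the 97.5th and 2.5th percentiles of the pooled
observation-level log-MMD — a scale-free summary for a continuous
covariate. Percentiles are computed on the analysis sample at hand, and
the CI scales the robust SE by the same gap. Proportional hazards are
checked with scaled Schoenfeld residuals (`survival::cox.zph`, KM time
transform by default).

## Trends and the shuffled-visit negative control

Trend tables average MMD in half-year bins (182.625 d, right-closed at
the anchor) counted back from death / last contact / transplant, out to
5 years, with a normal-approximation 95% band (half-width 0 for
single-observation bins).

An apparent pre-death rise could in principle be a boundary artefact. The
negative control permutes, within each patient, which visit profile sits
on which of that patient's own visit dates: dates (and hence the
gap-window structure) are preserved and only temporal ordering is
destroyed, so standardization and the covariance model are exactly
unchanged and are reused across replicates. The summary statistic is our
formalization of the check: within each patient, the mean MMD in the
last half-year bin minus the mean over all earlier in-horizon bins,
averaged over patients observed in both windows. The within-patient form
matters: shuffling a drifting series pairs temporally distant profiles
and inflates distances by a patient-specific factor that grows with
follow-up length, so *pooled* bin contrasts are biased under the null,
while the per-patient contrast is exactly centred at zero by
within-patient exchangeability. The add-one estimator
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + R)$ gives an exactly valid
permutation p-value.

## The synthetic cohort generator

No public hemodialysis dataset with this structure exists, so the
package ships a simulator whose defaults encode the study conditions it
emulates: 763 patients, 68.8% deaths and 19.5% transplants, bi-weekly
visits with ±2-day jitter and 10% missed visits, log-normal follow-up
with median ~2.1 years, 16 correlated biomarkers of which the 11
two-week markers appear at every visit (monthly markers on every second
scheduled visit, albumin on every eighth), and marker locations/scales
matching a typical panel in clinical units.

Each patient's latent transformed-scale profile is a correlated random
walk: initial state $N(0, R)$, innovations
$N(0, (\sigma\, m_t\, e^{\gamma})^2 R)$ with exchangeable correlation
$R$ ($\rho = 0.3$), step SD $\sigma = 0.2$, a patient-level log-scale
frailty $\gamma \sim N(0, 0.3^2)$, and $m_t$ ramping linearly from 1 to
$f = 2$ over the last 365 days before death. A random walk (not
mean-reverting) is the simplest process whose *step* distribution — the
thing MMD measures — is exactly controllable; because the initial state
and the innovations share $R$, pooled level covariance stays proportional
to the innovation covariance and estimated MMD differs from the
generating step distance only by a constant log-shift. Values are
emitted in clinical units by inverting the variance-stabilizing
transforms, so the pipeline's transform step recovers the latent scale
exactly.

Death timing is either *scheduled* (outcome and date pre-drawn, the
inflation ramp anchored to the death date — used for trend and
calibration studies) or *hazard-linked*: the hazard over each
inter-visit interval is
$\lambda_0 \exp\{\beta (z - \log\sqrt{p})\}$ where $z$ is the true log
step distance of the most recent *in-window* visit pair. Restricting
covariate updates to in-window pairs makes the generating covariate the
same observable step function a counting-process fit reconstructs;
without this the fit sees a stale covariate on out-of-window gaps and
$\hat\beta$ is attenuated. Hazard-linked recovery studies therefore also
set `miss_prob = 0`, since a missed visit likewise de-synchronizes the
generating and fitted covariate processes.

All randomness flows from one seed; patient $i$ draws every one of its
quantities from the substream seeded by
$(48271\,s + 9973\,i) \bmod 2147483629$, so the first $k$ patients of a
larger cohort reproduce a smaller one exactly.

What the generator does *not* emulate: mean-reverting homeostasis,
session-level pharmacodynamics, lab batch effects, informative visit
timing (sicker patients visiting more often), or real marker
cross-correlation structure beyond exchangeability. Passing calibration
and recovery tests on these cohorts shows the estimator chain is
internally correct, not that real cohorts satisfy its assumptions.

## Numerical conventions and degenerate inputs

Inverses come from the Cholesky factor after a symmetry projection
$(S + S^\top)/2$; matrices with rcond < 1e-10 are rejected with a hint
to drop the redundant red-cell indices. Squared distances are clipped at
0 before the root to absorb −1e-16-type noise. Ties in event times use
Efron's approximation. A zero-length final interval (an observation dated
exactly at the event) is folded into the preceding row. Quantiles use R's
default type-7 definition. Constant adjustment covariates are dropped
from the Cox formula with a message rather than producing NA
coefficients.

## Worked example

```{r example}
sim <- simulate_cohort(sim_config(n_patients = 120, seed = 42))
cohort <- apply_entry_filters(sim$cohort)
exclusion_report(cohort)

set2w <- builtin_biomarker_sets()$two_weeks
tbl <- compute_mmd_table(cohort, set2w)
fit <- fit_cox_hr95(build_survival_rows(tbl, cohort))
glance(fit)

trend_table(tbl, cohort, "deceased")
```

With the default pre-death variance inflation (`inflation_factor = 2`)
the deceased group's final half-year bins rise well above the earlier
bins and HR95 is far above 1; setting `inflation_factor = 1` and
`hazard_beta = 0` produces a null cohort on which the CI covers 1 at the
nominal rate (the test suite checks both, plus recovery of a planted
hazard coefficient).

## Monte-Carlo problem sizes

The calibration and power studies in the test suite use: 100 null
cohorts of 200 patients (coverage and PH type-I error), 50 hazard-linked
cohorts of 300 patients at $\beta = 0.8$ (recovery), 100 inflation
cohorts of 100 patients (trend signal), and 25 cohorts × 39 permutations
for each shuffle-null power/centrality study. These sizes are the
package's own study design, balancing Monte-Carlo error against a
single-CPU run.

## Known limitations

* The stationary-covariance assumption is tested only by discrete
  variants, not by a time-varying estimate (deliberately out of scope).
* The exact reverse-vs-forward time encoding of the original design
  cannot be uniquely reconstructed; forward time was chosen and
  documented above.
* HR95 percentiles are computed per analysis sample, not fixed cohort-wide;
  comparisons across subsets therefore compare slightly different
  contrasts.
* Whether "incomplete biomarker data" means never-measured markers or
  too-sparse series is ambiguous; the filter removes only never-measured.
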