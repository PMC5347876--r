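---
title: "Measuring engagement in outpatient HIV care with a clinically adaptive month classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring engagement in outpatient HIV care with a clinically adaptive month classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eicare)
```

## The measure

Fixed-interval retention measures (visit constancy, two-visits-per-year
rules, maximum-gap rules) treat every patient's expected attendance schedule
as identical. In practice the interval a clinician sets to the next HIV
outpatient appointment depends on the patient's current state: someone newly
diagnosed, recently started on antiretroviral therapy (ART), or showing
virological rebound is recalled within weeks, while a stable suppressed
patient may not be due back for six months. A patient seen every five months
may therefore be perfectly engaged, or repeatedly overdue, depending on their
clinical trajectory.

`eicare` implements a month-level measure that adapts to that trajectory.
Follow-up is divided into 30.4-day months anchored at study entry. Every
month containing at least one attendance marker is a *care episode*; repeat
laboratory tests clustered around one index visit therefore collapse into a
single episode rather than inflating apparent attendance. From each episode's
clinical state a rule table yields the number of months `N` within which the
next episode is expected. The `N` months after the episode are *in care*; any
later month up to and including the month of actual re-attendance is *out of
care*. A patient's engagement (EIC) is the fraction of follow-up months in
care.

In the absence of complete appointment data, dated CD4 counts, viral loads,
haemoglobin measurements and ART start/switch dates stand in as surrogate
markers of attendance. Follow-up is censored at the last recorded marker by
default, so the measure captures intermittent disengagement rather than
terminal loss to follow-up; an administrative end date can extend
classification past the last marker when that is wanted (the shipped worked
example uses an 18-month horizon).

## The rule table

The default configuration (`eic_rule_config()`) encodes standard UK
monitoring practice of the early 2010s. Intervals are whole months; when
several conditions hold at once, the *shortest* interval applies. Two months
is the floor — a visit can fall anywhere inside a 30.4-day month, so a
one-month expectation would be ambiguous — and six months is the routine
maximum.

| Condition at the care episode | Next episode expected within |
|---|---|
| Within 1 month of HIV diagnosis | 2 months |
| AIDS diagnosis this month | 2 months |
| Started ART | 2 months |
| Started a new combination (switch) | 2 months |
| *Not on ART:* CD4 ≤ 350 with any CD4 drop | 2 months |
| *Not on ART:* CD4 ≤ 350, no drop | 4 months |
| *Not on ART:* CD4 351–499 | 4 months |
| *Not on ART:* CD4 ≥ 500, drop ≥ 100 | 4 months |
| *Not on ART:* CD4 ≥ 500, drop < 100, VL ≥ 100 000 | 4 months |
| *Not on ART:* CD4 ≥ 500, drop < 100, VL < 100 000 | 6 months |
| *On ART:* VL > 200 | 2 months |
| *On ART:* VL 51–200, not a blip | 2 months |
| *On ART:* VL 51–200, appears to be a blip | 4 months |
| *On ART:* VL ≤ 50, CD4 ≤ 200 | 4 months |
| *On ART:* VL ≤ 50, CD4 > 200 | 6 months |

A *blip* is a viral load of 51–200 copies/mL whose most recent measured
predecessor was below 50 copies/mL. CD4 is in cells/µL, viral load in
copies/mL. Every threshold and interval is a constructor argument, and the
configuration round-trips through YAML (`write_rule_config()` /
`read_rule_config()`), so the table can track changed guidelines or local
clinic policy without touching code.

## Derived episode state and its edge cases

`build_episodes()` derives, per episode: the lowest CD4 measured that month
and its change from the previous *measured* value; the highest viral load and
its blip status; treatment status and event flags. Several decisions here are
worth making explicit:

* **Carry-forward.** When a month has an attendance marker but no CD4 (or
  viral load), the most recent earlier value is carried forward and flagged.
  Carried values satisfy threshold conditions — a patient seen for a
  haemoglobin check is still scheduled on their last known labs — but never
  generate CD4 drops or blips, which are defined only between measured
  values. This avoids phantom "changes" manufactured from stale data. There
  is no lookback limit on carry-forward.
* **Missing values.** A rule predicate that needs a value that has *never*
  been observed is simply unsatisfied. If no rule at all fires (no usable
  CD4, no viral load, no event flags — e.g. an on-ART patient with a
  suppressed viral load but no CD4 ever measured), a configurable fallback of
  4 months applies, chosen as the midpoint of the rule set, and the firing is
  counted and reported. This is a deliberate, visible default rather than an
  imputation.
* **Below-detection viral loads.** A value reported as "<X" is stored as X
  with a flag and behaves in comparisons as "just below X": "<50" satisfies
  both ≤ 50 and < 50, and never > 50. This matches the table's thresholds
  without guessing the unobserved true value.
* **Same-date start and switch.** A regimen switch recorded on the ART start
  date is treated as the start only.
* **AIDS diagnoses** fire their rule only in the episode month containing the
  diagnosis date, mirroring the construction of the
  within-one-month-of-diagnosis rule. Whether the condition should persist is
  genuinely open; `eic_rule_config(aids_persistent = TRUE)` provides the
  other reading.
* **Month 0** (the entry episode's month) is not itself classified: follow-up
  months are counted from 1, and the re-attendance month itself is labelled
  out of care when it falls beyond the expectation window.
* **Birth dates** supplied at year-month precision are imputed to the 15th;
  this only affects time-updated age strata.

## Person-month analytics

`person_month_table()` evaluates time-updated covariates at each month's
midpoint (entry + (month − 0.5) × 30.4 days): age group (<25, 25–45, >45
years), current ART status, nadir and current CD4 group (<200, 200–349,
≥350 cells/µL, from measured values only), calendar period (2000–2003,
2004–2007, 2008–2012) and time since entry (<1, 1–5, 5–10, >10 years).
`stratified_proportions()` reports person-month counts and in-care
percentages per level; months whose covariate is undefined appear as an
explicit `"(missing)"` level so levels always partition the person-months.

`fit_association_model()` fits a marginal logistic regression of the monthly
in-care indicator by generalized estimating equations, treating each patient
as a cluster of correlated months. The working correlation is exchangeable —
the standard default for repeated binary outcomes with no natural ordering
effect — and inference uses the robust sandwich variance, which remains valid
when that working structure is wrong. The fitter (`gee_logit()`) uses the
Liang–Zeger moment estimators for the dispersion and the exchangeable
correlation, Fisher scoring for the coefficients, and reports
separation/non-convergence as errors rather than returning silent output.
With an independence working correlation its coefficients equal ordinary
logistic regression and its robust variance equals the HC0 clustered
sandwich, which the test suite verifies against an independent
implementation. Unadjusted results model one covariate at a time; the
adjusted model includes all requested covariates plus clinic. Reference
levels carry an odds ratio of exactly 1; rows missing a modelled covariate
are dropped with a logged count, except ethnicity, whose unknowns are an
explicit category.

## The synthetic cohort and what it can (and cannot) show

`simulate_cohort()` generates loader-compatible cohorts with known
ground-truth engagement. Trajectories are simple parametric forms — linear
CD4 decline before ART (default 60 cells/µL/year) and recovery on ART (80
cells/µL/year, capped), a log-normal untreated viral-load set point (mean
4.5 log₁₀), step-wise suppression three months after ART start, occasional
blips (only after two suppressed visits, so the blip rule is genuinely
exercised), rare virological failures answered by a regimen switch, and
haemoglobin-only visits that exercise carry-forward. Visits are scheduled by
applying the *same* rule table to the recorded state, then delayed with
probability `p_delay` by a geometric (or fixed) number of extra months. Every
completed interval therefore has analytically known labels: the first `N`
months in care, the remainder out.

This closed loop is the package's strongest correctness check: with any
parameter setting, classifier output must agree with ground truth
month-for-month, and with no delays every patient must be 100% engaged. It
is equally important to say what passing these tests does *not* show. The
generator's state derivation is intentionally the same as the classifier's,
so agreement validates the windowing and scheduling logic, not the clinical
realism of the trajectories; real cohorts have irregular measurement
schedules, assay changes, transfers between clinics and missingness that is
informative rather than random. Simulation defaults were chosen once as
field-plausible values to make every rule row reachable (a coverage test
asserts each rule identifier fires in a large simulated cohort); they are
not calibrated to any real cohort's marginals.

## Numerical and design choices

* Months are `floor(days / 30.4)`; the entry date is month 0. Visit dates in
  the simulator are placed at `ceiling(30.4 m)` days so they always fall in
  month `m`.
* Episode dates are the first marker date in the month; ART status is
  assessed at the episode date, event flags at month granularity.
* CD4 bands for untreated scheduling use ≤350 / (350, 500) / ≥500 so
  non-integer values cannot fall between rows.
* The GEE exchangeable correlation estimate is clamped to [0, 0.95];
  dispersion and correlation use Pearson residuals with the usual
  degrees-of-freedom corrections.
* Problem sizes in the validation suite were chosen to make the checks sharp
  but cheap: 10⁴ random states for the interval-range property, 10⁴ random
  episode sequences against a brute-force month-walking oracle, a
  1000-patient no-delay cohort for the closed loop, and 200 replicates of a
  100-patient × 18-month cohort with a known month-level odds ratio of 2.0
  for interval-coverage of the estimating-equation fit.

## Known limitations

The measure uses surrogate markers, so visits without any laboratory test
are invisible and engagement is under- rather than over-estimated.
Psychosocial factors and comorbidities, which shorten real scheduling
intervals, are not in routinely collected data and are deliberately out of
scope; the rule table is configurable precisely so such factors could be
added where data exist. Cohort-scale published results (overall engagement
percentages and covariate odds ratios from clinical databases) depend on
access-controlled data: this package reproduces the *machinery* — the same
tables and models from any cohort in its input format — not those numbers.
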