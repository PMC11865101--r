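---
title: "Person-specific subgroup discovery for activity and sleep tracker data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-specific subgroup discovery for activity and sleep tracker data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actisleep)
```

## The analysis problem

Consumer wrist trackers record, for every monitored day, a step count, the
durations of light, moderate and intense activity (classified from
heart-rate zones, in seconds), and the daily totals of light and deep sleep
(day and night combined). Cohorts wearing such devices for months yield
dozens to hundreds of days per person, which makes the *day*, not the
person, the natural sampling unit: one can ask, separately for each
participant, whether physical activity on the preceding days is associated
with that night's sleep duration — and also pool everyone for a group-level
answer.

`actisleep` implements that analysis end to end: lagged feature
construction, a Spearman correlation screen with family-wise error control,
single-condition subgroup discovery on the numeric sleep targets, and a
permutation-based significance assessment of the best discovered subgroup.
Because raw tracker datasets of this kind are rarely depositable, the
package ships a synthetic-cohort generator with the same statistical
skeleton, including optional planted activity-to-sleep effects, so every
stage can be validated against known ground truth.

## From daily records to cases

A *case* is one analyzable day `d`: the two dependent variables (light and
deep sleep duration on day `d`, seconds) plus 28 independent variables
summarizing activity on the three prior calendar days. The 28 arise from 4
quantities (steps; light/moderate/intense activity duration) × 3 aggregates
(mean, min, max) × 3 windows (days `d−1`, `d−1…d−2`, `d−1…d−3`), minus the
duplicates in the one-day window where the three aggregates coincide:
4 × (1 + 3 + 3) = 28.

Two deliberate strictness choices:

* **Full-window completeness.** A day is a case only when both sleep
  targets are present on day `d` and *all four* activity quantities are
  present on *all three* prior days — even for the 1- and 2-day features.
  Every case therefore carries the complete 28-feature vector with no
  missing entries, and the correlation screen and the subgroup search see
  the identical case set.
* **Calendar lags, not observation lags.** "The prior three days" is a
  temporal statement; a missing day (an absent row or a missing cell)
  breaks the window rather than letting an older day slide in.

Participants contributing strictly more than `min_days = 30` cases are
retained — a pragmatic floor under which person-level inference is hopeless.

For pooled ("group") analysis, every feature and both targets are
z-standardized *within* participant (sample SD, n − 1): without this, a
pooled correlation mostly restates that people who move more or sleep more
differ from each other, which is not the question. A column constant within
any participant has no rank or subgroup information and a zero-fill would
dilute pooled associations, so such columns are dropped from the pooled
table entirely and reported via the `excluded_features` attribute.

## The correlation screen

For each scope (a participant, or the pooled table) and each of the two
targets, all 28 features are screened with Spearman's rank correlation
(mid-ranks for ties). Two-sided p-values use the t approximation
`t = r·sqrt((n−2)/(1−r²))` with `n − 2` degrees of freedom; an exact
permutation p-value changes nothing material at the case counts this
analysis needs (n > 30) and the t form is the transparent, conventional
choice. The Holm–Bonferroni step-down controls the family-wise error within
a scope; the family is all 28 × 2 = 56 feature–target tests of that scope,
the natural reading when both sleep outcomes are screened together
(`family_size` is exposed for other conventions). Per scope and target the
largest-|r| significant feature is flagged as the headline; when nothing
survives Holm, the overall largest |r| is flagged instead so a null screen
still reports its strongest (non-)finding.

Strength labels use the conventional |r| banding 0.10 / 0.40 / 0.60
(negligible / weak / moderate / strong).

## Subgroup discovery with an explained-variance quality

The screen sees only monotone trends. Subgroup discovery instead searches
for a *subset of days*, described by one threshold condition on one feature
(`feature ≤ t` or `feature ≥ t`, `t` an observed value), whose sleep
distribution deviates from the whole scope. Quality is the **explained
variance**

EV = 1 − SS<sub>within</sub> / SS<sub>total</sub>,

the fraction of target variance explained by the subgroup/complement split
— equivalently the squared point-biserial correlation between membership
and target (an identity the test suite uses as an independent oracle). Only
subgroups covering 10–90% of the scope's cases are admissible, for
generalizability; the bounds are configurable.

With one condition per subgroup, ≤ 2n thresholds per feature and a few
hundred cases per scope, exhaustive search is exact and cheap, so no beam
or discretization heuristic is used; `discover_best()` provably equals a
brute-force loop over every (feature, operator, observed threshold).

**Tie-breaking.** A split and its complement have identical EV, so every
maximum comes in a pair. Ties are resolved toward the *smaller* subgroup —
the side whose mean deviates more from the overall mean, which is the side
a subgroup description conventionally names (reports of "11% of days with
markedly longer sleep" rather than "89% of days with slightly shorter
sleep") — then `≤` before `≥`, then smaller |threshold|, then feature name.
This is a reporting convention only: the quality value is unaffected, and
the choice is deterministic, making discovery invariant to case order.

Reported alongside the condition: the subgroup size as a fraction, and the
subgroup's mean target divided by the overall mean (values above 1 mean
longer-than-usual sleep). On standardized group-level data the overall mean
is ~0, a ratio is meaningless, and the absolute mean difference is reported
instead; group-level thresholds are likewise rendered in SD units.

## Significance by swap randomization

Searching 28 features × all thresholds guarantees an impressive-looking
best subgroup even in noise. The permutation test used here — the
*distribution of false discoveries* — re-runs the **entire search** on
copies of the data whose target column has been randomly permuted (features
untouched, so their joint distribution and the candidate geometry are
preserved), recording each copy's best EV. The observed best EV is then
located in this null distribution of best-of-search qualities, which is
exactly the multiplicity-adjusted reference the search needs.

The p-value is the add-one estimator `p = (1 + #{null ≥ observed}) /
(1 + K)` — a valid permutation p-value, never exactly zero, with ties
counted conservatively — and a finding is significant when `p < α`
(strictly), α = 0.05 by default. `K = 1000` permutations by default
(minimum 100 enforced); the permutation stream is seeded once, so
lengthening a run leaves its prefix unchanged. In group mode the default
permutes within participant: standardization has already removed
participant means, but within-person swapping additionally preserves each
participant's case count and target multiset under the null
(`permute = "global"` is available).

The permutation inner loop dominates runtime, so it runs in compiled code
(`src/best_ev.cpp`): per feature the sort order and distinct-value
boundaries are computed once, after which each permutation costs one
prefix-sum sweep per feature. A property test pins the compiled kernel to
the R search path.

`calibrate_dfd()` closes the loop operationally: on independent null
cohorts the fraction of datasets declared significant should match the
nominal level, and the acceptance suite checks it lands in a binomial band
around 5%.

## The synthetic cohort generator

`generate_cohort()` emulates the data-generating shape the analysis
assumes, not any particular device's firmware:

* **Between-person heterogeneity.** Participant-level mean daily steps are
  log-normal with median 4 000 and log-SD 0.7 (person medians spanning
  roughly 1 000–10 000); activity-duration means are log-normal around
  ~3 h (light) and ~20 min (moderate, intense); sleep means are normal
  around 3 h 45 min light / 3 h 43 min deep with SD 30 min.
* **Within-person day-to-day variation.** Log-normal steps (CV 0.5), gamma
  activity durations (shape 3; right-skewed, as activity data are), normal
  sleep with SD 45 min, clamped to [0, 86 400) s and rounded to whole
  seconds.
* **Missingness** is independent per measurement cell per day (MCAR),
  default probability 0.08 — with the full-window completeness rule this
  yields roughly 60 complete cases per 200 monitored days, a realistic
  long-wear yield. Real tracker missingness (non-wear bouts, charging) is
  serially correlated; MCAR is the simplest testable choice, so passing
  recovery tests speak to the method under independent day-level dropout,
  not to structured non-wear.
* **Planted effects** are step-function mean shifts: after the activity
  series is simulated, the chosen lagged feature is computed, a threshold
  is set at a quantile of its marginal, and the target mean on qualifying
  days is shifted by a multiple of that participant's daily target SD.
  Step functions match the hypothesis class of the search; a linear
  dose–response is deliberately out of scope. The implied subgroup
  fraction must stay inside (0.10, 0.90), mirroring the search constraint.

Defaults (18 participants, 200 consecutive days) reproduce the scale of a
long-wear tracker study: a few dozen to ~170 complete cases per person and
on the order of a thousand pooled days. What the generator does *not*
emulate: intraday epochs, autocorrelated activity or sleep, day-of-week
structure, vendor post-processing of durations, or sleep spanning
midnight — the package pairs sleep recorded on day `d` with activity on
days `d−1…d−3` as dated by the device.

## Numerical and design notes

* SDs use the n − 1 denominator throughout.
* Spearman on a zero-rank-variance vector is reported as undefined (`NA`
  with a warning), never as 0; undefined tests never count as rejections.
* EV is clipped to [0, 1] against floating-point underflow; population vs
  sample scaling cancels in the SS ratio, so the ranking is
  convention-free.
* A permutation in which no condition is admissible (possible only in
  degenerate tables) records null quality 0 with a warning.
* Derived per-scope permutation seeds stay below 2³¹ − 1.
* Reports contain no timestamps, so a rerun with the same config and seeds
  is byte-identical — the pipeline's reproducibility contract, asserted in
  the test suite.

## Problem sizes used in validation

The shipped tests validate at reduced but honest scales: oracle-equivalence
on ~50 random tables of up to 200 cases; null-calibration on 500 independent
cohorts of 60 cases with 500 permutations each; planted-effect recovery
(1 SD shift at the 0.36 quantile of the 3-day minimum step count, 150
cases) over 100 seeds with 500 permutations. `scripts/acceptance.R` re-runs
the same machinery at comparable sizes and writes the resulting quantities
as JSON.

## A worked run

```{r example, eval = FALSE}
pe <- planted_effect("deep_sleep", "steps_min_3d", "<=",
  quantile = 0.36, shift = 1.0, participants = "P01")
cfg <- run_config(
  input = cohort_config(n_participants = 6, days_per_participant = 120,
    planted_effects = list(pe)),
  n_permutations = 500, seed_generation = 1, seed_permutation = 2)
report <- run_study(cfg, out_dir = "study_out")
report
```

The printed report lists inclusion counts, each scope's best subgroup with
its size, quality, permutation p-value and a rendered condition such as
`minimum number of steps in prior 3 days ≤ 3417`, and the gatekept table of
significant findings (size bounds respected and `p < α`, asserted on every
run).
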