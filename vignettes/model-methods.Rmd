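---
title: "Model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`darecea` evaluates regular digital ano-rectal examination (DARE) screening
for anal cancer in MSM living with HIV with a deterministic (expected-value)
Markov cohort model. This vignette records the model, its assumptions, the
calibration and numerical choices, and what the packaged synthetic inputs do
and do not establish.

## State space and event order

A cohort enters cancer-free at age 35 and is followed in one-year cycles to
age 100 (65 cycles). States are: `no_cancer`; undetected cancer in three
stages (local, regional, distal), each split into dwell-year layers within
the progression interval; detected cancer in three stages, each split into
time-since-diagnosis tunnel years so monitoring costs, the post-treatment
utility window, and the Weibull excess hazard can depend on elapsed time;
and two absorbing death states (cancer, other causes), kept separate only
for validation bookkeeping.

Within a cycle, events apply in a fixed order:

1. **Screening** (if the strategy's age window and interval make a screen
   due): each undetected stage moves to its detected counterpart with
   probability uptake × sensitivity. Screening is modelled at the routine
   HIV visit, which is why it leads the cycle.
2. **Background detection**: undetected cancer presents symptomatically with
   a per-stage annual probability.
3. **Progression**: undetected cancer that has completed its dwell moves one
   stage on; undetected distal cancer dies of cancer after its dwell. The
   dwell is deterministic — a cancer is local for exactly
   `progression_interval_years` years — not geometric.
4. **Incidence**: cancer-free occupants develop undetected local cancer at
   the age-specific annual probability.
5. **Mortality**: age-specific other-cause mortality applies to every alive
   state; detected states additionally face the stage's annual excess death
   probability at their tunnel year.
6. The dwell/tunnel clocks advance.

Life-years and utility-weighted life-years accrue on start-of-cycle
occupancy; event-driven costs (screens, false positives, diagnosis,
monitoring) accrue within the cycle. All per-cycle payoffs are discounted at
the cycle midpoint, `(1+r)^-(cycle-0.5)` — the half-cycle correction is a
discounting convention here, not trace averaging, which keeps every payoff's
present value well defined under a single rule.

## Key parameters

| Parameter | Default | Units / range | Note |
|---|---|---|---|
| `dare_sensitivity` | 0.9 | probability (0.70–1.00) | per screen, all undetected stages |
| `dare_ppv` | 0.25 | probability (0.1–0.5) | fraction of surgical referrals that are cancer |
| `p_background_detect_local` | 0.2 | /year (0.1–0.55) | symptomatic presentation, localized |
| `p_background_detect_regional` | 0.15 | /year | calibrated, see below |
| `p_background_detect_distal` | 0.20 | /year | calibrated, see below |
| `progression_interval_years` | 1 | years (1–3 in scenarios) | deterministic stage dwell |
| `surgical_excision_fraction` | 0.05 | probability | localized cancers treated by excision |
| costs | 16 / 218 / 1864 / 10386 / 11093 / 14638 | AUD 2014 | screen / false positive / workup / treatment by stage |
| `monitoring_cost_schedule` | 500, then 250 × 4 | AUD by year since diagnosis | stands in for an unavailable schedule |
| utilities | 0.76 / 0.71 / 0.66 / 0.52 | weight in [0,1] | no cancer / local / regional / distal |
| `discount_rate` | 0.03 | /year (0, 0.05) | half-cycle corrected |

The published "specificity" of DARE is, by its own definition, the fraction
of surgical referrals that turn out to be cancer — a positive predictive
value. It is stored as `dare_ppv`, and each screening cycle solves Bayes'
identity for the per-screen false-positive probability at the cohort's
current undetected prevalence, `f = prev·sens·(1-ppv)/(ppv·(1-prev))`. This
holds the ratio of false-positive to true-positive referrals at
`(1-ppv)/ppv` throughout life — a deliberately conservative convention (the
false-positive burden never improves with repeat screening), and the reason
false positives are charged per screening cycle rather than per detected
case.

## Calibrated defaults for unpublished inputs

Background detection for regional and distal cancer is not published.
These two values are pinned by two reported behaviours of the original
model: the no-screening stage-at-diagnosis split (~52/31/17%
local/regional/distal) and the stage shift under screening (localized share
of detections rising steadily as the interval shortens). Under 1-year
deterministic progression the two constraints pull against each other: a
localized share near 50% forces low regional/distal detection, which leaves
most cancers dying undetected, and screening then converts some of those
into *late-stage* diagnoses, which can dilute the localized share at middle
intervals. An exhaustive scan of the plane shows the clinically intuitive
ordering "more advanced ⇒ more likely symptomatic" is incompatible with a
localized share above ~42%. The packaged defaults (regional 0.15, distal
0.20) are the compromise: localized share 45% without screening, a strictly
monotone localized-share gradient across 5-yearly → annual screening, and
distal detection above regional.

Two related conventions, chosen once and documented rather than varied:
undetected cancer carries its stage utility (the disease burden exists
whether or not it is diagnosed); detected cancer carries the stage utility
for one treatment year (`treatment_utility_years`) and the cancer-free
utility thereafter, while remaining on the stage's excess-survival curve —
there is no separate remission state, because treated patients never return
to cancer-free dynamics. Monitoring costs run for five years after
diagnosis. The local-excision cost defaults to the workup-scale cost, since
only chemoradiation pathways are priced.

## Weibull survival calibration

Stage-specific relative survival — observed survival of cancer patients over
expected survival of a cancer-free population — proxies cancer-attributable
mortality and is modelled as `S(t) = exp(-(t/λ)^k)`. `fit_weibull()` fits
the log(-log) linearization by weighted least squares with delta-method
inverse-variance weights `n·(S·log S)²/(S(1-S))`: exactly invertible on
noiseless data, and properly downweighting the imprecise extremes of a
sampled curve. The annual excess death probability applied in the engine is
`1 - S(t+1)/S(t)`, computed through cumulative hazards (`expm1`) so it stays
finite where `S` underflows. The packaged default parameters (local k=1.1,
λ=20; regional k=1.0, λ=10; distal k=0.9, λ=4, i.e. five-year relative
survival of roughly 0.80/0.61/0.30) are fitted to the package's own
synthetic registry-like curves and labelled synthetic; the fitted curve is
applied uniformly across ages at diagnosis.

## Synthetic study inputs

The generators emulate the statistical structure of the unavailable registry
inputs:

* **Incidence**: a logistic ramp in age (midpoint 54, steepness 4), flat
  after 65, giving a mean annual probability at ages 50–64 about nine times
  that at 35–49; a global multiplier is root-found so the no-screening
  cohort's lifetime cumulative diagnosis probability is 3.0% (the cohort
  engine itself is the calibration oracle; convergence tolerance 1e-6 on the
  multiplier, with a hard ±0.2-percentage-point acceptance band).
* **Mortality**: Gompertz, `p(a) = min(1, m·0.0012·e^{0.088(a-35)})`, with
  `m` root-found so a cancer-free cohort's discounted (3%) life expectancy
  is 24.2 years, emulating an HIV cohort's elevated all-cause mortality.
* **Survival datasets**: the Weibull curve plus truncated heteroscedastic
  noise scaled to the binomial standard error at `n_at_risk`, with
  monotonicity restored by a running minimum.

What passing tests on this fixture establish: the engine's accounting
(conservation, discounting, dominance arithmetic), the direction of its
responses (stage shift, sensitivity-analysis gradients), and the calibration
machinery. What they do not establish: the absolute costs, QALYs and ICERs
of the original evaluation, which depend on the true registry schedules. For
that reason the frontier arithmetic is verified separately, on the bundled
reference outcome tables, where agreement is exact to the printed dollar.
One consequence worth noting: on the reference tables the five-yearly ≥50
strategy is removed by extended dominance on the QALY scale (its ICER,
29,779, exceeds its successor's recomputed 29,760), so reported life-year
ICERs are computed between the QALY-frontier members — recomputing dominance
independently on the printed life-year column would keep that strategy by a
rounding-level margin (14,496.0 vs 14,496.6) and shift the next ICER by one
dollar.

## Economics conventions

Strategies are ranked by increasing effect (ties broken by lower cost; exact
duplicates collapse to one representative). Strict dominance removes
strategies weakly worse on both axes; extended dominance then repeatedly
removes the first strategy whose incremental ratio is not strictly below its
successor's, until frontier ICERs strictly increase — equivalent to the
lower convex hull, and tested against an exhaustive convex-combination
oracle. Ratios are reported rounded to the nearest dollar, halves away from
zero; internal arithmetic is never rounded. ACERs compare every strategy
with no screening. The same interface serves the per-QALY and per-life-year
analyses.

## Sensitivity analysis

One-way analysis re-runs the whole pipeline on a grid, holding all else at
base. A caveat discovered here: with deterministic stage dwell, pairwise
ICERs between adjacent screening intervals resonate with the progression
interval (three-yearly screening catches every cancer during a three-year
local phase, so it can dominate two-yearly screening outright). Across
progression scenarios the stable summaries are each strategy's ICER against
no screening and the menu's minimum frontier ICER, and those are what the
progression-direction checks use; false-positive-cost and discount-rate
responses are monotone in the published pairwise layout as well.

The PSA draws every varied parameter independently — gamma for costs, beta
for probabilities and utilities, method-of-moments with mean at base and SD
30% of it (per-parameter overrides accepted; infeasible beta variances are
clipped to 95% of the maximum, with a message). One draw is applied to all
strategies (common random parameters), both as variance reduction and
because a draw represents one state of the world. Independent utility draws
can invert the health-state ordering, in which case life extension
legitimately loses QALYs — so "screening never loses QALYs" holds only for
draws with a coherent utility ordering, and is tested as such. Acceptability
curves default to the pairwise definition (probability that net monetary
benefit versus no screening is positive), since per-strategy curves reported
independently can exceed 1 in sum under the multiway definition, which is
available behind a flag. Progression-interval and survival-shift analyses
are scenario re-runs, not distribution draws; a survival shift rescales each
stage's annual excess death probabilities so five-year survival moves by the
requested number of percentage points.

## Numerical choices and degenerate inputs

* Occupancy must sum to 1 within 1e-9 at every cycle; the engine verifies
  this each step and the whole pipeline is deterministic given a seed.
* Calibrations use `uniroot` with tolerances 1e-6 (incidence multiplier) and
  1e-7 (mortality multiplier); unattainable targets raise calibration
  errors rather than returning the nearest value.
* `fit_weibull` requires three usable points in (0, 1); an all-ones curve is
  a degeneracy error; non-monotone curves are accepted and fitted as-is.
* A run with no diagnoses flags its validation summary as degenerate instead
  of dividing by zero. A zero prior or a PPV of 1 gives a zero
  false-positive rate; an impossible test observation raises an
  undefined-posterior error.
* Problem sizes in the test suite are chosen to exercise the claims at
  desk scale: 1,000 random frontier instances against the exhaustive
  oracle, 100 seeds of Weibull parameter recovery at n_at_risk 2,000,
  10,000 distribution draws for the PSA moment checks, and a 200-iteration
  engine PSA for the acceptability-curve properties.

## Limitations

* A cohort (expected-value) model: no individual-level variability beyond
  the second-order PSA.
* No HPV/HSIL precursor states — this models late(r)-stage early detection,
  not cytology-based precursor screening.
* Utilities are not age- or comorbidity-adjusted; the cancer-free utility is
  flat across ages.
* The synthetic schedules are calibrated stand-ins; absolute outputs on them
  are indicative of scale, not estimates of the original results.
* Costs are fixed in 2014 Australian dollars; no currency or inflation
  machinery.
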