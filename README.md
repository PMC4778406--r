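# darecea

Cost-effectiveness modelling of regular **digital ano-rectal examination
(DARE)** screening for anal cancer in men who have sex with men (MSM) living
with HIV.

Anal cancer is common in MSM with HIV (roughly 78 per 100,000 person-years)
and is usually diagnosed late, when chemoradiation is the only option and
prognosis is poor. Where anal cytology programmes are unavailable, a
clinician's anal examination at the routine HIV visit is a cheap
early-detection alternative. `darecea` implements a probabilistic Markov
cohort model that asks: for a cohort of 35-year-old MSM with HIV followed to
age 100, is screening every 1–5 years — starting at age 35 or at age 50 —
worth its cost per quality-adjusted life-year (QALY) gained?

## The model

A one-year-cycle cohort model over the states

```
no cancer → {local, regional, distal} undetected → {local, regional, distal} detected
                                 ↘ death (cancer) / death (other causes)
```

* Undetected cancer progresses one stage per progression interval (base: one
  year); undetected distal cancer is fatal after a further year. A cancer can
  be found by screening (sensitivity 0.9) or by background (symptomatic)
  presentation (localized: 0.2/year).
* A positive DARE refers the patient to a colorectal surgeon. The referral's
  positive predictive value (0.25) is held fixed; Bayes' identity
  `f = prev·sens·(1−ppv) / (ppv·(1−prev))` converts it to a per-screen
  false-positive probability at the cohort's current undetected prevalence.
* Detected cancer is treated (workup + stage-specific cost; 5% of localized
  cancers get local excision) and follows a stage-specific Weibull relative
  survival curve `S(t) = exp(−(t/λ)^k)` through time-since-diagnosis tunnel
  states, with annual excess death probability `1 − S(t+1)/S(t)` on top of
  other-cause mortality. Treated patients never return to the cancer-free
  state.
* Lifetime costs (AUD 2014) and QALYs accrue each cycle and are discounted at
  3%/year with half-cycle correction: `(1+r)^−(cycle−0.5)`.
* Strategies are compared by ACERs (versus no screening) and frontier ICERs
  after strict and extended dominance elimination:
  `ICER = Δcost / ΔQALY` between consecutive frontier members.
* Uncertainty: one-way sensitivity analysis over published ranges and
  second-order Monte Carlo PSA (gamma for costs, beta for probabilities and
  utilities, SD = 30% of the mean), summarized as cost-effectiveness
  acceptability curves.

The original registry inputs (age-specific incidence, HIV-cohort mortality,
stage-specific relative survival) are not distributed; a synthetic-data
module generates calibrated stand-ins (~9× incidence rise from ages 35–49 to
50–64, 3% lifetime diagnosis risk, Gompertz cohort mortality, Weibull
survival), clearly labelled as such.

## Worked example

The bundled reference outcome table (discounted lifetime cost and QALYs per
strategy) run through the dominance algorithm:

```r
library(darecea)
tab <- base_case_table(reference_outcomes(discounted = TRUE))
tab[, c("label", "cost", "qaly", "icer_qaly", "acer_qaly", "status")]
```

```
                       label cost    qaly icer_qaly acer_qaly             status
                No screening  195 18.3857        NA        NA           frontier
  Age 35-49 every five years  529 18.3899        NA     79524 extended_dominated
  Age 35-49 every four years  629 18.3919        NA     70000          dominated
 Age 35-49 every three years  736 18.3936        NA     68481          dominated
   Age 35-49 every two years 1033 18.3977        NA     69833          dominated
   Age >=50 every five years  600 18.3993        NA     29779 extended_dominated
        Age 35-49 every year 1745 18.4008        NA    102649          dominated
   Age >=50 every four years  692 18.4024     29760     29760           frontier
  Age >=50 every three years  837 18.4069     32222     30283           frontier
    Age >=50 every two years 1119 18.4131     45484     33723           frontier
         Age >=50 every year 1915 18.4206    106133     49284           frontier
```

Screening men aged ≥50 every four years costs $29,760 per QALY gained versus
no screening (its frontier predecessor); shortening the interval to three,
two and one year(s) costs $32,222, $45,484 and $106,133 per additional QALY.
All strategies that start screening at age 35 are dominated: starting at 50
(where incidence is ~9× higher) buys more QALYs for less money.

Running the engine end-to-end on the synthetic fixture:

```r
bc <- base_case_parameters()
sched <- reference_schedules(1)                 # calibrated synthetic inputs
res <- run_cohort(no_screening_strategy(), bc$params, bc$settings, sched)
validation_summary(res)$stage_distribution     # ~45/26/29% local/regional/distal
validation_summary(res)$lifetime_risk          # 0.030
```

Other entry points: `run_strategies()` (outcome table for a strategy menu),
`frontier()` / `ce_plane()` (economics on any cost/effect table), `owsa()`
(one-way sensitivity), `run_psa()` + `ceac()` (probabilistic sensitivity),
and the artifact writers `cmd_base_case()`, `cmd_psa()`, `cmd_owsa()`,
`cmd_validate()`, `cmd_synth()`.

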