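---
title: "A lifetime Markov cost-utility model of wet AMD therapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lifetime Markov cost-utility model of wet AMD therapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amdcea)
```

## The decision problem

Neovascular ("wet") age-related macular degeneration progressively destroys
central vision. Anti-VEGF agents — ranibizumab, licensed and expensive, and
bevacizumab, used off-label at a small fraction of the price — improve
visual acuity, while verteporfin photodynamic therapy (PDT) and supportive
"usual care" are the older alternatives. In a resource-limited health
system the question is not only whether the new agents work but whether
their health gain is worth their cost. `amdcea` implements a cost-utility
model that compares the four strategies over a patient's remaining
lifetime, separately for the three angiographic lesion subtypes
(predominantly classic, minimally classic, occult), and reports incremental
cost-effectiveness ratios (ICERs) in US\$ per quality-adjusted life-year
(QALY).

## Model structure

The model is a Markov cohort simulation over six health states: five
visual-acuity (VA) bands of the better-seeing eye on the Snellen scale —
\>20/40, ≤20/40 to \>20/80, ≤20/80 to \>20/200, ≤20/200 to \>20/400, and
≤20/400 (light perception only) — plus absorbing death. Each band spans
roughly one Snellen doubling, i.e. about three chart lines. Cycles are 3
months; in a cycle the cohort can stay, improve by more than 3 lines (up
one state), lose 3–6 lines (down one), or lose more than 6 lines (down
two), and can die from any state at the age-specific background rate. No
disease-specific excess mortality is applied: wet AMD impairs vision, not
survival, and only natural mortality is modelled.

Within a cycle death is resolved first and vision transitions apply to
survivors. This ordering makes mortality independent of the vision
outcomes, which matters only for how a single cycle's mass is split; over
the 3-month cycle the difference to other orderings is second-order. Moves
past the boundary states are folded into the boundary state (a gain from
the best state means staying there), which preserves the total event
probability rather than renormalizing it away.

### From trial outcomes to cycle probabilities

The trials report *cumulative yearly* probabilities of gaining \>3 lines,
losing 3–6 lines, and losing \>6 lines, for usual care and PDT at years 1
and 2. Assuming a constant event rate within each year (exponential
waiting times), a yearly cumulative probability $P$ converts to a
quarterly probability $q = 1 - (1-P)^{1/4}$, the "density method";
compounding $q$ over four cycles recovers $P$ exactly. Year-2 printed
probabilities are interpreted as the probability of the event occurring
*during* year 2, so they too are spread over four cycles.

The four strategies were never compared head-to-head in one trial, so the
anti-VEGF arms are constructed indirectly on the cumulative-probability
scale. Ranibizumab outcomes are the comparator baseline times the reported
risk ratio — PDT is the comparator for predominantly classic lesions, usual
care otherwise, matching the designs of the underlying trials — and
bevacizumab chains the head-to-head bevacizumab-vs-ranibizumab risk ratio
onto the derived ranibizumab probabilities. Products above 1 are clamped
with a warning. Beyond year 2 no effectiveness evidence exists; every
strategy reverts to the usual-care year-2 transition probabilities until
death (treatment effects are not extrapolated, only the natural history
is).

### Mortality and the life table

Background mortality comes from an age-indexed life table (annual `qx`),
converted per cycle as $1-(1-q_x)^{1/4}$ with $q_x$ looked up at
`floor(current age)`; the fractional starting age of 73.6 years therefore
uses the age-73 row for its first two cycles. The horizon runs one cycle
past the terminal life-table age, whose `qx = 1` absorbs any remaining
cohort, so "lifetime" needs no arbitrary cycle cap.

National 2011 life tables are not redistributable inside the package, so
the default table is synthetic: a Gompertz–Makeham hazard
$\mu(x) = \lambda + a e^{bx}$ with $\lambda = 5\times10^{-4}$,
$a = 4.83\times10^{-5}$, $b = 0.09$ over ages 40–105, calibrated so that
residual life expectancy at age 73.6 is about 12 years — plausible for the
elderly Chinese population around 2011. Any real life table can be dropped
in as a two-column CSV (`read_life_table()`), and the packaged CSV is
explicitly labelled synthetic.

## Costs, utilities, discounting

Costs are 2012 US\$ from the payer perspective; only direct medical costs
enter (productivity losses are out of scope by design). Per cycle, the
living cohort accrues:

* **Treatment** (years 1–2 only): administrations per year × unit price.
  PDT averages 2.05 and 1.54 verteporfin-plus-laser sessions in years 1
  and 2; the anti-VEGF arms give 8 then 6 injections (drug dose plus
  intravitreal injection fee). Bevacizumab is assumed to follow the
  ranibizumab schedule, per their equivalent acuity effects on the same
  schedule.
* **Follow-up** (lifelong, all arms): ophthalmologist consultation and OCT
  once per cycle, fluorescein angiography four times a year. Where a
  printed annual mean total disagrees with its own unit-cost × frequency
  arithmetic, the annual mean is stored as authoritative.
* **Serious adverse events** (anti-VEGF arms, treatment years):
  endophthalmitis, lens damage, retinal detachment as annual mean costs
  per arm. Utility decrements for these events are deliberately excluded;
  they are rare and mild, and only their cost is modelled.
* **Comorbidities of low vision** (lifelong): depression, falls and
  assisted living as annual mean costs, applied to occupancy of the three
  worst VA states (≤20/80 and worse). The published inputs say these costs
  vary with "degree of visual acuity" without printing a per-state split;
  the three-worst-states mapping is this package's choice and is
  configurable per state (`cohort$comorbidity_states`).

Utilities per VA state (0.89, 0.81, 0.57, 0.52, 0.40 from best to worst;
death 0) come from time-tradeoff valuations of better-seeing-eye acuity.
QALYs per cycle are occupancy-weighted utility × cycle length.

Costs and QALYs are discounted at 3%/year, evaluated at cycle start, and
accrual uses start-of-cycle occupancy with **no half-cycle correction**:
the reference totals are reproducible without one, and a config switch
(`cohort$half_cycle_correction`) enables mid-cycle averaging for anyone
who prefers it. "Vision-years" — expected undiscounted years with acuity
better than 20/200 (states 1–3) — is a reporting convention of this
package since the quantity is tabulated but never defined in the source
material; the cutoff is configurable (`cohort$vision_cutoff`).

The initial VA distribution of an incident cohort is not published; the
default is uniform over the five VA states, and `scenario_initial_state()`
explores degenerate single-state cohorts. This is the single largest
source of disagreement with the published totals (see *Limitations*).

## Incremental analysis

`build_frontier()` classifies strategies as strictly dominated (costlier,
no more effective), extendedly dominated (removed iteratively until
frontier ICERs increase), or on-frontier, and reports each strategy's ICER
versus usual care regardless of dominance, because decision tables
conventionally print both. Verdicts use WHO GDP-multiple bands with
per-capita GDP \$7,480 (2011): at most 1× is cost-effective, 1–3×
marginally so, above 3× not cost-effective. Both thresholds are
configurable. Tests cross-check the frontier against an independent
gift-wrapping oracle on randomized instances.

## Sensitivity analyses

**One-way (tornado).** `one_way()` re-runs the whole pipeline at the low
and high bound of a single input; `tornado_parameters()` lists the default
set (starting age 55–88, bevacizumab risk-ratio components at ±20%,
utilities over their published ranges, bevacizumab and injection prices,
injection frequencies, and 2- vs 10-year horizons). Inputs without a
published range default to ±20% of base. Bounds violating an invariant
fail before any model run.

**Probabilistic (PSA).** `run_psa()` draws 1000 parameter sets by default:
probabilities and utilities from beta distributions and costs from
lognormal distributions, each matched by method of moments to mean = base
and SD = 20% of the mean. The named distributions do not pin down a
parameterization; method of moments is this package's choice, with the SD
shrunk to 95% of its feasible maximum when a mean sits too close to 0 or 1
for a valid beta. Risk ratios are positive and right-skewed, so they are
sampled lognormally with the same moment rule; a base risk ratio of 0
stays 0. All four strategies are evaluated on the *same* draw (common
random parameters), so incremental quantities are coherent within a draw.
Utilities are drawn independently per state: draws that invert the VA
ordering are counted and reported, not re-sorted, since re-sorting would
distort the marginal distributions. Draws whose outcome probabilities sum
past 1 (making a transition matrix impossible) are regenerated and
counted.

**Acceptability curves.** `compute_ceac()` reports, per willingness-to-pay
value on a default grid of \$0–30,000 in steps of \$250 (covering 1× and
3× GDP), the share of draws in which each strategy has the greatest net
monetary benefit ($\mathrm{NMB} = \lambda \cdot \mathrm{QALY} - C$); the
four probabilities sum to 1 by construction, with exact NMB ties broken by
column order (measure-zero under continuous sampling). A pairwise
vs-usual-care variant is available (`pairwise = TRUE`); best-of-four is
the default because it answers the actual adoption question among four
options.

## Verification strategy and problem sizes

The test suite checks the engine against closed forms (a discounted
one-year full-health cohort equals the annuity
$0.25\sum_{k=0}^{3}1.03^{-k/4} = 0.98901$; frozen-vision traces reproduce
the life-table survival curve exactly) and against an independent
individual-level microsimulation that replays the same schedules by
categorical sampling — 100,000 paths agree with the cohort engine within
three standard errors on cost and QALYs. Frontier construction is checked
against a gift-wrapping oracle on 1,000 random instances, transition
schedules for row-stochasticity over 100 randomized parameter sets, and a
degenerate-SD PSA must reproduce the base case to machine precision.
These sizes keep the default suite to a few minutes while leaving
Monte-Carlo error far below the tolerances tested.

The synthetic-data generator emulates the *structure* of the study inputs
(a plausible elderly life table, a valid initial distribution, randomized
but invariant-respecting parameter tables). It does not emulate real-data
features such as correlated utilities and costs, reporting error in trial
probabilities, or cohort heterogeneity in treatment response — so passing
tests demonstrate the model machinery is correct, not that the synthetic
base case equals the published one.

## Limitations

* The published analysis' initial VA distribution and exact 2011 life
  table are not printed and cannot be reconstructed; with the uniform
  default and the synthetic table, the *qualitative* decision structure
  reproduces exactly (ranibizumab most effective everywhere, PDT strictly
  dominated by bevacizumab everywhere, bevacizumab under 1× GDP per QALY)
  and the bevacizumab-vs-usual-care ICERs land within about 15% for the
  predominantly classic and occult subtypes but about a third low for
  minimally classic, where the incremental QALY is most sensitive to the
  starting distribution.
* Treatment beyond year 2 is neither given nor costed (the
  continuous-treatment question is explicitly out of scope), and no
  retreatment or discontinuation logic exists.
* The share of patients receiving treatment is fixed at 100% per arm.
* Comorbidity costs apply uniformly within the eligible states; no
  per-state cost gradient is available in the inputs.
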