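---
title: "Methods: a Markov cohort model for supplemental short-protocol brain MRI after negative head CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model for supplemental short-protocol brain MRI after negative head CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokecea)
```

## The clinical question and the model

Emergency patients with mild, unspecific neurological symptoms and a
negative non-contrast head CT may still harbour a minor ischaemic stroke:
small diffusion-restricted lesions are frequently CT-occult. Detecting
them matters because immediate secondary prophylaxis (antiplatelet
therapy, stroke-unit care) reduces the risk of a subsequent major stroke
by roughly 80%. `strokecea` evaluates whether adding a short-protocol
brain MRI after negative CT is cost-effective compared with relying on
clinical assessment alone.

The model has two parts.

**Decision tree.** Each strategy is a diagnostic test applied to a cohort
with minor-stroke prevalence $p$ (default 10.17%, the rate at which the
supplemental scan changed management in the underlying accuracy study,
6/59). With sensitivity $se$ (0.60 for clinical assessment alone, 0.94 for
supplemental MRI) and specificity fixed at 1 (a positive diffusion lesion
is not a false positive in this setting), the cohort splits into true
positives $p \cdot se$ entering the *detected, first year* state, false
negatives $p(1-se)$ entering the *undetected, first year* state, and true
negatives $1-p$ entering *well*. Imaging costs are charged to every
patient in the arm (the MRI is supplemental to CT for all comers); acute
minor-stroke care (\$3{,}000) is charged only to detected cases, since an
undetected minor stroke by definition receives no acute stroke care.

**Markov cohort.** Seven health states are tracked over yearly cycles
(default 30, entry age 61): `well`, `undetected_y1`, `undetected_post`,
`detected_y1`, `detected_post`, `post_major`, and absorbing `dead`. The
first-year/later split is a tunnel-state device: recurrence risk after a
minor stroke is much higher in the first year (detected: 5.1% vs 1.1%;
untreated: 25.5% vs 5.5%, the treated risks divided by $1-\mathrm{RRR}$
with $\mathrm{RRR}=0.80$), and the tunnel is anchored to the stroke event
itself. Detection of a prevalent undetected stroke (10%/year, an
assumption varied widely in sensitivity analysis) therefore routes to
`detected_post`, not `detected_y1`: by the next cycle the index stroke is
over a year old.

Within a cycle, competing risks are resolved in a fixed order that keeps
each transition row a probability distribution without renormalisation:

1. death, with state-specific mortality — the life-table probability
   $q_x$, plus 0.075 (undetected) or 0.06 (detected) *additive* annual
   excess, or multiplied by relative risk 1.71 after major stroke
   (an average mRS of 4);
2. among survivors, major stroke (state-specific annual risk);
3. among survivors without a major stroke, detection (from the undetected
   states) or a new minor stroke (0.3%/year, from `well`), which enters
   the undetected first-year tunnel — its recognition is then governed by
   the yearly detection rate, and no acute or imaging cost is charged for
   these incident events.

Patients after major stroke face no further modelled stroke events, only
elevated mortality, mirroring the single average post-major state.

## Rewards, discounting, and cycle-timing conventions

Cycle $t$ accrues, discounted by $(1+r)^{-t}$ at the default $r = 3\%$:
yearly care costs (\$7{,}023 for detected minor-stroke patients, \$19{,}062
after major stroke), a one-time acute major-stroke cost (\$6{,}500) for the
flow of new entrants into `post_major` that cycle, and QALYs (utility 1
for all alive-without-major-stroke states — undetected minor stroke is
assumed not to reduce quality of life — and 0.33 after major stroke).
Upfront decision-tree costs enter at cycle 0 undiscounted.

Where within the cycle state rewards are valued is a genuine modelling
convention, and it matters quantitatively:

* `reward_timing = "end"` (the default): end-of-cycle occupancy,
  discounted at the cycle end. With full survival and $r = 3\%$ this
  yields the ordinary 30-year annuity $(1 - 1.03^{-30})/0.03 = 19.60$
  discounted life-years — the plainest reading of a yearly model.
* `"begin"`: start-of-cycle occupancy discounted at the cycle start, the
  accrual convention of common decision-tree/Markov software, equivalent
  to an annuity-due (factor 1.03 larger in the degenerate case). Everyone
  alive at a cycle's start is credited with that cycle's reward.
* `"half_cycle"`: the mean of start and end occupancy (half-cycle
  correction), which lies between the two.

The package's tests pin the default; the acceptance script reports the
base case under both `"end"` and `"begin"` so the size of the convention
effect is visible (about one discounted QALY over 30 years). Published
cumulative magnitudes from tools that accrue at cycle start are best
compared against `"begin"`.

## The life table and the synthetic stand-in

Background mortality comes from an annual life table (`age,qx` CSV). The
published analysis used US life tables of unstated vintage; no table is
bundled as data. Instead `synthetic_life_table()` generates one from a
Gompertz–Makeham hazard, $q_x = 1 - \exp(-(\lambda + \alpha
e^{\beta(x - x_0)}))$ — a constant background hazard plus an exponentially
age-increasing component, the classical three-parameter description of
adult mortality. The defaults ($\lambda = 5\times10^{-4}$,
$\alpha = 4.3\times10^{-3}$, $\beta = 0.092$, ages 50–110) were calibrated
once to the magnitude of recent US period mortality: $q_{61} \approx
0.012$, rising to $\approx 0.15$ by age 90.

What the synthetic table does *not* emulate: the exact vintage, sex mix
and old-age detail of any published national table. Cumulative discounted
costs and QALYs are sensitive to this choice (survival enters every
reward stream), so results under the synthetic table demonstrate the
model's structure, orderings and invariances — dominance of the MRI
strategy at base case, mass conservation, oracle agreement — rather than
exact published dollar figures. Users seeking exact reproduction should
supply a real US annual life table via `read_life_table()`. Ages beyond
the table end clamp to the final $q_x$ rather than forcing death, since
entry age 61 plus 30 cycles exceeds short tables.

## Sensitivity analyses

**One-way (tornado).** `one_way_dsa()` sets one parameter to its low and
high value, all else at base, and reports the incremental net monetary
benefit $\mathrm{NMB} = \mathrm{WTP}\times\Delta E - \Delta C$ at WTP
\$100,000/QALY — a single signed scalar in which a positive value means
the MRI strategy is preferred and dominance appears as positivity
throughout the range. Ranges investigated in the published analysis are
used where stated (age 50–70, MRI cost \$155–\$500, no-imaging
sensitivity 0.40–0.80); all other ranges default to ±50% of the base
value truncated to validity (probabilities to $[0,1]$; the risk reduction
to $[0, 0.9]$ so the derived untreated risks stay below 1). Whenever a
treated recurrence risk or the risk reduction is varied, the untreated
risks are re-derived, so the derivation propagates consistently.

**Probabilistic.** `run_psa()` samples every uncertain parameter jointly:
beta distributions for probabilities and utilities, gamma for costs,
moment-matched to mean = base value and sd = `spread_cv` × mean. The
published analysis states the families but not the spreads; the default
coefficient of variation of 0.2 is a common convention when uncertainty
is unreported, and it is exposed rather than hidden. Two departures from
a literal reading of the input table: the relative risk of death after
major stroke (mean 1.71) cannot follow a beta distribution, so it is
gamma-sampled; and the untreated recurrence risks are re-derived from the
sampled treated risks and sampled risk reduction each iteration (they are
consequences, not independent quantities), truncated at 1 for the rare
draws in which the sampled risk reduction approaches its upper bound.
Boundary-valued parameters (utility 1, specificity 1) have zero feasible
variance and stay fixed. No other correlation between parameters is
modelled. Results: the per-iteration cost/effect cloud, the fraction of
iterations in which the intervention strictly dominates, and the CEAC —
the probability that the intervention's NMB exceeds the comparator's as a
function of WTP.

The full analysis uses 30,000 Monte Carlo iterations (the package
default); the test suite and the acceptance script run 3,000, which the
package treats as its standard verification size — dominance fractions
and CEAC points at 3,000 iterations carry a Monte Carlo standard error
below one percentage point. All sampling is seed-reproducible.

## Validation by independent microsimulation

`microsim_oracle()` re-implements the identical state, transition and
reward rules at the individual level — sequential uniform-draw event
sampling per person and cycle, in the same death → major stroke →
detection/new-minor order — sharing no transition-matrix code with the
cohort engine. With 200,000 individuals its Monte Carlo standard errors
are small enough that agreement with `run_cohort()` within three standard
errors, across the base case and perturbed parameter fixtures, is a
meaningful end-to-end check of both implementations.

## Numerical choices and degenerate inputs

* Validation is strict: out-of-range inputs raise errors naming the
  field; nothing is silently clamped (clamping would corrupt sensitivity
  analyses). The two deliberate exceptions, both documented above, are
  mortality adjustments capped at 1 and the PSA's truncation of derived
  untreated risks.
* When incremental QALYs are exactly zero but costs differ, strategies
  are ranked by cost alone (cost minimisation) and the ICER is left
  undefined; with both increments zero no dominance is declared. ICERs
  are reported only for genuine trade-off quadrants.
* Transition rows are asserted row-stochastic to $10^{-12}$ and cohort
  occupancy rows to $10^{-10}$; the absorbing-death column is checked
  monotone.
* Equal diagnostic accuracy in both arms collapses the comparison to the
  upfront MRI charge exactly — a useful structural identity used in the
  tests.

## Known limitations

The model inherits the published analysis's structure: a single average
post-major state (no mRS stratification), no recurrent events after major
stroke, no stroke-mimic or thrombolysis pathways, US cost basis without
inflation adjustment, and a cohort homogeneous in age and sex. Base-case
dollar/QALY magnitudes additionally depend on the life-table vintage and
the cycle-timing convention, neither of which the published report pins
down; the package exposes both (`read_life_table()`, `reward_timing`) and
treats orderings and invariances, not absolute magnitudes, as the robust
outputs under the synthetic table.
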