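# strokecea

Cost-effectiveness analysis of supplemental short-protocol brain MRI
after negative non-contrast head CT for the detection of minor strokes in
emergency patients with mild, unspecific neurological symptoms.

Small ischaemic lesions are frequently CT-occult, and a missed minor
stroke forfeits the chance of immediate secondary prophylaxis — which
reduces the risk of a subsequent major stroke by about 80%. This package
implements a decision-analytic model for radiologists, neurologists and
health-economics researchers who want to examine whether the extra scan
pays for itself in averted major strokes.

## The model

Two strategies are compared for a cohort with minor-stroke prevalence
*p* = 10.17% at entry age 61:

* **no additional imaging** — clinical assessment after negative CT,
  sensitivity 0.60;
* **additional short-protocol MRI** — supplemental scan for all comers,
  sensitivity 0.94 (specificity 1 in both arms).

A decision tree allocates the cohort to true positives (*p·se*, detected
minor stroke), false negatives (*p(1−se)*, undetected), and true
negatives (1−*p*), and charges upfront imaging plus acute care for
detected cases. A seven-state Markov cohort model (well; undetected and
detected minor stroke, each with a first-year tunnel; post-major stroke;
dead) is then run for 30 yearly cycles. Cycle rewards — yearly care costs
($7,023 detected; $19,062 post-major), one-time acute major-stroke costs
($6,500), and utility-weighted life-years (utility 0.33 after major
stroke) — are discounted at 3%/year. Strategies are compared by
incremental cost ΔC and effectiveness ΔE, dominance, the ICER ΔC/ΔE
where defined, and net monetary benefit NMB = λ·E − C at willingness to
pay λ = $100,000/QALY. One-way deterministic (tornado, ICER-vs-parameter)
and probabilistic (moment-matched beta/gamma Monte Carlo, CE plane, CEAC)
sensitivity analyses are included, along with a Gompertz–Makeham
synthetic life-table generator and an independent individual-level
microsimulation that cross-validates the cohort engine.

## Worked example

```r
library(strokecea)

fit <- cea_markov()   # Table-1 defaults + synthetic US-like life table
fit
#> Cost-effectiveness of supplemental short-protocol brain MRI
#>   cohort age 61, 30 yearly cycles, 3% discounting
#>
#>                       strategy cumulative_cost cumulative_effectiveness
#>          no_additional_imaging         $22,093              12.24 QALYs
#>  additional_short_protocol_mri         $21,737              12.30 QALYs
#>                          delta           $-356               0.05 QALYs
#>         interpretation
#>     Dominated strategy
#>      Dominant strategy
#>  intervention_dominant
```

The MRI strategy costs less *and* yields more QALYs — it dominates: the
extra $309 scan is more than repaid by averted major strokes (each
costing $6,500 acutely plus $19,062/year thereafter) and the QALY gain
comes from major strokes prevented by timely prophylaxis. No ICER is
reported for a dominant strategy. Absolute magnitudes depend on the life
table (supply a real US table with `read_life_table()`), but the
dominance ordering is the robust finding.

Sensitivity analyses:

```r
one_way_dsa(ranges = data.frame(
  parameter = c("cost_mri", "detection_rate_undetected"),
  low = c(155, 0.05), high = c(500, 0.15)))
#>                   parameter    low   high inmb_low inmb_high   swing dominant_throughout
#> 1 detection_rate_undetected   0.05   0.15 6253.485  5403.323 850.162                TRUE
#> 2                  cost_mri 155.00 500.00 5922.864  5577.864 345.000                TRUE

psa <- run_psa(n_iterations = 3000, seed = 1)
psa   # mean costs/effects per strategy, fraction of iterations dominant
plot(psa)  # cost-effectiveness plane
```

The incremental NMB stays positive across each range
(`dominant_throughout`), and a higher background detection rate of missed
strokes — the largest lever here — narrows but does not erase the MRI
advantage. A command-line wrapper with subcommands (`base-case`, `dsa`,
`icer-curve`, `psa`, `make-life-table`) is installed at
`inst/scripts/stroke-cea.R`.

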