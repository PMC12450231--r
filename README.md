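# coopclim

An evolutionary agent-based simulator of hominin cooperation under
Pleistocene climate constraints in a two-region mountain landscape (a
stylized Tian Shan / Altai corridor). It asks a paleodemographic question:
under which climate regimes, and at which initial levels of cooperative
behavior, can small forager populations persist for a century of monthly
time steps — and when does cooperation itself survive?

The package is written for quantitative archaeologists and cultural-evolution
modelers. Everything user-facing is tidyverse-native: runs come back as tidy
tibbles, fitted/run objects have `tidy()` and `glance()` methods, and every
result type has an `autoplot()`.

## The model in brief

Agents forage on a lattice of 0.5-km² patches split into two climate regions.
Each tick is one month; seasons rotate every three ticks and each of four
climate scenarios prescribes per-region quarterly temperatures (S1 mild
glacial–interglacial average, S2/S3 cold high-seasonality, S4 warm but arid).
Survival is governed by two coupled budgets:

* **Body temperature.** In cold air the body cools toward the ambient
  temperature, `ΔT_b = (T_b − T_c) · CR`, with scenario-specific cooling rate
  `CR`; dropping below 30 °C is death by hypothermia. Shelters (and mild air)
  restore +1 °C per tick, capped at 37 °C.
* **Energy.** Agents spend energy every tick, faster where perceived risk is
  high (sharply so above an 80 % risk threshold), and can recover it only at
  "attractors" — resource-rich shelter places with a finite, regrowing store.

Each adult carries a binary trait, cooperate (1) or defect (0). The trait
dynamics follow a conformist-transmission / payoff-bias model. With
cooperator frequency `p`, the public-goods payoffs with punishment are

    b_c = (1 − e) (pB(1 − e) − C + e(pB − N p₁ ρ))
    b_d = (1 − e) (pB − N p₁ ρ)
    Δb  = b_c − b_d = (1 − e) (N p₁ (1 − e) ρ − C)

and the per-tick change in cooperator frequency is

    Δp = p (1 − p) [ (1 − α) β Δb + α (2p − 1) ]

where `α` is the strength of conformist transmission, `β` a normalization,
`C` the cost of cooperation, `ρ` the punishment, `B` the group benefit, `e`
the probability of failing in cooperation and `p₁` the punisher frequency.
At the agent level the payoff-biased flow is realized as stochastic trait
switching, conformity as a radius-3 neighborhood majority pressure, plus a
small spontaneous-defection probability. Cooperators consume fewer resources
than defectors and are the only agents who can found new shelters — which
requires ≥ 5 km spacing, a half-full patch, and nearby companions. Exhausted
shelters collapse; agents on depleted patches migrate after a waiting period.

The methods vignette (`vignettes/cooperation-climate-model.Rmd`) documents
every parameter, which values come from the published factor tables and
which are this package's own calibrated extrapolations, and the known
limitations of the synthetic landscape.

## Worked example

A mild-scenario run at 80 % initial cooperation on the desk-scale 128 × 64
landscape:

```r
library(coopclim)

cfg <- coop_config(scenario = "S1", width = 128, height = 64, ticks = 600,
                   prob_cooperation = 0.8)
run <- run_simulation(cfg, seed = 42)
run
#> <coop_run> S1 | 600 ticks | survived
#> final population: TianShan 400, Altai 8
glance(run)
#> # A tibble: 1 × 7
#>   scenario ticks final_population final_cooperator_share extinct extinction_tick
#>   <chr>    <int>            <dbl>                  <dbl> <lgl>             <int>
#> 1 S1         600              408                      1 FALSE                NA
table(run$events$event)
#>     birth collapsed     death   founded
#>       606       124       218       128
autoplot(run)   # population, cooperators, defectors per region over time
```

The population persists for the whole 50-year window and ends fully
cooperative (`final_cooperator_share = 1`): with 80 % initial cooperation the
payoff and conformity channels both favor the majority, defectors disappear,
and cooperators keep re-founding shelters as stores are exhausted (128
foundings against 124 collapses here). The same configuration under scenario
`"S2"` (glacial winters of −20 °C in the Altai) typically collapses within a
few simulated years — the contrast the model was built to explore.

The factorial experiment of the study design (probability of cooperation ×
α × cost × scenario, 108 cells × 3 repetitions) is available as:

```r
plan  <- experiment_plan()            # 324 runs with a pure seed schedule
sweep <- run_sweep(plan, coop_config(width = 128, height = 64))
summarize_outcomes(sweep)             # final populations, cooperator shares,
                                      # extinction rates per cell and region
autoplot(sweep, cells = 1:4)          # mean ± sd and min–max bands
```

A thin command-line front end wraps the same functions:

```sh
Rscript scripts/coopsim.R simulate --scenario S1 --seed 1 --out run.csv
Rscript scripts/coopsim.R sweep --repetitions 3 --outdir sweep_out
```

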