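---
title: "An agent-based model of cooperation under climate constraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of cooperation under climate constraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopclim)
```

coopclim simulates small Pleistocene forager populations in a two-region
mountain landscape under four theoretical climate scenarios, coupling an
individual survival physiology (energy and body temperature) to an
evolutionary model of cooperative behavior. This vignette is the package's
methodological record: the model and its assumptions, which parameters are
taken from the published factor tables and which are this package's own
extrapolations, the numerical choices that make the simulator deterministic
and stable, and what the synthetic landscape does and does not emulate.

## The world

The environment is a lattice of patches, each representing 0.5 km² (so one
patch edge is `sqrt(0.5) ≈ 0.7071` km; every km-denominated rule — movement
speed, shelter spacing — is converted through this scale). A boundary column
splits the grid into two regions, Tian Shan to the left and Altai to the
right; the two regions share a landscape but receive different climate
forcing, with the Altai always at least as cold. Ordinary patches hold
uniform-integer resources on [0, 50] with cap 50; a small number of
designated *attractor patches* (three per region by default) hold up to 100
and start full. Only attractor patches regenerate; ordinary patches are a
non-renewable stock, which makes long occupations deplete a neighborhood and
is one of the model's deliberate pressures toward mobility. Elevation can be
attached from an Esri ASCII raster but is metadata only — it has no
dynamical effect, the same choice the source environment makes for water.

The climate forcing is a fixed table: per scenario and region, one annual
"setup" mean used at initialization and four quarterly means that drive the
run. Seasons advance every 3 ticks (one tick = one month) starting in
winter; the forcing is exact table lookup with no interpolation, so
temperature is a 12-tick periodic step function. Scenarios S2 and S3 share
one quarterly block (the printed table provides a single row for both); they
differ in their setup means and, in this implementation, not at all in
quarterly forcing — their printed distinction is carried by the setup values
only, which is how the table is published.

## Agents and physiology

Agents have energy (0–100), body temperature (normal 37 °C), age (months
accumulate at 1/12 year per tick), a strategy trait (cooperate/defect,
unset before age 12), and optional knowledge of a path to a shelter.

**Body temperature.** In cold air the body cools toward the ambient
temperature by `ΔT_b = (T_b − T_c) · CR`. The cooling rate CR is
scenario-specific: 0.02 per tick in the mild scenarios S1/S4 and 0.05 in the
extreme S2/S3 (the source states only that the rate is defined "differently
in the more extreme scenarios"; these magnitudes make unsheltered survival
in an Altai S2 winter a matter of a few months, not years). Below 30 °C the
agent dies of hypothermia. Shelters warm occupants by +1 °C per tick, capped
at 37 °C (the cap is our addition; warming is stated without one).

A calibration decision worth flagging: applied unconditionally, the cooling
law kills every unsheltered agent even in a 24 °C summer, because any
ambient below 30 °C eventually drags the body below the threshold — which
would make all four scenarios uniformly lethal and contradict the viable
mild-scenario populations the model is supposed to produce. We therefore
gate the law with a thermoregulation threshold `comfort_temp` (default
10 °C): below it the cooling law applies; at or above it thermoregulation
succeeds and the body recovers at the shelter warming rate. At 10 °C this
reproduces the intended gradient — in S1/S4 the Tian Shan is survivable
outdoors most of the year, the Altai marginally, while in S2/S3 every
quarter in the Altai (and all but summer in the Tian Shan) cools.

**Energy.** Agents spend energy every tick: the scenario base cost (1 per
tick in S1/S4, 2 in S2/S3) times a perceived-risk multiplier. Risk is
`100 · clip(0.5 · d/d_max + 0.5 · (1 − resource fraction))` with `d` the
distance to the nearest active shelter (dropped entirely when no shelter is
active) and `d_max` the grid diagonal; standing on an active shelter means
risk 0. Below the 80 % risk threshold the multiplier is a mild
`1 + human_risk/100 · risk/100` (human-risk default 5); above it, a sharp
`1 + (risk − 80)/20`. Energy can only be restored at shelters. Reaching 0
is death.

**Demography.** Initial ages are uniform integers on 1–50. Death from age
uses a hard cap at 50 years by default (matching a stated mean mortality
around 50); a geometric hazard with the same mean lifespan is
config-selectable. Adults (age ≥ 12) reproduce with probability 0.10 per
tick; newborns appear at the parent's position with full energy and an
unset trait. Births are suppressed while the total population is at or
above `max_population` (default 400) — a demographic ceiling we add because
a 10 %-per-month fertility with store-fed shelters otherwise grows without
bound; the value is at the scale of plausible regional forager populations
and also bounds the cost of a run.

**Movement and learning.** Agents move 0.75 km per tick. Naive agents
random-walk; with probability `learning_rate` (default 1) per tick an agent
learns the path to the nearest active shelter in its current region
(smallest id on ties) and then moves greedily toward it, settling once
within the occupancy radius (1 patch). Knowledge is reset when the known
shelter collapses. Partial steps land on the nearest patch center and
positions are clipped to the grid.

## Cooperation

Adults carry trait 1 (cooperate) or 0 (defect). The region-level bookkeeping
each tick computes the cooperator frequency `p`, the payoffs

$$b_c = (1-e)\,(pB(1-e) - C + e(pB - N p_1 \rho)), \qquad
  b_d = (1-e)\,(pB - N p_1 \rho),$$

their closed-form difference `Δb = (1−e)(N p₁ (1−e) ρ − C)`, and the
frequency change

$$\Delta p = p(1-p)\,[(1-\alpha)\beta\,\Delta b + \alpha(2p-1)],$$

clamped so `p + Δp` stays in [0, 1]. The published factor table fixes
`C = 10`, `ρ = 7`, `α = 0.20`, initial cooperation probability 0.20 and
spontaneous-defection probability 0.001; it does not fix `β`, `e`, `B` or
`p₁`. Our extrapolations: `e = 0.1`, `B = 20`, `p₁ = p` each tick
(cooperators carry the punishment role; its cost is already inside `C` and
`ρ`), and `β = 0.05`, sized so that the payoff-biased term `|βΔb|` (about
0.5 at default payoff scales) is comparable to the conformist term (about
0.2). With a much smaller `β` payoff bias is negligible against conformity:
cooperation then dies out regardless of its cost and the cost factor loses
all effect, which is inconsistent with the cost-of-cooperation results the
model exists to explore.

The population-level equation is coupled to agents as a three-stage
per-region update:

1. **Payoff-biased drift.** `|Δp_payoff| · N` adults of the disfavored
   strategy switch toward the favored one, where
   `Δp_payoff = p(1−p)(1−α)βΔb` and the count is *stochastically rounded*
   (floor plus a Bernoulli draw on the fraction) so the realized flow equals
   the equation's in expectation even when `|Δp|·N < 1`. Deterministic
   ceiling rounding was rejected: it turns any nonzero drift into at least
   one switch per tick, an order-of-magnitude overshoot at small N that
   absorbs every minority within tens of ticks.
2. **Local conformity.** Each adult whose radius-3 neighborhood (Euclidean,
   excluding self) holds a strict majority of the opposite strategy switches
   with probability `α`; majorities are evaluated simultaneously and ties
   exert no pressure. Because this stage realizes the conformist channel
   spatially, the drift stage deliberately carries only the payoff term —
   driving stage 1 with the full `Δp` would count conformity twice.
3. **Spontaneous defection.** Each cooperator defects with probability
   0.001.

Juveniles reaching age 12 adopt the strict-majority strategy within the
radius; with no trait-bearing neighbors (or a tie) they draw
Bernoulli(initial cooperation probability). Strategy also shapes
consumption: cooperators draw 1 resource unit per tick, defectors 2,
juveniles 1, all ×1.25 in the Altai where resources are more limited; S4
expresses its aridity through halved patch caps instead of higher draws.

## Shelters

Shelters ("attractors" in the model's vocabulary, not the dynamical-systems
sense) grant warmth and energy. The six initial shelters sit on the
attractor patches with a store of 500 energy units each. Occupants within 1
patch draw up to 5 energy per tick, rationed pro rata when the store cannot
serve everyone; cooperators and defectors are served identically. Occupants
are provisioned by the store rather than the landscape: their upkeep (the
base energy cost) and their consumption draw are debited from the store, so
defector-heavy crowds drain shelters roughly twice as fast — which is how
"excessive resource consumption" makes a shelter disappear. For the same
reason occupants are exempt from the patch-based migration trigger; without
that exemption the depleting patch under a shelter would evict its own
occupants into lethal cold and shelters could not function at all. A patch
hosting an active shelter routes its regrowth (default 40 units per tick)
into the store; a bare attractor patch regrows itself, which is what makes
re-founding possible after a collapse.

Founding is a cooperator initiative, attempted in agent-id order within a
tick (sequential processing keeps the spacing invariant deterministic):
the candidate patch must be ≥ 5 km from every active shelter, hold at least
50 % of its cap (we read the stated "50 % of its available resources"
against the patch, the sentence's subject), and the initiating cooperator
needs company — at least 1 cooperator and 2 agents total within the
strategy radius, not counting the initiator (the source requires "a limited
number of cooperators" without values; both thresholds are config-exposed).
A store reaching exactly 0 deactivates the shelter (strict zero rule: 0.01
stays active); inactive shelters are invisible to learning, risk and
services, and their sites can be founded again.

## Migration

A patch below 20 % of its cap counts as depleted. An unsheltered agent
whose patch has been depleted for 6 consecutive ticks (the "period of time"
is unstated; 6 months is our choice) targets the nearest viable patch —
preferring patches within the strategy radius of an active shelter — and
walks there; cross-region moves are allowed by default. If nothing on the
map is viable the agent stays and keeps foraging locally.

## Scheduling, determinism and numerical choices

Each tick runs: (1) climate update and body-temperature physiology,
(2) learning, (3) cooperation, (4) consumption, shelter services and energy,
(5) shelter founding/collapse and regrowth, (6) migration and movement,
(7) aging, trait adoption and reproduction, (8) bookkeeping. Dead agents are
removed at the stage where death fires, with the cause (energy,
hypothermia, age) logged as an event; every run satisfies
`N(t+1) = N(t) + births − deaths` and
`cooperators + defectors + juveniles = N` at every recorded tick.

A run uses one RNG stream seeded once; regions are processed in a fixed
order (Tian Shan, then Altai), so identical (config, seed) pairs give
bit-identical results. Extinction ends a run early and pads the series with
zero populations to keep result shapes rectangular. Other numerical
choices: resource stocks are continuous non-negative reals with uniform
*integer* initial draws; consumption aggregates demand per patch and floors
at zero; `Δp` is clamped into the frequency simplex before use; nearest-
shelter ties break on the smallest id; the default simulation start is
winter (the harshest season exercises early-life rules first, and it is
configurable).

## The synthetic landscape, and what passing tests do not show

The default landscape generator emulates the study environment — a
534 × 328 grid split into two regions, uniform resources, spaced attractor
patches — but places attractor patches uniformly at random within each
region rather than at real site locations (a loader for site coordinate
tables and elevation rasters is provided). It does not emulate: the real
geography and clustering of sites, hydrology, elevation effects, or any
spatial autocorrelation in resources. Results on the synthetic landscape
therefore speak to the model's mechanisms (when cooperation persists, how
shelters structure survival), not to predictions about real site locations
— the same caveat the source analysis makes about its own use of
archaeological points.

The test suite exercises desk-scale problems: unit tests on grids around
40 × 20, full qualitative checks on a 128 × 64 landscape with 10 agents per
region, 1200 ticks and ten seeds per condition, and the stress test of the
spacing rule on 48 × 24 with dense cooperator clusters. The full published
grid (534 × 328) is supported and used for generator tests, but the
dynamics checks run at the smaller scale, which keeps the whole suite in a
few minutes while preserving every mechanism (both regions, all stages,
founding and collapse cycles, migration waves).

## Known limitations

* The cooperation decision algorithm at agent level is unspecified in the
  source; our three-stage rule is one faithful realization, and its
  conformity stage is stronger than the equation's conformist term in
  well-mixed populations (it is spatial, which is the point).
* `β`, `e`, `B`, `p₁`, cooling rates, shelter economics and the
  thermoregulation threshold are calibrated extrapolations — defensible,
  config-exposed, but not printed values; conclusions that hinge on their
  exact magnitudes should sweep them.
* Non-attractor patches never regenerate, so century-scale runs on small
  grids inevitably mine the landscape; population ceilings and shelter
  regrowth set the sustainable scale.
* The demographic ceiling truncates booms; comparisons between scenarios at
  the ceiling understate differences in growth rate (extinction contrasts
  are unaffected).
* The published run total for the factorial design (216) does not factor
  into its stated 108-cell × 3-repetition grid; `experiment_plan()` follows
  the grid (324 runs) and we do not guess at the composition behind the
  printed total.
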