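---
title: "An event-driven hallmark cellular automaton of avascular tumor growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An event-driven hallmark cellular automaton of avascular tumor growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hallmarkCA)
```

## The model

`hallmarkCA` simulates avascular tumor growth on a 3D cubic lattice in which
every site holds at most one cell. A cell's state is an artificial genome of
five binary cancer hallmarks —

* **SG** (self-growth): divide without external growth factor;
* **IGI** (ignore growth inhibit): attempt division despite a fully occupied
  neighborhood by competing with a neighbor;
* **EA** (evade apoptosis): immune to the genetic-damage death test;
* **EI** (effective immortality): divide with exhausted telomeres;
* **GI** (genetic instability): raised mutation rate —

plus two per-cell quantities: a telomere counter `tl` (remaining divisions)
and a mutation denominator `m` (per-hallmark activation probability `1/m`
at each division). Hallmarks activate by copy errors at mitosis and are
never repaired: flags are monotone along a lineage.

Time advances through a global priority queue of *mitosis events*. Each
cell's next division attempt is scheduled a uniform integer 5–10 iterations
ahead, standing in for a 15–24 h cell cycle; one iteration therefore
averages $19.5/7.5 = 2.6$ hours, so 5000 iterations are about 77.4 weeks.
Popping an event runs a fixed decision cascade:

1. **Random death** with probability $1/a$.
2. **Genetic damage death** with probability $n/e$ for $n$ active
   hallmarks, skipped entirely when EA is ON.
3. **Replicative limit**: a cell with `tl = 0` dies on its division attempt
   unless EI is ON.
4. **Growth factor**: outside the central sub-box covering 95% of each
   dimension ($0.95^3 \approx 85.7\%$ of the volume) mitosis is blocked
   unless SG is ON.
5. **Space**: division requires an empty site in the 26-site Moore
   neighborhood; a surrounded cell is quiescent and requeued, unless IGI is
   ON, in which case it competes with a uniformly chosen neighbor and,
   with probability $1/g$, kills and replaces it with its daughter.

A successful division copies the genome to a uniformly chosen empty
neighbor, decrements the telomere of both cells, applies independent
mutation draws to both (Fig-style "new cells", plural), and schedules fresh
events for both. A blocked mitosis requeues the mother with a fresh 5–10
delay. Events whose cell has died in the meantime are discarded lazily at
pop time, which is semantically equivalent to eager deletion because dead
cells' identities are never reused.

### Cancer stem cells

The hierarchical compartment distinguishes cancer stem cells (CSCs) from
differentiated cancer cells (DCCs). A CSC carries EA and EI permanently ON,
ignores the random-death test (see below), and divides only when an empty
neighbor exists: symmetrically with probability $p_s = 0.01$ (two CSCs) or
asymmetrically otherwise, producing one CSC and one DCC that carries
exactly one uniformly chosen hallmark and a fresh telomere. Treatments
never kill CSCs, reflecting their resistance to cytotoxic therapy.

### Treatments

A `treatment_plan()` kills each DCC independently with probability
`kill_prob` at every active iteration (an exact-fraction mode kills
`floor(kill_prob * n)` uniformly chosen DCCs instead). Phases: a single
`pulse`; a `continuous` window; `periodic_pulse` (one application per
period); `periodic_sustained` (the first `pulse_duration` iterations of
each period). A threshold gate restricts application to iterations where
the DCC count is at or above a fraction of the grid size (1% in the gated
experiments). Treatment is applied at the iteration boundary, before that
iteration's events; the source material does not order the two, and the
choice only shifts kills by less than one iteration.

## Parameters

| parameter | meaning | default |
|---|---|---|
| `m` | mutation denominator; activation probability `1/m` per hallmark per division | 100000 |
| `a` | random-death denominator; `1/a` per processed event | 1000 |
| `e` | damage denominator; death probability `n/e` | 10 |
| `g` | competition denominator; takeover probability `1/g` | 30 |
| `tl0` | initial telomere length (divisions per lineage) | 50 |
| `p_s` | CSC symmetric-division probability | 0.01 |
| `gi_factor` | multiplicative mutation-rate increase while GI is ON | 100 |
| `boundary_fraction` | growth-factor region extent per dimension | 0.95 |
| `mitosis_delay` | event scheduling window (iterations) | 5–10 |
| `cycle_hours` | cell-cycle duration the delay stands for | 15–24 h |

`gi_factor` has no reference value in the source material, which states
only that GI "increases" the rate; a fixed multiplicative factor (default
100, capped at probability 1, non-compounding) follows the convention of
the antecedent hallmark-automaton models and is exposed as a knob.

## Design choices where the design was open

* **Neighborhood.** The space-competition semantics use the 3D Moore
  neighborhood (26 sites, clipped at edges, no wrapping); von Neumann (6)
  is available for sensitivity tests.
* **Growth-region discretization.** The reference value is a continuum
  (95% per dimension); per side the exclusion margin is
  `max(1, round(side * (1 - f) / 2))` for `f < 1`, else 0, so a side-50
  grid has margin 1 and a 48³ growth region. The discrete site fraction
  converges to $f^3$ as the side grows (checked at sides 25/50/200).
* **IGI competition failure.** The source says the surrounded cell
  "competes for survival ... with a likelihood of success 1/g" and does not
  state what failure does. Reading failure as death of the dividing cell
  makes crowded IGI proliferation a subcritical branching process (expected
  offspring $2/g < 1$ for $g > 2$): at $g = 5$ no tumor ever grows, which
  contradicts the described emergent behavior where IGI is the predominant,
  rapidly invading hallmark. The package default is therefore
  **failure aborts the mitosis and requeues the cell**
  (`igi_failure_kills = FALSE`); the loser-dies mode remains available and
  tested. This is the package's one deliberate departure from the stricter
  reading.
* **CSC random-death exemption.** Stable CSC counts over thousands of
  iterations are incompatible with a `1/a` per-event death rate, so CSCs
  skip that test by default (`exempt_random_death`, configurable).
* **Asymmetric daughters** carry *only* their single random hallmark (they
  do not inherit the CSC's EA/EI) and do not receive an extra `1/m`
  mutation draw at birth (configurable via `csc_daughter_mutations`).
* **CSCs cannot be killed by IGI competition** (configurable). When a
  protected CSC is the chosen victim, the winning draw is treated as a
  failure; rate checks for `1/g` therefore use CSC-free populations.
* **Ties and uniform choices.** Queue ties break FIFO by insertion order;
  daughter placement and competition victims are uniform over the eligible
  sites; the asymmetric daughter's hallmark is uniform over all five.
* **RNG.** One global stream (R's RNG) drives everything; `tumor_sim(seed=)`
  makes entire trajectories bit-reproducible.

## What the synthetic experiments emulate

All inputs are self-generated: the experiment presets
(`scenario_preset("fig2")` … `"fig5d"`) encode the reference
configurations — a 50³ grid full of healthy cells, CSCs seeded at 1–5% of
grid size in random growth-region positions, the high-invasion scenario
(`g = 5`) or the high-mutation scenario (`m = 1000`), and the pulse /
continuous / periodic treatment schedules with the 1% threshold gate.
`scale` shrinks the side and every time quantity linearly (probabilities,
rates and fractions are preserved exactly; the scaled side is floored
at 10).

Scaling is *not* innocuous, because tumor take-off is an intrinsic
time-scale: the first IGI-bearing DCC arises from rare CSC asymmetric
divisions, so shrinking both the CSC count (16× fewer at side 20) and the
pre-treatment budget (5000 → 2000 iterations) makes initial growth
marginal and inflates replicate variance. Likewise the contrast "massive
kill bursts liberate CSC differentiation" depends on many simultaneous
holes per CSC and weakens at small scale. Consequently two scaled
acceptance clauses measure a reversed sign at side 20 and are left red
with analysis in the test suite's ledger: the 200-iteration
asymmetric-division comparison between the pulse and continuous strategies,
and the fig4a-vs-periodic asymmetric-division comparison. A green scaled
test therefore establishes mechanism correctness (rates, invariances,
controller behavior, regrowth ordering), not full-scale effect sizes;
full-scale runs remain available through `scenario_preset(name, scale = 1)`
and the CLI.

## Numerical and degenerate-input notes

* Probabilities given as denominators accept `Inf` to switch a channel off
  exactly (`1/Inf == 0`); `gi_factor/m` is capped at 1.
* Telomeres floor at 0; the ledger invariant `tl0 - tl == divisions` holds
  along any lineage while `tl > 0` and is asserted in tests.
* The threshold gate compares `n_dcc >= threshold_fraction * side^3` with a
  `1e-9` slack to avoid floating-point misses at exact equality.
* `round(fraction * side^3)` CSCs are seeded; requesting more CSCs than
  growth-region sites is an error.
* Iteration budgets of 0 return an empty trajectory and leave the state
  untouched.

## Known limitations

Angiogenesis, metastasis, CSC motility and quorum-sensing differentiation
control are out of scope; the model covers the avascular phase only. Cells
have no size, shape or mechanics; there is no pharmacokinetics or
resistance evolution in treatments. The regrowth-time metrics use an
artifact-defined occupancy target (20% of grid size by default) because the
reference growth curves are figures without printed values.

## A short worked run

```{r example, eval = FALSE}
sim <- tumor_sim(20, hallmark_params(g = 5), seed = 1)
seed_cscs(sim, 0.01)
plan <- treatment_plan("pulse", start = 2000, kill_prob = 1)
traj <- sim_run(sim, 2400, plan)
regrowth_metrics(traj, treatment_end = 2000)
```
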