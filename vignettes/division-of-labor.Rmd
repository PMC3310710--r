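---
title: "Model and methods: evolving neural-network workers for division of labor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: evolving neural-network workers for division of labor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dolsim` simulates the evolution of task-allocation behavior in colonies of
social insects. This vignette is the package's own account of the model, its
tunable parameters, the numerical and design choices made where the design
was genuinely open, and what the scaled-down test runs do and do not show.

## The model

**Colony life cycle.** A population holds `M` colonies, each founded by a
single-mated pair (a foundress and her mate). Every generation each colony
produces `N` workers, runs a *work phase* of `T` time steps, is scored for
fitness, and contributes sexuals to a common pool in proportion to that
fitness. The `2M` sexuals form `M` random pairs that found the next
generation's colonies; the population size is fixed.

**Stimulus dynamics.** Two task-associated stimuli `s1, s2 >= 0` encode the
colony's need for work. At the start of each time step both rise by `delta`
(inflow of work demand). Whenever a worker performs task `j`, `s_j` drops by
`alpha` immediately — floored at 0 — so workers polled later in the same
step already see the reduced demand. Workers are polled in a fresh uniform
random permutation each step.

**Worker behavior.** A polled worker perceives each stimulus with error:
`s~_j = s_j + e_j`, `e_j ~ N(0, noise_sd)` drawn independently per input and
per assessment (`noise_sd = 1` is the model's standard value; perceived
values are *not* clamped at 0). Its two output neurons compute linear
activation energies

```
E_i = w_1i * s~_1 + w_2i * s~_2            (feedforward)
E_i(t) = ... + u_i * E_i(t-1)              (recurrent)
```

with no squashing function. Neuron `i` is active iff `E_i > theta_i`
(strict). No active neuron: the worker idles. One: it performs that task.
Both: a fair coin decides. With identity weights (`w11 = w22 = 1`, cross
weights 0) and `u = 0` this reduces exactly to the response-threshold rule,
which is both the ancestral state of every simulation and a permanent
special case of the architecture.

**Switching costs.** If the chosen task differs from the worker's previous
task, the decision is a *switch*: with cost `c > 0` the worker performs no
act that step and stays inactive for the next `c` steps; with `c = 0` the
switch completes as a normal act. The worker's task memory updates at
decision time, so it does not pay twice for the same change.

**Fitness and selection.** Colony fitness is the weighted geometric mean of
acts per task, `F = A1^beta * A2^(1-beta)` — zero unless both tasks are
performed, and maximized for fixed total work when the share of task 1
equals `beta`. The maximum `F_max = N*T*beta^beta*(1-beta)^(1-beta)` (full
employment at the optimal split) normalizes the reported relative fitness.
Sexual production is a fitness-proportional multinomial over colonies
(stochastic, with the biologically expected drift), followed by random
pairing.

**Genetics.** The network parameters are haploid loci: 6 expressed loci for
the feedforward architecture, 8 for the recurrent one (self-feedback weights
exist but are fixed at 0 under feedforward). The two threshold loci form one
linkage group, the six weight loci the other; the groups always segregate
independently. Within a group, with probability `1 - r` the whole block is
copied from one uniformly chosen parent, otherwise every locus picks its
parent independently. Mutation hits each expressed locus with probability
`mu`, adding a `N(0, sigma_m)` step; thresholds are clamped at 0 afterwards,
weights may take either sign.

**Worker specialization.** For every worker with at least two work
decisions, `C_k` is the fraction of consecutive decision pairs on the same
task. The colony statistic is `D = mean(C_k) / (q1^2 + q2^2) - 1`, where
`q_i` is the colony's share of work on task `i`, so `D ~ 0` under random
task choice, `D -> 1` for strict specialists at an even split, `D < 0` for
over-switching. `D` is reported unclamped; since `q1^2 + q2^2 >= 1/2` the
statistic is bounded by 1 above and by -1 below exactly when `C = 0`.

## Parameters, defaults, and why

| parameter | meaning (units) | default | rationale |
|---|---|---|---|
| `M`, `N`, `T_steps` | colonies, workers, work-phase steps | 100 / 100 / 100 (`preset_scaled()`: 50/50/50) | magnitudes consistent with multi-thousand-generation dynamics; the scaled preset keeps test runs tractable |
| `beta` | fitness weight of task 1 (0,1) | 0.5 | symmetric reference case; 0.75 for the 3:1 demand scenario |
| `delta` | stimulus inflow per step (stimulus units) | 1 | sets the stimulus scale relative to the unit perception noise |
| `alpha` | stimulus drop per act | `3*delta/N` | see below |
| `noise_sd` | perception error SD | 1 | the model's standard value |
| `c` (`switch_cost`) | idle steps per task switch | 0 | scenario parameter, 0–5 |
| `r` | within-block recombination probability | 0.5 | free recombination reference; 0 for tight linkage scenarios |
| `mu`, `sigma_m` | mutation probability / step SD per locus | 0.01 / 0.1 | conventional rates for real-valued evolutionary simulations at this population size |
| `init_theta`, `init_w_direct`, `init_w_cross` | founder network | 1 / 1 / 0 | the response-threshold special case at a mid-range stimulus value; self-feedback always starts at 0 |
| `init_stimulus` | starting stimuli | (0, 0) | work demand builds up from nothing |

**Why `alpha = 3*delta/N`.** The per-act stimulus drop determines how much
work the stimuli can "pay for": pure stimulus-following workers can sustain
at most `delta/alpha` acts per task per step, i.e. a fraction
`2*delta/(alpha*N)` of the colony's worker-steps. If `alpha <= 2*delta/N`
that fraction reaches 1: plain threshold-following already eliminates
idleness, nothing favors the evolution of ratio biases or
stimulus-decoupled work, and the model loses its central trade-off. The
default follows the convention of the classic fixed-threshold simulations
(inflow 1, colony-size-scaled absorption 3), capping stimulus-following
employment at 2/3 so that strategies decoupling work from depleted stimuli
(cross-stimulation, self-feedback) carry a real fitness premium.

## Numerical and design choices

* **Strict activation (`E > theta`).** Ties at equality count as inactive.
  Consequence: a stimulus floored at exactly 0 cannot activate a
  zero-threshold neuron through its direct weight at zero noise.
* **Threshold clamp at 0** after mutation (not reflection or resampling):
  the simplest monotone map preserving non-negativity; about half of the
  mutations of a threshold sitting at 0 leave it there.
* **Switch semantics.** The switch decision itself consumes the act and
  starts the `c`-step penalty; the alternative (performing the first act of
  the new task after the penalty) would shorten effective penalties by one
  act and was not adopted.
* **Recurrent memory during penalties.** A penalized worker does not assess
  stimuli; its stored activation energy is held frozen rather than decayed
  through the feedback weight. This is the main untestable interpretive
  choice in the recurrent architecture and is isolated in one code branch
  should sensitivity analysis be wanted.
* **`C_k` over work decisions, not raw time steps.** With switching costs,
  literal consecutive-step comparisons would conflate enforced idleness with
  behavioral switching; pairs of successive work decisions (acts and switch
  decisions) skip idle and penalty steps.
* **Branching detection.** Exact 1-D two-means on the pooled parent alleles
  of a locus; "bimodal" requires cluster separation `> k` pooled
  within-cluster SDs and at least 5% of values per cluster. Two-means on a
  *unimodal* Gaussian yields a separation ratio concentrated near 2.65
  (cluster means ±sqrt(2/pi), within-SD sqrt(1 - 2/pi)), so the default is
  `k = 3`, above the Monte-Carlo 95th percentile of that null at n = 200.
* **Y/N/P outcome classification.** A replicate satisfies a result
  population-wide when at least 90% of its colonies do (a strict "all
  colonies" reading would be destroyed by single-colony noise). `Y` = every
  replicate population-wide; `P` = a nontrivial fraction (>= 10% of
  colonies) in the majority of replicates; `N` otherwise.
* **RNG.** The compiled engine uses xoshiro256++ seeded through splitmix64
  from the single run seed, with Marsaglia–Tsang ziggurat normals and Lemire
  bounded integers; one stream drives a whole run, so a seed fixes every
  byte of the output logs. The R-level operation surface uses R's own RNG;
  the two paths are reconciled by trace replay (the engine records its
  random inputs, an independent R simulator must reproduce every action and
  stimulus exactly) and by distributional tests, never by sharing streams.
* **Logs.** Tab-separated text with 17-significant-digit numerics (exact
  double round trip); every run directory carries a manifest with the
  resolved configuration, which keys were defaulted, the seed and the RNG.

## What the simulations show at scaled size — and what they cannot

The test suite and the acceptance script run the model at `M = N = T = 50`
(one batch at `M = 30`), a quarter or less of the full-size population, for
1500–6000 generations. At this scale all qualitative phenomena of the model
appear: the feedforward architecture's evolved work-ratio bias (folded
proportion ~0.3 with ~90% relative fitness, despite a symmetric optimum),
the 3:1 demand case approaching a 0.75 work share, specialization under
switching costs carried by evolutionary branching of cross-connection
weights into opposite-sign branches, and the recurrent architecture's
experience-based specialization and over-switching equilibria with
self-feedback loci branching under tight linkage.

Three scale effects matter when comparing numbers with full-size runs, and
they explain why some acceptance checks are deliberately left failing
rather than loosened:

1. **Halved mutational supply and stronger drift.** Evolutionary transitions
   (the ratio-bias escape, branching onset) are waiting-time phenomena;
   at `M = 50` they scatter over thousands of generations, so fixed-length
   runs catch some replicates mid-transient. Percentages of specialized
   colonies measured at a fixed generation are systematically below
   full-scale values.
2. **Mirror-basin trapping.** With asymmetric demand (`beta = 0.75`) the
   direction of the ratio escape is decided early, when the fitness
   difference between the two directions is second-order; small populations
   sometimes commit to preferring the *wrong* task and stay there, which
   full-size populations essentially never do. Mixed replicate sets
   therefore average below the optimal work share.
3. **Extreme-value statistics.** Quantities like "the minimum colony fitness
   in the population" scale badly: with `N*T = 2500` acts per colony the
   worst of 50 colonies sits ~10% below the population mean from sampling
   noise alone, against ~1% at full size.

The synthetic dynamics emulate demand-driven task allocation with
noise-limited perception; they do not emulate task heterogeneity in space or
effort, more than two tasks, within-lifetime learning, morphological castes,
or multiple mating — all outside the model family.

## Limitations

* The population loop is sequential; replicate batches parallelize at the
  process level (distinct seeds), not within a run.
* `D` is undefined (reported `NA`) for colonies in which no worker makes two
  work decisions — relevant only for pathological configurations.
* Work-phase trace recording, used by the equivalence tests, is limited to
  small `N * T` for memory reasons.
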