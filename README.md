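# dolsim

Evolutionary agent-based simulation of self-organized division of labor in
social-insect colonies whose workers decide between two tasks with small
evolvable neural networks.

## The scientific problem

In the classic response-threshold picture, a worker performs a task when the
task-associated stimulus exceeds an internal threshold. Stimuli reflect the
colony's need for work: each time step both stimuli rise by a fixed amount
δ, and every act of work lowers the corresponding stimulus by α. `dolsim`
replaces the hard-wired threshold rule with the simplest evolvable neural
architectures around it and asks what task-allocation behavior natural
selection actually builds:

* **feedforward** — two stimulus inputs, two task outputs, all four
  connections evolvable. A worker perceives each stimulus with Gaussian error
  (s̃ⱼ = sⱼ + εⱼ, εⱼ ~ N(0,1)) and computes an activation energy per output
  neuron, `E_i = w_1i·s̃₁ + w_2i·s̃₂`. Output `i` fires iff `E_i > θ_i`; one
  firing neuron means that task is performed, two mean a fair coin decides,
  none means the worker idles. With `w11 = w22 = 1`, `w21 = w12 = 0` this is
  exactly the response-threshold rule.
* **recurrent** — the same network plus an evolvable self-feedback weight per
  output, `E_i(t) = w_1i·s̃₁ + w_2i·s̃₂ + u_i·E_i(t−1)`, letting previous
  experience influence current decisions.

Each generation, `M` colonies (each founded by one single-mated pair) run a
work phase of `T` steps with `N` workers polled in random order; performing a
task immediately depletes its stimulus, so later workers in the same step see
the updated demand. Switching tasks can cost `c` enforced idle steps. Colony
fitness is the weighted geometric mean of the work done for the two tasks,

    F = A₁^β · A₂^(1−β),

which is zero unless both tasks are performed and, for a fixed total, is
maximized when the proportion of work on task 1 equals β. Colonies seed the
next generation's 2M sexuals in proportion to F; sexuals pair at random. The
six (feedforward) or eight (recurrent) network parameters are haploid loci:
the two thresholds form one linkage block, the weights the other, blocks
segregate independently, and with probability `r` the loci within a block are
transmitted independently instead. Mutation adds N(0, σ_m) per locus with
probability μ (thresholds clamped at 0).

Worker specialization is measured by

    D = C̄ / (q₁² + q₂²) − 1,

where C̄ averages each worker's fraction of consecutive work decisions that
stayed on the same task and q₁² + q₂² is the chance-stay probability at the
colony's work ratio: D ≈ 1 for strict specialists, ≈ 0 for random task
choice, < 0 for over-switching. Evolutionary branching of connection-weight
loci (detected by a 1-D two-means split) is the genetic signature of
colonies mixing two specialist network types.

The package is aimed at theoreticians studying the interplay of
self-organization and evolution in task allocation: it exposes every layer
(genome, network, colony work phase, selection loop, metrics, config/logs)
as documented R functions, with the hot loops compiled.

## Worked example

A scaled-down run (M = N = T = 50) of the feedforward architecture with
β = 0.5, no switching costs, stimulus inflow δ = 1 and per-act depletion
α = 3δ/N:

```r
library(dolsim)
cfg <- preset_scaled(alpha = 3 / 50, seed = 12)   # feedforward, beta 0.5
sim <- run_evolution(cfg)
summary(sim)
#> Quasi-equilibrium over the final 100 generations:
#>   mean p1             0.7007 (folded: 0.2993)
#>   mean F_rel          0.8899
#>   min colony F_rel    0.7860
#>   mean D (final gen)  0.0665
#>   % colonies D > 0.5  0.0
```

Although β = 0.5 makes a 1:1 work ratio optimal, the population evolves a
biased ratio — here ~70% of all acts go to one task (folded proportion 0.30
for the other) — because networks that use the *other* task's stimulus as
their motivation can keep working after their own stimulus is depleted,
eliminating idleness at the cost of a skewed ratio. The colony then reaches
~89% of the theoretical maximum fitness `N·T·β^β(1−β)^(1−β)`, the ceiling
imposed by the ratio bias, while worker specialization stays near zero.

The phenotype of any genotype can be mapped over stimulus space:

```r
g <- genotype(theta = c(1.1, 0.9), w = c(0.2, 2.6, 0.1, 1.2))
m <- response_map(g, s1 = seq(0, 4, 2), s2 = seq(0, 4, 2))
table(m$label)
#>  none task1 task2  both
#>     3     0     0     6
```

`run_replicates()` repeats a configuration under distinct seeds and reports
the across-replicate mean ± SD of the work ratio, % specialized colonies and
relative fitness; `classify_outcome()` condenses replicate sets into the
Y/N/P outcome notation; `detect_branching()` tests a locus for a bimodal
allele split. A thin command-line front end lives in `inst/cli/dolsim.R`
(subcommands `simulate`, `replicate`, `summarize`, `response-map`) and runs
off plain YAML configs and tab-separated logs.

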