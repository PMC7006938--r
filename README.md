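# animats

Evolution and reliability of Markov-brain animats in groups.

`animats` is an R implementation of a multi-agent artificial-life platform:
groups of clone agents ("animats") controlled by genome-encoded Markov
brains evolve a two-room spatial-navigation task, are re-tested after
evolution under modified group sizes, interaction rules and wall
arrangements to quantify their *reliability*, and have their brain
complexity measured with integrated-information metrics.

## The model

**Task.** A 32 x 32 grid world contains two rooms connected by a gate and 72
uniformly distributed start slots. In each trial of `T = 500` timesteps a
group of clones is placed on random slots with random orientations and
updated serially in a random order: sense → update brain → act. An animat's
score is

```
f(a) = Σ_t [ crossing at (t, t+1) is rewarded ]·(+1.0)  −  Σ_t [ c(x(a), y(a), t) > 1 ]·(0.075)
```

A gate crossing is rewarded only if no crossing of any kind occurred in the
preceding 100 timesteps (the refractory period) and the animat has fewer
than 4 rewarded crossings, so a trial is worth at most **4 points**. The
collision penalty applies per timestep of co-occupancy; under *blocking*
animats can never share a cell. A genome's fitness `F` is the mean over 30
trials of the score of one randomly picked clone.

**Brains.** A Markov brain is a set of binary units — sensors (range-one
wall/agent/universal detectors), memory units, and two motors (`11` =
forward, `10`/`01` = turn, `00` = rest) — updated by deterministic lookup
gates. Gates are encoded in a genome of 2,000–20,000 integer loci in
[0, 255]: each start codon (42, 213) opens one gate whose header bytes give
the input/output arity (1–4), the connected units, and the lookup table.
Evolution is asexual: fitness-proportional selection plus per-locus point
mutations and occasional segment insertions/deletions; there is no
crossover.

**Reliability.** After evolution, the best genome is re-tested across the
21-element group-size vector `GS = [1, 4, 7, ..., 68, 72]` and eight test
conditions (four interaction-rule variants on the original map, four
modified maps). Reliability is the mean task fitness across group sizes in
the Original condition:

```
R = <TF_Original>_GS ,   |GS| = 21
```

**Brain complexity.** For every brain state visited during a trial the
package evaluates integrated information Φ over all candidate subsets of
computational units (exhaustive cause/effect-repertoire partition search,
earth mover's distances, unidirectional system cuts) and reports
`Φ^Max = max_S Φ` together with the number of concepts of the maximizing
subsystem.

## Worked example

```r
library(animats)

cfg <- evolution_config(setup = "0.25", population_size = 50,
                        generations = 300, trials_per_genome = 10, seed = 11)
lin <- evolve(cfg)
glance(lin)
#> # A tibble: 1 × 6
#>   setup generations population_size    EF final_mean_fitness  seed
#>   <chr>       <int>           <int> <dbl>              <dbl> <int>
#> 1 0.25          300              50   0.1             -0.217    11
```

The lineage starts near a mean fitness of −5 (random seeded brains collide
constantly in a group of 18) and climbs toward 0 as selection removes
collision-prone movers; `EF` is the best final-generation fitness, here a
brain that has begun to earn gate rewards. `autoplot(lin)` draws the fitness
curves, and the evolved brain feeds straight into the post-evolution
analyses:

```r
b <- best_brain(lin)
sw <- task_fitness_sweep(b, sweep_spec(trials_per_cell = 5), setup = "0.25")
reliability(sw)
log <- run_trial(builtin_world("original"), b, trial_config(group_size = 18))
behavior_profile(log)
phi_max_over_lifetime(b, log)
```

Hand-scripted trajectories exercise the scoring rules exactly:

```r
w <- builtin_world("original")
log <- scripted_trial_log(w, data.frame(animat = 1, t = 1:3,
                                        x = c(15, 16, 17), y = 15))
score_animat(log, animat = 1)
#> [1] 1
```

## World maps

Worlds are plain ASCII (`#` wall, `.` empty, `G` rewarding gate, `g`
non-rewarding gate, `S` start slot); see `inst/extdata/worlds/`. The four
modified worlds are best-effort reconstructions of the published figures —
the format makes substituting your own maps trivial (`load_world()`,
`write_world()`).
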