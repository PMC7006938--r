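---
title: "Methods: evolving and evaluating Markov-brain animats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evolving and evaluating Markov-brain animats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(animats)
```

This vignette documents the model implemented by `animats`, the choices made
where the design was genuinely open, and what the bundled tests do and do
not establish.

## The task and its scoring

Animats live on a 32 x 32 grid with an all-wall boundary, two rooms, one
rewarding gate, and 72 uniformly distributed start slots (36 per room on a
6 x 6 lattice). A trial lasts `T = 500` timesteps. Animats are updated
*serially*: one permutation is drawn per trial and reused every timestep, so
an animat senses the live occupancy, with already-moved group members at
their new positions. Movement is four-directional; a forward step into a
wall is a no-op, and under *blocking* a forward step into an occupied cell
is also a no-op.

The per-animat score adds +1.0 for each rewarded gate crossing and
subtracts 0.075 for each timestep spent sharing a cell with another animat
(when the penalty is active). Two details deserve care:

* **Refractory window.** A crossing is rewarded only when no crossing of
  any kind happened within the preceding 100 timesteps — an unrewarded
  crossing also restarts the window. We read "within" inclusively: a repeat
  crossing spaced exactly 100 steps after the previous one is unrewarded,
  and spacing 101 is rewarded. Measured operationally (scan the spacing in
  scripted trials until the second reward appears), the window length is
  exactly 100 timesteps.
* **Reward cap.** With spacing 101 an animat can fit five rewarded
  crossings into 500 steps (t = 3, 104, 205, 306, 407). Because the trial
  maximum is stated to be 4 points, the scorer caps rewarded crossings at
  `reward_cap = 4`. The cap is configurable.

Collision accounting is literal: every animat standing on a cell with
occupancy above one pays the penalty at every such timestep, so a
persistent overlap accrues repeatedly. Under blocking, overlap never
happens and only realized co-occupancy is penalized — a *blocked* move
attempt (a bump) costs nothing.

Crossing detection tracks each animat's room label: gate cells belong to no
room, and a crossing event fires when an animat re-enters a room different
from the one it last occupied, attributed to the gate cell it passed
through. This makes multi-gate worlds (four-rooms variants) well defined,
including non-rewarding gates.

A genome's fitness `F` is the mean over `n_trials = 30` trials of the score
of *one* randomly chosen clone per trial. For the randomized-group-size
setup, each trial's group size is drawn uniformly from the 21-element
vector `[1, 4, 7, ..., 68, 72]`.

## Genome encoding and mutation

The genome is a vector of 2,000–20,000 integers in [0, 255]. Every
occurrence of the start codon (42, 213) opens one hidden Markov gate; the
genome wraps cyclically so a header near the end still yields a complete
gate. The header is: one byte each for the input and output arity (mapped
to 1–4 by modulo), four input-id bytes and four output-id bytes (the first
`n_in`/`n_out` used, reduced modulo the number of units legal in that
role), then `2^n_in` table bytes, each reduced modulo `2^n_out`. Inputs may
be sensors, memory, and — when motor feedback is enabled — motors; outputs
are memory and motors only. Multiple gates writing one unit combine by OR,
and units with no writer fall to 0. This layout follows the conventions of
the Markov-brain literature; the original encoding is not published, so the
layout is a documented reconstruction, as are the mutation defaults
(`point_rate = 0.005`, `insert_prob = 0.05`, `delete_prob = 0.02`, segment
lengths 128–512; inserted segments duplicate a random parent slice).
Deletions that would undershoot 2,000 loci and insertions that would
overshoot 20,000 are skipped entirely.

**Initialization.** First-generation brains are described in the source
material as having no connections. We expose both options and default to
planting 8 start codons (`seed_gates = TRUE`): desk-scale runs (hundreds of
generations) need standing variation in gate structure to show fitness
movement, and seeding is the common initializer for this family of models.
`seed_gates = FALSE` reproduces the connection-free initialization exactly
(chance codon pairs are scrubbed).

## Evolution

A population of 100 genomes (configurable) evolves by fitness-proportional
(roulette) selection on shifted fitness `f − min(f) + 1e-6` — the shift
accommodates the negative scores that collision penalties produce — with
one parent per offspring and no crossover. A tournament scheme and optional
elitism are available but off by default, since the reference framework's
exact selection settings are not published. Seeds fan out from the master
seed through a counter-based derivation (`derive_seed()`), so any single
trial, selection draw or mutation is replayable in isolation and runs are
bit-identical given the master seed.

## Post-evolutionary evaluation

The sweep re-tests evolved brains over the 21 group sizes and eight
conditions: Original, No Penalty, Blocked, Blocked-and-no-Penalty on the
original map, and the original rules on four modified maps (noisy corners,
small gate, four rooms, four messy rooms — all four gates reward in
`four_rooms`; only the vertical mid-line gates reward in
`four_messy_rooms`). Reliability `R` is the unweighted mean of the Original
task-fitness values across the 21 group sizes.

Behavior profiles pool *animat-timesteps* (rather than averaging per trial
first); the three action classes are rest, turn, and forward, with a
blocked forward attempt counted as rest because only realized movement is
observable in the logs. The sensor/motor transition table classifies each
animat-timestep into a 2-bit state — S = 1 iff *any* sensor fired
(regardless of architecture), M = 1 iff the animat moved or turned — and
estimates `P(SM_{t+1} | SM_t)` over consecutive timestep pairs; rows
without support are reported as `NA`, not renormalized, to avoid biasing
table differences.

## Integrated information

Brain complexity uses the state-dependent integrated-information framework
with exhaustive search. For a visited brain state, sensors are clamped to
their observed values and non-member computational units are frozen as
background; member units are perturbed into all `2^k` states to give an
interventional transition rule. Cause repertoires multiply per-mechanism-
node likelihoods and renormalize (virtual elements); effect repertoires
factorize over purview nodes; unconstrained inputs are marginalized
uniformly. Small phi is the minimum over cause/effect of the maximal
purview's minimum-information bipartition, with repertoire distances
measured by an exact earth mover's distance (min-cost flow; no LP library
is required) under the Hamming ground metric. Big Phi is the minimum over
unidirectional cuts of the constellation distance: small-phi mass is
transported between concepts (ground distance = cause EMD + effect EMD over
the full subsystem space), with unmatched mass moved to or from the null
concept of the *uncut* system. Ties among equal-phi purviews prefer the
larger, then lexicographically smallest purview; ties among equal-Phi
subsets prefer the smaller, then lexicographically smallest subset. These
conventions are pinned here because the reference formulation delegates
them to "standard settings" of its software.

Two structural facts make useful sanity anchors: a cut that severs no
dependency leaves the transition rule unchanged, so feed-forward and
disconnected systems have Phi = 0; and the two-unit mutual-copy system has
exactly two first-order concepts (phi = 0.5 each) and positive Phi. The
test suite also checks the implementation against an independently written
brute-force oracle on all systems of up to 3 units (tolerance 1e-9).

Exhaustive search is exponential twice over, so exact evaluation is limited
to candidate subsets of at most 5 units (configurable), and brains with
more than 8 computational units return an explicit "not computed" result
rather than an approximation.

## Problem sizes and what the tests show

The bundled tests run the full machinery at reduced scale: evolutions of
50–100 genomes for up to 300 generations with 10 trials per genome, sweeps
over subsets of conditions, and complexity on hand-wired brains of up to 3
candidate units. At this scale the suite establishes correctness of the
operators (scoring identities, TPM round trips, oracle agreement,
bit-level reproducibility) and the qualitative signature of the science —
mean fitness rises out of the initial collision-penalty regime in at least
9 of 10 seeds — but not the published full-scale outcomes (30 replicates
of 10,000 generations), whose aggregate statistics are outside desk scale.
The synthetic worlds reproduce the documented 32 x 32 / 72-slot / two-room
structure exactly; the four modified-world geometries are reconstructions
from small figures and are labeled as such. Real replication of the
original campaign would also need the unpublished selection and mutation
constants noted above.

## Known limitations

* The gate-encoding byte layout and mutation defaults are reconstructions;
  all are configurable, and genomes/brains serialize to plain text so
  alternative encodings can be compared.
* Phi values reproduce this package's pinned conventions of the cited
  formulation; other implementations may differ in tie-breaking or in the
  treatment of single-unit systems.
* The engine is serial-update by design; there is no continuous time, no
  diagonal movement, and no explicit communication between animats.
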