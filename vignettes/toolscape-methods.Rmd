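---
title: "Model and methods: simulating primate stone-tool transport"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: simulating primate stone-tool transport}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toolscape)
```

## The question the model addresses

Chimpanzee nut-cracking moves stone hammers only short distances at a time:
a forager picks up a hammer within a few cells of a nut tree, uses it, and
drops it at or beside the tree. Each bout is tiny, yet field surveys find
hammers kilometres from any natural stone source, and hammer mass and
density fall off with distance from sources — patterns familiar from the
early archaeological record. `toolscape` simulates how thousands of such
expedient bouts, together with tool breakage, exhaustion, and the turnover
of nut trees, redistribute stone at the landscape scale, and what the
accumulated material record at the end of a run looks like to a surveyor.

## Entities and state

The world is a bounded `width x height` cell grid (default 250 x 250),
thought of as a forest stand. Cell coordinates are 0-based integers; all
radii and distances are Chebyshev (chessboard) distances, the natural
metric for the Moore 8-neighbour geometry used by movement and discard.
The grid does not wrap by default: a torus would let tools circle the world
and corrupt distance-to-source statistics; a `torus` flag exists purely for
sensitivity checks.

* **Primates** (default 100) are memoryless random walkers; one step of one
  cell per time-step, uniform over in-grid Moore neighbours.
* **Sources** (10/100/500 in the factorial) are immobile raw-material
  exposures supplying unlimited fresh hammers. Each carries a *fragility*
  drawn uniformly from {0, 25, 50, 75} percentage points.
* **Trees** (100/500/1000/2000) are the resource requiring tools. In the
  dynamic condition each tree ages one unit per step and dies at age
  10,000; a replacement appears immediately at a uniformly chosen free cell
  within 10 cells of the dead tree, so the live count never changes. In the
  static condition the tree layer is completely frozen (no ageing — the
  condition is defined by tree locations never changing).
* **Pounding tools** carry mass (g), inherited fragility, provenance (origin
  source and its position), a use counter, and a fragment flag. A tool is
  *usable* while its mass is at least 2000 g (the smallest field-recorded
  Panda-nut hammer motivates the threshold); below it the tool is exhausted
  and permanently inert.

## The per-step update

Each time-step (one nut-cracking episode) the primates are activated once
in a freshly shuffled order. An activated primate:

1. moves one cell in a random direction;
2. if its new cell is at or beside a live tree (Chebyshev distance <= 1,
   nearest tree first, ties uniform), it searches a radius of 2 cells for
   material: all sources and all usable tools are pooled, the nearest item
   wins, and equally-near items are chosen uniformly;
3. with a source it acquires a fresh hammer there (mass drawn from a
   truncated normal, below); with a tool it re-uses it — exhausted tools
   are never candidates;
4. it carries the hammer to the tree's cell or one of its in-grid Moore
   neighbours (uniform over the candidates), uses it once, and discards it
   there, where it remains available for future reuse.

The geometry bounds every bout: material can be at most
`search_radius + interaction_radius = 3` cells from the tree it serves, and
a single bout displaces material at most 4 cells (3 plus the discard halo).
Long-distance displacement can therefore only *accumulate*, tool to tool,
tree to tree — which is exactly the phenomenon under study.

On each use the tool breaks with probability
`min(1, baseline + fragility/100)` (baseline 0.25, so fragility 25 breaks
half the time and fragility 75 every time). A break sheds a fragment whose
mass is drawn from the fragment distribution, capped at the tool's current
mass and subtracted from it; the fragment is recorded as an additional tool
object at the discard cell, inheriting fragility and provenance. Mass is
conserved exactly and audited in the tests. A fragment heavy enough to pass
the usability threshold behaves as any other tool; in practice nearly all
fragments are far lighter and simply accumulate where they were shed.

After all primates act, the tree layer advances (dynamic condition only),
and the monitor records the number of **tool-use locations**: live trees
with a source or usable tool within 3 cells — the places where nut-cracking
is actually possible. Growth of this count over a run is the model's
niche-construction signal.

## Parameters whose values the field data do not pin down

Two distributions are calibrated rather than taken from published tables,
and both are exposed as configuration so an empirical table can replace
them.

**Initial hammer mass** — `Normal(5000, 1500)` g, rejected and redrawn
below 2000 g (a source supplies functional hammers, never instantly dead
ones). The values are representative of published Taï Forest Panda-nut
hammer masses, which span roughly 1–9 kg.

**Fragment mass** — a two-component lognormal mixture: with probability 0.9
a small chip, `LN(log 6.5, 0.8)` (mean ~9 g), else a large fragment,
`LN(log 70, 0.6)` (mean ~84 g); overall mean ~16 g. Field observations of
nut-cracking breakage motivate the shape (mostly small chips, occasionally
large pieces). The scale was fixed once from the use-life arithmetic: a
hammer must lose ~3100 g to die, so expected use-lives are
`3100 / (p_break x 16.4)` — about 190 uses at fragility 75 and about 770 at
fragility 0, placing use-lives in the low hundreds. Within a finite run the
*observed* median at exhaustion is lower (~120–150), because slow-wearing
tools created late are still alive at the cutoff and the exhausted subset
over-represents fast wearers; this survivorship censoring is a property of
any fixed-length run, not of the breakage rule.

## Numerical and scheduling choices

* All randomness flows through R's RNG in one documented order (shuffle;
  per primate: move, tree tie-break, material tie-break, mass draw, discard
  draw, break draw, fragment draw; then regrowth draws in tree-id order),
  so `(config, seed)` fixes every output value. The per-step shuffle always
  starts from the identity permutation, which makes a serialised world
  resume bit-for-bit identically to an uninterrupted run.
* Trees and sources occupy unique cells (collisions resampled at
  initialisation and regrowth); primates and tools may stack freely.
* Initial tree ages are uniform on 1..10,000 so the first cohort does not
  die synchronously; a regrown tree dies exactly one lifespan after birth.
* If a dead tree's 10-cell regrow window is completely full, the
  replacement is placed anywhere free on the grid and the event is counted
  (`n_regrow_widened`); with realistic densities this never fires.
* The break check applies to every use, including the first immediately
  after acquisition.
* Sweep seeds derive from the base seed by multiplicative hashing modulo
  2^31 - 1, are pairwise distinct by construction, and depend only on the
  (combination, iteration) index — never on execution order.
* Timeseries are recorded every 50 steps for runs longer than 10,000 steps
  (every step otherwise); recording consumes no random numbers, so the
  interval cannot perturb a trajectory.

## Analysis layer

Every reported quantity is recomputed from the persisted run record alone:

* `count_tool_use_locations()` — the census above; the compiled
  implementation is tested for exact agreement with an exhaustive
  brute-force R twin (`brute_force_locations()`) on randomised snapshots.
* `max_displacement()` — the largest Chebyshev distance between a
  non-fragment tool's origin source and its final resting cell.
* `build_assemblages()` — the archaeological view: per occupied cell,
  counts of usable tools, exhausted tools and fragments (a usable fragment
  tallies as usable, matching the reuse rule), total mass, and distance to
  the nearest source.
* `distance_decay()` — two relations: per-cell record counts against
  nearest-source distance (exponential fit on `log(count + 1)`; the +1
  protects zeros) and usable tool mass against the distance from each
  tool's *own* origin source (provenance distance, fitted on `log(mass)`).
  Spearman rank correlations accompany both fits as the robust statistic;
  inputs spanning fewer than two distinct distances are flagged degenerate
  and never silently fitted.
* `sweep_statistics()` — Kruskal–Wallis tests of maximum displacement
  across tree-count and source-count groups, OLS of displacement on both
  counts (standardised coefficients compare effect sizes), and the pooled
  fractions of runs with transport beyond 3 cells and with net
  tool-use-location growth. Runs are pooled with equal weight.

## What the test scenarios show — and what they do not

The deterministic scenarios (`scenario_no_transport()`, `scenario_chain()`)
pin down reachability: no tool can ever exist when every tree is more than
3 cells from every source, and a chain of trees spaced <= 4 cells apart
carries tools arbitrarily far while a 5-cell gap stops them at the first
discard halo (the extra cell comes from discard scatter around the last
reachable tree). These are geometry checks, not forest models: scenario
configs may set the break probability to 0 or the mass spread to 0 to make
a path deterministic, overrides that never appear in study conditions.

Problem sizes used in the routine test suite are deliberately compact
(60-cell worlds, a few hundred to a few thousand steps); the acceptance
checks run the full factorial at the reference scale (250 x 250, 75,000
steps, 3 replicates per combination), which the compiled core completes in
a few minutes.

## Known limitations

* Movement is a pure random walk: no memory, goal-direction, or social
  learning, matching the reference model's scope. Encounter rates with
  trees are therefore diffusion-limited and lower than real foraging.
* The fragment and initial-mass distributions are documented stand-ins for
  field datasets that are not reproduced here; quantities that depend on
  their exact shape (most visibly the *minimum* share of assemblages
  retaining a usable tool, which falls to ~5% in our extreme condition)
  shift with these choices even though every qualitative ordering —
  fewer sources, more trees, turnover all reduce that share — is stable.
* The sweep's replicate count (default 10, 3 in the acceptance checks) is
  far below what narrow order statistics demand; fractions carry binomial
  noise of a few points at these sizes.
* A single run stores every tool and fragment ever created (a million-plus
  records in dense conditions); memory, not time, is the binding constraint
  for very long runs.
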