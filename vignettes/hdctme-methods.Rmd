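---
title: "Modeling early tumor-macrophage dynamics on a lattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling early tumor-macrophage dynamics on a lattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hdctme` implements a hybrid discrete-continuous (HDC) agent-based model of
the first five days of a nascent tumor interacting with the innate immune
system. Discrete cellular agents live on a two-dimensional square lattice
(default 100 x 100 sites, one cell of each kind per site per layer) and are
coupled to five continuous scalar fields:

* **M2S** — a lumped pro-M2 soluble factor, secreted by tumor cells (`p2`)
  and M2 macrophages (`p4`). It is simultaneously the M2-polarizing
  cytokine, the chemoattractant followed by macrophages, and the
  pro-angiogenic signal driving vasculature growth (`p14`).
* **TLS** — the tumor lethality signal secreted by M1 macrophages (`p5`);
  tumor cells die where TLS reaches the threshold `p6`.
* **Activator** — a tumor-derived licensing signal (`p3`); naive
  macrophages polarize only where Activator reaches `p7`. Recently dead
  tumor cells keep releasing Activator for a configurable window
  (necrosis-mediated activation).
* **Oxygen** — delivered in proportion to local vasculature (`p8`), consumed
  at a fixed rate by every live cell (`p9`); any live cell below the anoxia
  threshold `p10` dies and is retained as a dead cell.
* **Vasculature** — a non-diffusing density that grows with local M2S and is
  capped at `v_max`; it sets both oxygen delivery and the recruitment rate
  of naive macrophages (`p15`).

There are two occupancy layers. The tumor layer holds live and dead tumor
cells; the macrophage layer holds naive, M1, M2 cells (plus their
engineered counterparts under therapy) and dead macrophages. The two layers
overlay the same domain, so macrophages can sit on top of tumor cells —
this is what lets the model reproduce macrophage invasion of the tumor
mass. Dead entries are never removed and block their layer, producing a
persistent necrotic core.

Polarization is stochastic: an activated naive macrophage adopts the M2
state with probability

$$P(\mathrm{M2}) = \operatorname{logistic}\!\left(\frac{[\mathrm{M2S}] - p_{13}}{p_{16}}\right),$$

and M1 otherwise; the decision is irreversible. `p13` is the half-maximal
threshold and `p16` the width of the dose-response: as `p16` grows the
curve flattens and the cell-level decision becomes noisier, which makes
`p16` the model's *functional heterogeneity* dial. *Spatial heterogeneity*
enters through the initial M2S field, drawn per site from a normal
distribution with mean `p11` and standard deviation `p17` (truncated at
zero by clamping).

### The update loop

Each macro step of `dt = 0.005` day applies eight stages in a fixed order:
(1) secretion, oxygen delivery/uptake and first-order decay; (2) diffusion
of all diffusible signals; (3) vasculature growth; (4) recruitment;
(5) polarization; (6) chemotaxis; (7) tumor division; (8) death checks.
The order is chosen so that cellular decisions read post-transport
concentrations and deaths settle the step; a macrophage recruited in stage
4 can polarize in stage 5 of the same step. Exactly one `dt` of each
process occurs per step.

Chemotaxis visits all live macrophages in a random order each step (fixed
sweep orders produce directional lattice artifacts). In the default
deterministic mode a cell moves to the candidate site — its own plus
unoccupied neighbors — with maximal M2S, ties broken uniformly at random; a
stochastic variant draws the destination with probability proportional to
candidate M2S plus a uniform floor. Movement and division use the Moore
(8-neighbor) neighborhood by default; a von Neumann option exists. All
macrophage classes chemotax by default; a `naive_m1`-only variant is a
configuration flag.

Death thresholds are inclusive (`TLS >= p6` kills, `oxygen < p10` kills,
`Activator >= p7` activates) so that boundary tests are exact.

### Numerics

Diffusion uses the explicit forward-time central-space 5-point stencil with
zero-flux (mirror) boundaries — the simulated patch is conceptually
embedded in like tissue, so no mass crosses the boundary and each field's
total is conserved to rounding error. The scheme is sub-stepped so the
diffusion number $D\,\delta t/\mathrm{d}x^2$ stays at or below 0.2 (the
stability bound is 0.25; the 0.8 safety factor keeps the checkerboard mode
well damped). With the base diffusion coefficient `p1 = 50` LS²/day and
`dt = 0.005` day this means two sub-steps per macro step; the sub-step
count adapts automatically when `p1` is swept. `validate_parameters()`
reports a violation if a pinned sub-step count breaks the bound.

Signal decay is applied as an exact exponential factor per step, which
preserves positivity for any rate. Oxygen has cellular uptake instead of
decay, with the uptake floored at zero concentration. Because uptake is
zeroth-order, an empty oxygenated region has no concentration-dependent
fixed point; the initial oxygen level is therefore a configuration value
(`o2_init = 1` pg/LS, the top of the normoxic color range) rather than a
computed steady state, and far from cells oxygen rises slowly over the
5-day horizon (by about `p8 * v0 * t`). This is a documented property of
the model, not a numerical defect: dynamics are governed by the
delivery/uptake balance near cells.

The clock is computed as `step * dt` from the step counter, not by
accumulating floating-point increments, so output rows land exactly on the
sampling grid.

### Seeding and reproducibility

All randomness — initialization, recruitment, polarization draws, movement
tie-breaks, division — flows through R's RNG, so a run is bit-reproducible
from `(parameters, config, seed)`. Sweeps derive one seed per
(design-point, replicate) pair from a master seed through a pure
counter-based map (`derive_run_seed()`), which makes ensembles identical
under any execution order or degree of parallelism and lets interrupted
sweeps resume from per-point checkpoint files.

Runs may exit early once the tumor is extinct: dead cells are never
removed and no rule recreates tumor cells, so extinction certifies the
outcome. The time series is then padded with its last values. Because this
freezes the macrophage trajectories, `run_ensemble()` defaults to running
the full horizon, and the outcome-only sweeps (`run_design()`,
`therapy_sweep()`) keep the early exit for speed.

## Base parameter values and calibration

The eighteen swept parameters ship with calibrated defaults
(`make_base_parameters()`); quantities never swept (domain size, `dt`,
decay rates, initial densities, conventions) live in
`make_engine_config()`. Field scales follow the model's display
conventions: M2S on the order of 10⁻⁶ pg/LS, oxygen of order 1 pg/LS,
vasculature 0-40 au.

The defaults were chosen, once, so that the base configuration exhibits
the physiology the model is meant to capture:

* a 200-run ensemble contains **both** outcomes — tumor survival (live
  tumor cells at day 5) and tumor death — with survival probability around
  0.3-0.5;
* initial oxygen uptake makes the tumor interior anoxic within hours, so a
  retained **necrotic core** forms well before day 2 in essentially every
  run, and subsequent growth is an oxygen-limited, asymmetric rim;
* the early immune response is M1-dominated (M2S starts below `p13`
  almost everywhere), while M2S accumulating from the tumor and from the
  first M2 cells makes late polarization M2-biased, so the macrophage
  compartment eventually switches to an **M2-dominated** state; in runs
  that end in tumor death the switch completes around the horizon;
* the **MPI at 0.5 day** — `M2 / (1 + M1 + naive)` — separates the two
  outcome groups in the direction of higher early M2 bias among surviving
  tumors, and across the focused `p11 x p13` sweep it is strongly
  predictive of survival probability (R² around 0.9) while early tumor
  size is not (R² below 0.1);
* increasing either heterogeneity dial (`p16`, `p17`) increases survival
  probability, and the engineered-macrophage comparisons reproduce the
  expected ordering (below).

Mechanistically, the decisive competition is a race between the early
M1 cohort — whose accumulated TLS can erode the tumor rim faster than it
regrows (`p12` = 1/day) — and ignition of the M2S positive feedback loop
(`p4`), which blankets the tumor in a polarization-protective,
vasculature-promoting microenvironment. Local pockets of the initial M2S
field (`p17`) and decision noise (`p16`) can ignite the feedback early,
which is why both heterogeneities promote tumor survival. The slowish
decay rates of M2S (0.5/day) and TLS (0.3/day) matter for this balance:
M2S integrates history so the late recruit cohort tilts M2, while
persistent TLS lets a kill complete even after the M2 switch.

## Behavior metrics

* `mpi()` — the macrophage polarization index; engineered cells count with
  their phenotypic class by default (a `native_only` flag restricts to
  unmodified cells) so therapy ensembles remain comparable.
* `mean_local_cv()` — spatial heterogeneity of a field: the grid is tiled
  into non-overlapping 10 x 10 arrays, the per-array coefficient of
  variation (population sd / mean; 0 where the mean is 0) is averaged over
  all arrays (exactly 100 on the default domain).
* `field_summary()`, `survival_probability()` (with exact binomial
  intervals), `aggregate_by_outcome()` (outcome-stratified mean ± SE
  trajectories and MPI distributions), and
  `regress_metric_vs_survival()` — OLS of survival probability on a
  (min-max normalized) early-time metric over design points with survival
  probability below one; saturated points carry no information about the
  boundary, and R² is invariant to the normalization.

## Sensitivity analysis

`build_design()` enumerates the one- and two-parameter designs: five
multipliers per parameter, `{0.25, 0.75, 1.25, 1.75, 2.25}` (linear mode,
one order of magnitude) or `{0.1, 0.3, 1, 3, 10}` (log mode, two orders).
With 18 parameters the design comprises 18 single cases (90 points) and
153 proper pair cases (3825 points) — 3915 unique parameter combinations.
Counting unordered pairs *with* the degenerate self-pairs, whose grids
collapse onto the single cases, gives the alternative tally of 171 pair
cases; `design_cardinality()` reports both conventions.

`quadratic_sensitivities()` fits the full quadratic response surface in the
multipliers,

$$m \approx \beta_0 + \sum_i \beta_i x_i + \sum_i \beta_{ii} x_i^2 +
\sum_{i<j} \beta_{ij} x_i x_j,$$

with `x_i = 1` where a parameter is unvaried, and defines the sensitivity
of metric $m$ to parameter $i$ as the partial derivative at the base point
$x = 1$: $s_i = \beta_i + 2\beta_{ii} + \sum_{j \ne i}\beta_{ij}$.
Covariates are dimensionless fold-changes, so sensitivities are comparable
across parameters; they are normalized to a maximal magnitude of one and
ranked by signed value. Interaction terms are included by default
(a no-interaction variant is a flag); on designs that cannot identify some
terms the rank-deficient columns are dropped and reported, with their
coefficients treated as zero. On any noiseless quadratic surface the
procedure recovers the analytic derivative exactly, which is how it is
tested. `sensitivity_delta()` compares two reports for the same metric
(for example the reduced-feedback base case `p4 = 0.25` against the
original) on a shared normalization scale, and `pairwise_surface()`
extracts the 5 x 5 metric grid of any parameter pair.

A full linear-design sweep is 3915 points x 50 replicates, roughly 200k
runs — cluster scale, supported through counter-based seeding, forked
parallelism and per-point checkpointing. The packaged tests and the
acceptance script exercise the machinery on reduced designs (parameter
subsets, 2-8 replicates) and verify the estimator against exact synthetic
surfaces instead.

## Engineered-macrophage therapies

Three "Trojan horse" strategies modify recruited engineered macrophages
(EMP) while leaving their chemotaxis, oxygen consumption and anoxia death
native; from `t_intro` onward each recruit is an EMP with probability
`emp_fraction` (only the recruit mix changes — no bolus dose):

* **ENHANCED_TLS**: EMP polarize normally but EMP-M1 secrete TLS at four
  times the native rate (default multiplier 4).
* **NO_M2**: activated EMP always take the M1 branch.
* **ACTIVE_CONVERSION**: as NO_M2, plus every live EMP constitutively
  secretes a diffusible blocker. Native naive cells then polarize using
  the competitively attenuated signal
  `M2S_eff = M2S / (1 + blocker / k_blocker)` — a single-constant
  saturating model of receptor blockade. The blocker diffuses with the
  shared coefficient `p1`, has its own fixed decay rate, and is not swept
  by the sensitivity analysis.

At the shipped calibration the strategies reproduce the expected ordering:
enhanced lethality helps only when introduced immediately and as a majority
of incoming macrophages, whereas both polarization-suppressing strategies
drive the tumor to extinction even when introduced late (day 2.5) at a
quarter of incoming macrophages, with little difference between them. In
this implementation the suppression strategies need fractions on the order
of 0.1-0.25 rather than below 0.1; the boundary location depends on the
calibrated kill-versus-feedback balance, while the ordering of strategies
is robust.

## What the simulations do and do not emulate

The generator's stochastic elements — uniformly random resident
macrophages, normally distributed initial M2S, vasculature-proportional
recruitment, Bernoulli polarization — stand in for biological variability
between tissue sites. They do not emulate: three-dimensional geometry,
explicit vessel networks or flow, cell mechanics and crowding pressure,
macrophage death other than anoxia, M1/M2 interconversion, adaptive
immunity, or pathway-level signaling. Passing tests therefore demonstrate
internal consistency of the model and reproducibility of its emergent
statistics, not quantitative agreement with any particular tissue.

## Problem sizes used by the packaged checks

The unit tests run on 20 x 20 lattices over half a simulated day; the
acceptance checks use the full 100 x 100 domain with a 200-run base
ensemble, a 5 x 5 focused sweep of `p11 x p13` at 8 replicates per cell,
and 20-replicate therapy probes — sizes chosen so the whole suite
completes in minutes on a single core while keeping every statistic
well-resolved. One full-horizon base run takes on the order of a second.

## Known limitations

* The quadratic surface is a local description; sensitivities are
  derivatives at the base point and say nothing about far-from-base
  behavior (the log-range design exists for that).
* With zeroth-order oxygen uptake, far-field oxygen grows linearly over
  the horizon (see *Numerics*); the model should not be run for much
  longer horizons without adding an oxygen sink.
* MPI values depend on counting naive cells domain-wide, so their absolute
  scale is diluted by resident macrophages far from the tumor; comparisons
  across conditions are meaningful, absolute values are
  convention-dependent.
* Early extinction freezes a run's macrophage series when the early exit
  is enabled; outcome-level quantities are unaffected.
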