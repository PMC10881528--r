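---
title: "pcabm: model, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pcabm: model, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcabm)
```

## The model

`pcabm` simulates the prostate tumor microenvironment (TME) as a stochastic
cellular automaton on a bounded rectangular lattice. Four cell types are
modeled as agents: androgen-sensitive tumor cells (LNCaP-like), castration
resistant tumor cells (LNCaP-abl-like), fibroblasts, and macrophages in the
two conventional polarization extremes — pro-inflammatory, tumoricidal M1 and
anti-inflammatory, tumor-promoting M2. Each agent occupies exactly one grid
cell; the default grid is 125 × 125 cells of 142.89 µm² each (one tumor-cell
footprint), scaled to a 96-well culture surface. The grid does not wrap:
the boundary models the wall of a culture well.

Time advances in ticks of 4 hours; a default run of 42 ticks covers the
7 days of a live-cell imaging experiment. Within a tick the agent groups act
in a fixed order — tumor cells (sensitive and resistant together),
fibroblasts, M1, then M2 macrophages — while the order of agents *within*
a group is reshuffled every tick to remove positional bias. Agents born
during a tick idle until the next tick, which prevents same-tick division
chains.

Every action is stochastic: an agent draws a uniform number per decision and
acts when the draw falls below the action's probability. An agent performs
at most one action per tick, resolved sequentially:

* **Tumor cells** die spontaneously (`TUpdeath`); otherwise attempt to
  proliferate (`TUpprol`, resistant: `TUpprolres`); otherwise attempt to
  migrate (`TUpmig` / `TUpmigres`); otherwise idle. Proliferation requires a
  free Moore neighbor (the 8 cells at Chebyshev distance 1) and remaining
  division capacity (`TUpmax` / `TUpmaxres`); the daughter is placed on a
  uniformly chosen free neighbor and *both* parent and daughter carry the
  parent's post-division capacity. A proliferation attempt blocked by
  crowding or exhausted capacity falls through to the migration decision. A
  newborn sensitive cell becomes resistant with probability `TUpres`, in
  which case it starts with the full resistant capacity `TUpmaxres`.
* **Fibroblasts** follow the same scheme with `Fpdeath`, `Fpprol`
  (capacity `Fpmax`, unlimited by default), and `Fpmig`; they have no
  resistance mechanism.
* **Macrophages** that are engaged (post-kill refractory period) only
  recover: `engagement_remaining` decreases by `Mspeed` sub-steps per tick
  and nothing else happens. Free macrophages may die spontaneously
  (`Mpdeath`, default 0); otherwise, if a tumor cell is Moore-adjacent and
  kills remain (`Mkmax` capacity), they kill a uniformly chosen adjacent
  tumor cell with probability `Mpkill`, decrement their kill budget, and
  enter engagement (`MengagementDuration` sub-steps); otherwise they may
  migrate (`Mpmig`) up to `Mspeed` single-cell moves in one tick, stopping
  as soon as a tumor cell becomes adjacent or no free neighbor remains.

Migration steps are random with probability `rwalk` and directed otherwise:
a directed step moves to the free Moore neighbor minimizing the Euclidean
distance to the nearest live target — fibroblasts for tumor cells, tumor
cells for fibroblasts and macrophages — with ties broken uniformly. There is
no sensing radius: the nearest target is found over the whole grid, and when
no target exists the step degrades to a uniform random one. Finally, while
at least one live M2 macrophage is present anywhere in the system, sensitive
tumor cells add `M2TUadd` to their proliferation probability (a global,
paracrine-like growth stimulus; the sum is clamped to 1).

## Hormone conditions and presets

Two calibrated presets ship with the package (`preset_params()`), one per
hormone condition of the underlying co-culture experiments: `"R1881"`
(synthetic androgen, hormone proficient) and `"DMSO"` (vehicle control in
charcoal-stripped medium, emulating androgen deprivation therapy). The
androgen response is concentrated in two parameters — tumor proliferation
(`TUpprol` 0.1144 vs 0.0389, a ~3-fold drop under deprivation) and M1
killing (`M1pkill` 0.1116 vs 0.005, a ~22-fold drop) — while spontaneous
death, capacities, and migration are essentially hormone insensitive.
Resistance is active only under deprivation: newborn sensitive cells switch
with `TUpres` = 0.002, and resistant cells proliferate at `TUpprolres` =
0.0596 with a large capacity (`TUpmaxres` = 50), modeling the growth
advantage of castration-resistant clones. `report_fold_changes()` computes
these ratios, together with those from the tumor–macrophage-only refits
(`nofibroblast_refits()`).

## Units of speed and engagement

`M1speed`/`M2speed` (40) and the engagement durations (60) are kept in
*sub-steps*: a migrating macrophage makes up to 40 single-cell moves per
4-hour tick, and an engagement of 60 sub-steps at speed 40 paralyzes it for
`ceiling(60/40) = 2` ticks. This preserves both literature-derived numbers
under the 4-hour tick; reading the engagement as whole ticks would make a
single kill consume more than a whole experiment, which is biologically
implausible.

## Scenarios

`build_scenario()` exposes a catalog of named co-culture compositions in
both hormone conditions: monocultures, tumor–fibroblast at 4:1 and 1:1,
tumor–fibroblast–macrophage at 4:1:1, tumor–macrophage at 4:1 (no
fibroblasts), macrophage-dose variants at M:TU:F = 1:4:1 and 1:1:1, and
castration-resistance (CRPC) variants. Ratio suffixes follow the listing
order of the name (`M1_TU_F_141` seeds M1:TU:F at 1:4:1). Absolute counts
are a design choice of this package: the reference composition seeds 1000
tumor cells (~6.4% occupancy of the default grid), with all other counts
scaled by the ratio; the experiments being emulated report seeding ratios
but no on-grid counts. CRPC scenarios seed 1 resistant per 100 sensitive
tumor cells: resistance emerging from rare clones is the phenomenon being
modeled, so the rare orientation of the 1:100 ratio is used.
`LNCaPabl_mono` seeds a fully resistant monoculture for calibrating
resistant-cell parameters.

Growth output is normalized as in the live-cell experiments:
`relative_growth()` divides counts by the count at t = 24 h ("time point
zero" of the assays, tick 6), and errors explicitly if that baseline is
zero. Normalization makes curves scale invariant, which is what permits
calibrating on relative fluorescence data.

## Resistant-focus statistic

The claim that resistant cells grow in spatial clusters is tested with a
Clark–Evans-style index (`nearest_neighbor_clustering()`): the observed mean
nearest-neighbor distance among resistant cells divided by its expectation
under uniform random placement of the same count on the same grid. The
expectation is estimated by Monte Carlo rather than the classical
closed-form because the agents live on a discrete lattice with at most one
agent per cell; the same placements provide a lower-tail p-value. Values
below 1 indicate clustering. The statistic and its null are choices of this
package — the underlying observation is visual — and with fewer than two
agents the index is reported as an explicit error rather than a number.

## Calibration

Free parameters are fitted by minimizing the mean squared error between the
replicate-mean relative growth curve of the data and the mean relative curve
of `n_sim_rep` simulations (default 3), on the data's time grid (data times
are matched to the nearest tick; a mismatch over half a tick is an error).
The optimizer is a hand-written global-best particle swarm
(`pso_optimize()`): swarm 20, 60 iterations, inertia 0.729, cognitive =
social = 1.49445 (standard constriction-style values), velocities clamped to
half the range per dimension, reflecting bounds. These hyperparameters are
defaults of this package, exposed in `pso_config()`, since no canonical
values exist for this problem. Two choices tame the stochastic objective:
candidates within one iteration share the same evaluation seed (common
random numbers), and integer capacities are searched continuously and
rounded at evaluation, so the swarm handles the mixed discrete–continuous
space without specialization. Default bounds are `[0, 0.5]` for
probabilities, `[0, 0.3]` for the M2 growth bonus, `[1, 20]` for capacities
(`[1, 60]` for the resistant capacity).

`staged_fit()` reproduces the staged protocol used to build the presets
(stage order, freezing rules, and replicate aggregation are described in its
help page): per biological replicate the swarm is restarted 50 times
(default), per-replicate medians are taken, and the across-replicate median
is frozen and fed forward. Technical replicates are averaged into one curve
per biological replicate before costing. The tumor–macrophage-only stage
fits two alternative freezing schemes (free proliferation vs free killing)
and reports both with their costs; which describes the biology better is a
question for the data, not the optimizer, so neither feeds forward.

## Synthetic data

`generate_logistic_dataset()` and `generate_simulated_dataset()` produce
growth datasets with the structure of the emulated live-cell experiments:
7-day curves sampled every 4 h, two hormone conditions, three biological
replicates of six technical replicates, normalized at 24 h. The logistic
generator is a smooth stand-in (multiplicative log-normal noise, default sd
0.05 — a placeholder magnitude, since the assay's noise level is not
published as numbers); the simulator-backed generator provides exact ground
truth for parameter-recovery experiments. Synthetic data reproduce the
replicate structure and normalization of real data but not plate effects,
fluorescence artifacts, or correlated technical noise, so passing recovery
tests demonstrates identifiability of the model given its own dynamics, not
robustness to real-world measurement error.

## Reproducibility and numerics

All randomness — placement, action draws, tie-breaks, swarm updates, null
placements — flows through R's RNG, so a single integer seed makes any run
byte-reproducible. Sub-stream seeds (per technical replicate, per restart,
per evaluation) are derived from the master seed by fixed small-modulus
arithmetic, so changing one stream cannot silently shift another; cost
evaluations additionally restore the caller's RNG state, so the number of
simulations inside an evaluation cannot perturb the swarm's draws.
Coordinates are 0-based `(row, col)`; snapshots are integer matrices with
the code map 0 empty, 1 tumor, 2 resistant, 3 fibroblast, 4 M1, 5 M2.

Directed-migration and nearest-neighbor searches use an expanding
Chebyshev-ring scan over the occupancy grid that is exact for the Euclidean
metric (rings are scanned until the ring radius exceeds the best distance
found), which keeps dense late-stage grids fast without approximating the
target choice.

## Problem sizes used by the test suite

The package's tests exercise full-scale scenarios (125 × 125 grid, 1000
seeded tumor cells, 42 ticks; CRPC runs extended to 250 ticks) for the
directional properties, and a reduced calibration scale for parameter
recovery: a 40 × 40 lattice with 100 seeded tumor cells, 10 swarm restarts
of 15 particles × 40 iterations, and 2 simulations per cost evaluation.
These sizes are the package's own choice of a desk-scale recovery
experiment; recovery there is demonstrated to within the tolerances the
tests assert, and nothing prevents rerunning the same code at the full
defaults. One design point deserves a note: the `M1pkill` recovery seeds
macrophages at tumor:M1 = 2:1 rather than the experimental 4:1, because at
4:1 only a small fraction of the tumor population is ever killed and the
growth curve carries little information about the killing probability —
recovery of a contact-killing rate needs a design in which contact killing
visibly shapes the curve.

## Known limitations

The model is two-dimensional, on-lattice, and purely contact-based: no
diffusible cytokine fields, vasculature, T cells, mechanics, or cell–cell
adhesion. It is calibrated to in vitro time scales and LNCaP-derived lines;
transferring conclusions to tissue requires the usual caution for
culture-calibrated models, and outputs are best read qualitatively
(directions and orderings) rather than as quantitative predictions.
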