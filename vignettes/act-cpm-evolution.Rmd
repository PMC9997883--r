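---
title: "Evolving cell migration under mechanistic constraints: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving cell migration under mechanistic constraints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actevolve)
```

`actevolve` asks a simple question with a deliberately mechanistic model:
when a migrating cell is selected only for covering area, which parts of
the behaviour that evolves are "strategy", and which are side effects of
how cell migration physically works? This vignette documents the models,
the estimators, and every numerical choice a user might want to audit.

## The Act cellular Potts model

Cells live on a 2D toroidal pixel lattice. Each pixel carries a cell
identity (0 is the background medium), and dynamics proceed by *copy
attempts*: a random pixel tries to copy its identity into a random Moore
neighbour. An attempt that would change the energy by $\Delta H$ succeeds
with the Metropolis probability

$$P = \min\left(1, e^{-\Delta H / T}\right),$$

where $T = 20$ is the model temperature. The energy combines four terms:

* **Adhesion**: each unlike Moore pixel pair on the grid pays a contact
  energy $J$ depending on the two cell types (T cell-background 20;
  in skin additionally keratinocyte-keratinocyte 200, T
  cell-keratinocyte 2).
* **Volume**: each cell pays $\lambda_V (V - V^*)^2$, with $V^* = 500$
  pixels and $\lambda_V = 30$ for T cells (750 for keratinocytes).
* **Perimeter**: analogously $\lambda_P (P - P^*)^2$, where the perimeter
  counts Moore pairs from a cell pixel to a non-member pixel
  ($P^* = 260$, $\lambda_P = 2$ for T cells; 330 and 10 for
  keratinocytes).
* **Protrusion activity** (the Act extension): a pixel newly gained by a
  cell remembers this for `max_act` MCS (its "activity" starts at
  `max_act` and decays by 1 per MCS). A copy attempt from source $s$ into
  target $t$ gains
  $$\Delta H_{\text{act}} = -\frac{\lambda_{\text{act}}}{\text{max}_{\text{act}}}
  \left(\mathrm{GM}_{\text{act}}(s) - \mathrm{GM}_{\text{act}}(t)\right),$$
  where $\mathrm{GM}_{\text{act}}(p)$ is the geometric mean of activity
  over $p$ and its same-cell Moore neighbours. Recently protruding
  regions therefore protrude more easily: a positive feedback that
  produces spontaneous polarisation and migration without any imposed
  direction.

One Monte Carlo step (MCS), the time unit, comprises `width x height`
copy attempts. The activity term only ever contributes to $\Delta H$, not
to a stored total energy, which is why `total_hamiltonian()` sums the
physical terms only; `delta_h_physical()` is validated against it by
brute force in the test suite.

Only `max_act` and `lambda_act` are heritable; everything else is held
fixed. This is the heart of the study design: the genotype controls
migration only *indirectly*, through shape and feedback dynamics, so
speed and persistence are emergent, coupled quantities rather than dials.

### Conventions the model statement leaves open

Choices we fixed, following the conventions of the published engine
family for this model:

* Acceptance rule as above, with $\Delta H = 0$ accepted with
  probability 1.
* Adhesion and perimeter both use the Moore neighbourhood.
* $\mathrm{GM}_{\text{act}}$ includes the centre pixel, restricted to
  same-cell pixels; background pixels have
  $\mathrm{GM}_{\text{act}} = 0$, and a single zero activity zeroes the
  geometric mean.
* The activity parameters acting on a copy attempt are those of the
  source pixel's cell, or of the target's cell when the source is
  background — so the medium "pulling back" an active protrusion is
  resisted by that protrusion's own feedback strength.
* `max_act` stays continuous under mutation and is used as a real number
  both in $\Delta H_{\text{act}}$ and when stamping activity onto a
  gained pixel; decay remains $-1$ per MCS.
* A pixel taken over by another cell simply has its activity overwritten
  by the gaining side (0 for background).
* A cell may lose its last pixel (annihilation); nothing prevents this,
  it is recorded and scores fitness 0.
* One exact optimisation: attempts whose source pixel has no unlike
  neighbour can never change the state, so the compiled kernel skips runs
  of them with a geometric draw and samples sources among interface
  pixels. The distribution of state changes — and the per-MCS attempt
  budget — is identical to naive uniform sampling; this is what makes
  whole evolutionary runs feasible on one CPU.

## Environments

**Free**: a single T cell seeded as a compact disc of $V^*$ pixels at the
centre of an empty 150x150 torus, burnt in for 500 MCS. The seed shape is
irrelevant after burn-in, which is why a disc was chosen without further
ceremony.

**Skin**: a densely packed keratinocyte sheet. 31 keratinocytes are
seeded at uniform random background positions, one every 50 MCS so that
neighbours do not entangle, with a transiently tightened perimeter target
of 200 that keeps them round while growing; after 500 MCS of
equilibration the first-seeded keratinocyte is replaced by the T cell
(activity zeroed) and the others get their true perimeter target of 330.
Seed positions use a 5x5 free footprint; a keratinocyte annihilating
during setup (rare) triggers a retry with a fresh derived seed, with a
message. Each evolved individual gets a freshly generated tissue, so
genotypes cannot adapt to one particular tissue realisation; the seed of
each tissue is recorded in the history.

## Fitness and the evolutionary algorithm

A fitness evaluation simulates one cell for 10,000 MCS, logging its
centroid every 5 MCS, accumulating every pixel the cell ever occupied
(recorded at copy time, not merely at log points), and checking
*connectedness* at every log point. Connectedness is the probability that
two uniformly drawn pixels of the cell lie in the same Moore-connected
component, $C = \sum_k (n_k/N)^2$; a cell with $C < 0.9$ at any log point
counts as broken. Fitness is the explored pixel count divided by a cell
volume of 500 pixels — zero for broken or annihilated cells. Checking
breakage at the 5-MCS logging cadence (rather than every MCS) is a
cost/fidelity trade-off; the cadence is a parameter of
`run_simulation()` for users who want it tighter.

Evolution is a $(\mu + \lambda)$ genetic algorithm: 10 parents each
produce 3 offspring; all 40 individuals — parents re-evaluated by fresh
simulation, so a lucky simulation cannot immortalise a genotype — are
ranked by fitness and the top 10 survive. Ties rank in uniform random
order. Mutation log-transforms each parameter and adds Gaussian noise,
$x \mapsto e^{\ln x + \epsilon}$, $\epsilon \sim N(0, \sigma)$, with
$\sigma = 0.6$ for the first 5 generations and 0.2 afterwards. The larger
early step exists purely to shorten the neutral drift phase: the founders
(`max_act` = 5, `lambda_act` = 5 free; `lambda_act` = 100 in skin, where
tissue resistance raises the motility threshold) cannot move at all, so
early fitness differences are nil and only drift carries the population
into the motile regime.

The consensus optimum over runs (`estimate_optimum()`) drops runs that
have not converged — a run is excluded when *either* parameter's survivor
mean changes by at least 20% between generations $G-9$ and $G$; the
stricter either/or reading was chosen because a run drifting in one
parameter has not converged in any useful sense — then pools survivors'
values over the last 10 generations across runs, averages on the log
scale (mutation is log-normal, so the population explores log space), and
rounds to the nearest 5. The relative change is measured on the raw
scale, the most literal reading.

## Track statistics

`step_speeds()` divides consecutive centroid displacements by the 5-MCS
logging interval; the reported speed is the mean of this distribution.

`msd_curve()` pools all overlapping displacements. Overlap makes large
lags wildly under-informative — a 2,000-step track has 2,000 lag-1
displacements but effectively one independent lag-2,000 displacement —
so each point carries a weight equal to the number of independent
displacements, $\sum_{\text{tracks}} \lfloor n/\Delta t \rfloor$. The
weighting is not cosmetic: unweighted, the noisy tail dominates and the
persistent-random-walk fit collapses onto a pure-diffusion solution (a
regression test in the suite demonstrates exactly this failure).

`fit_furth()` fits the persistent random walk MSD form
$\mathrm{MSD}(\Delta t) = 4D(\Delta t - P(1 - e^{-\Delta t/P}))$ in two
stages. Lattice cells barely move below their persistence time, so small
lags deviate from the continuous model; a rough weighted fit on all
retained lags gives order-of-magnitude $(D_0, P_0)$, then the final fit
uses lags $\Delta t \ge P_0$. Both stages fit on the log scale — the
scale MSD curves are judged on — estimating $\ln D$ rather than $D$, and
both use the independence weights (prescribed for the final stage;
harmless and stabilising in the rough one). Two windowing choices
stabilise the estimator: lags beyond a quarter of the longest lag are
discarded up front (fewer than four independent displacements per track
remain there, and their strongly correlated noise otherwise drags the
fit; in ground-truth recovery experiments this cut removes an upward
bias of up to ~40% in $P$), and stage-1 $P$ is bounded below by one
logging interval (persistence below the sampling interval is not
resolvable, and letting the optimiser collapse there stalls stage 2 on
vanishing finite differences). Further numerical guards: both stages run
Levenberg-Marquardt least squares directly with box constraints; lags
whose model argument would be non-positive under trial parameters drop
out of that iteration's objective; weights are normalised to mean 1 to
keep the normal equations well-scaled. Starting values:
$P_0^{\text{start}}$ = 10 logging intervals, $D_0^{\text{start}}$ =
MSD at the largest lag / (4 x largest lag).

`autocov_curve()` takes mean dot products of step vectors at each lag;
for a persistent random walk this decays as $c\,e^{-\Delta t/P}$.
`fit_autocov()` first drops lags $\Delta t \le 0.5 P_{\text{MSD}}$ (the
same small-lag lattice artefact), then finds $t_{5\%}$, the smallest
retained lag where the autocovariance falls below 5% of the curve's
initial value, and drops lags $\Delta t \ge 3 t_{5\%}$ — beyond that the
curve is noise around zero, which would otherwise dominate. The decay
constant is fitted as $P^2$ so the optimiser cannot visit negative
persistence, starting from $(c = 1, P_{\text{MSD}}^2)$. If the curve
never decays below threshold the window stays open and the fit is
returned flagged (`converged = FALSE`) with whatever large $P$ the data
imply. The 5% reference is the curve's value at its smallest available
lag (before the half-$P_{\text{MSD}}$ filter): for a clean exponential
with $P = 5$ sampled at integer lags this puts $t_{5\%}$ at 15, i.e.
$\approx 5\ln 20$.

`grouped_estimates()` reports speed and both persistence estimates as
mean ± SD over 6 groups of 5 tracks, grouped in simulation order — six
independent replicate estimates rather than one pooled number.

## The run-and-pause reference model

To show what evolution does when the genotype-phenotype map is *direct*,
`simulate_beauchemin()` implements a classic run-and-pause description of
T-cell motility: straight runs of duration `t_free` at speed `v_free`
alternating with stationary pauses of `t_pause`, a fresh uniform
direction each run. We simulate in the plane (the coverage fitness below
is planar, so a 3D walk would only add a projection step), start with a
run, and sample positions at integer steps for 10,000 steps.

Its fitness stamps a disc of radius $r = 13$ pixels (about one T-cell
area) onto an imaginary lattice at every sampled position and counts
distinct covered lattice points, divided by $\pi r^2$ exactly (not the
rounded 530). All three parameters evolve from 1 under the same GA for
25 generations. Because parameters map directly onto behaviour, runs
predictably lengthen, speeds rise, pauses shrink — and once consecutive
discs stop overlapping, fitness saturates and the parameters drift: the
fitness plateau that makes longer runs pointless in this model.

## Synthetic ground truth

`make_prw_tracks()` generates persistent random walks by angular
diffusion: the heading performs a Gaussian random walk with per-step
variance $2\Delta t/P$, which makes the step-vector autocovariance decay
exactly as $e^{-\Delta t/P}$ (since
$E[\cos\theta_k] = e^{-k\sigma^2/2}$), at perfectly constant step speed.
This calibration is verified by a test, not assumed. `make_furth_msd()`
and `make_exp_autocov()` evaluate the two model curves noiselessly so the
fitters can be held to $10^{-6}$ self-consistency. `make_toy_lattices()`
provides byte-stable miniature states (intact, touching, split, and
boundary-straddling cells) for the energy and connectedness oracles.

What the generators deliberately do *not* emulate: the small-lag lattice
artefacts of real CPM tracks (jitter without net motion below the
persistence time), cell shape, breaking, or tissue interactions. Passing
the recovery tests therefore validates the estimators on ideal
persistent random walks; the CPM integration tests, not the generators,
exercise the artefact-handling windows of the fitters.

## Problem sizes and reproducibility

Full study conditions (10 runs x 50 generations x 40 individuals x
10,000 MCS on a 150x150 grid, per environment) are an overnight,
embarrassingly parallel computation. The package's own test suite and
acceptance script instead run the model at sizes chosen to finish in
minutes while preserving the phenomena: `scaled_free_config()` keeps all
CPM parameters and the full population structure but uses a 100x100
grid, 2,000-MCS evaluations and 15 generations, which reproducibly shows
the evolutionary trend (rising `max_act`, `lambda_act`, fitness);
migration statistics at the evolved optimum (50, 1165) are computed at
full resolution (150x150, 10,000 MCS, 30 tracks), where one simulation
takes well under a second.

Every stochastic function takes a seed; all kernel randomness flows from
one 64-bit seed through a counter-based generator, and R-level seeds are
derived from the caller's seed via R's RNG, so a master seed reproduces
an entire evolutionary run bit-for-bit (tissue seeds and per-individual
simulation seeds are recorded in the history and manifests).

## Known limitations

* The breakage check runs at the logging cadence; a cell that splits and
  re-merges entirely within 5 MCS would not be flagged by default.
* At the evolved optimum, cells are persistent beyond the 10,000-MCS
  measurement horizon: the autocovariance never reaches its 5% point
  within one track, the window stays open, and both persistence
  estimators return large, flagged values. This is a property of the
  measurement design, not a fit defect; persistence is best quantified at
  parameter points whose decay fits inside the horizon (e.g. the
  mid-trajectory presets).
* The evolved optimum's exact location depends on engine conventions
  (neighbourhood choices, acceptance rule) that published engines vary
  in; qualitative structure — motility evolving to the edge of the
  breaking regime, speed-persistence trade-offs — is robust, exact
  endpoint values are not guaranteed to match other implementations
  digit-for-digit.
* Connectedness component analysis treats the torus as connected through
  the boundary; a cell wrapped entirely around the torus is still one
  component.
* The run-and-pause model omits directional persistence across pauses
  and 3D confinement; it is a deliberately minimal contrast model.
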