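---
title: "Modelling CXCR5-driven B-cell migration in the lymph-node follicle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling CXCR5-driven B-cell migration in the lymph-node follicle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

follisim simulates naive B cells migrating inside a lymph-node B-cell
follicle, guided by the chemokine CXCL13 through its receptor CXCR5. The
simulator couples three layers:

1. **Stromal network** (`generate_network()`). Three CXCL13-secreting
   stromal subsets are placed in a 250 x 250 x 350 um follicle box:
   marginal reticular cells (MRC, 100 cells) in a 20-um shell under the
   subcapsular sinus (the top face), follicular dendritic cells (FDC,
   Poisson with mean 200) in the central third, and B-zone reticular cells
   (BRC, Poisson with mean 450) in the outer follicle. Each node is joined
   to its 3 nearest same-subset neighbours, giving a connected dendritic
   web per compartment. Secretion (0.18 fg min^-1 cell^-1 at baseline for
   all subsets) is distributed along the web: each node's output is split
   over the node and interpolated points every 5 um along its incident
   edges (`secretion_points()`), conserving total output. We initially
   secreted from nodes only, as the positions are the only imaging-derived
   quantity we reproduce; with isolated point sources, however,
   chemotaxing cells oscillate at local concentration maxima and
   wild-type cells scan *fewer* lattice sites than receptor-deficient
   cells — inverting the knockout phenotype the model is validated
   against. A connected secreting web produces ridged concentration
   landscapes that cells travel along, which restores the phenotype;
   node-only secretion remains available (`secrete_along_edges = FALSE`).

2. **Chemokine field** (`chemokine_field()`, `step_field()`). CXCL13
   amounts live on a 10-um lattice as double-precision molecule counts.
   Each 1-s molecular step applies, in order: secretion deposits,
   explicit 7-point-stencil diffusion (D = 7.6 um^2 s^-1), and
   first-order decay (0.007 s^-1) as an exact exponential factor.
   Boundaries are no-flux, so pure diffusion conserves mass to machine
   precision and decay is the only field sink; this makes the ligand
   budget auditable (the engine reports secreted, decayed, captured,
   released and clamped totals every run). The explicit scheme requires
   D dt/dx^2 <= 1/6; `step_field()` refuses unstable steps, while the
   engine automatically subdivides the diffusion update when a
   sensitivity analysis samples large D (up to 146 um^2 s^-1).
   Unit bridges: 0.18 fg min^-1 of a 10,300 g mol^-1 protein is ~175
   molecules s^-1; a (10 um)^3 voxel is 1 pL, so 1 nM corresponds to
   ~602 molecules per voxel. At baseline the burned-in follicle averages
   ~1.5 nM with ridge peaks of a few nM, inside the 1-50 nM range
   supported by experimental estimates.

3. **B-cell agents** (`run_simulation()`). Each of the 6000 agents (an
   8-fold downscaling of the 4.8 x 10^4 measured B cells per follicle)
   carries a four-state CXCR5 pool — free, ligand-bound, desensitized,
   internalized — advanced every second by one RK4 step of the linear cycle
   with the local ligand concentration held fixed:
   binding (k_on = 4.8e5 M^-1 s^-1), unbinding (k_off = 4.8e-3 s^-1),
   desensitization (k_des = 0.075 s^-1), internalization
   (k_i = 3.3e-3 s^-1) and recycling back to the free surface pool
   (k_r = 4e-3 s^-1). The pool sum is conserved exactly. Ligand captured
   by binding is removed from the containing voxel, ligand released by
   unbinding is returned, and ligand on internalized receptors is
   destroyed; all three integrals use the same RK4 quadrature so the
   budget closes to 1e-6 relative.

### Gradient sensing and movement

Every 15 s each cell makes a movement decision. Six surface sectors (cell
radius 3.5 um along the +-x, +-y, +-z axes) sample the field — by
trilinear interpolation by default, because nearest-voxel lookups quantize
the perceived gradient to lattice steps and cells then chase
discretization noise. Each sector is allocated one sixth of the cell's
current *free* receptors, and its readout is the equilibrium occupancy at
the sector concentration, `(r_free/6) * L / (L + Kd)` with
Kd = k_off/k_on = 10 nM. The signal is `delta_LR`, the spread between the
best- and worst-occupied sector; the literature value of 10 receptors
across a cell is the threshold. We examined two alternative probe
formulations — a single 1-s or 15-s kinetic step of the full four-state
cycle per sector — and found that the desensitization drain caps their
sensitivity near 0.3 nM across a cell, which essentially abolishes
baseline chemotaxis; the equilibrium readout is the classical formulation
from which the 10-receptor threshold originates and uses only the
calibrated binding constants. Desensitization still modulates sensing,
but through the whole-cell free pool: sustained exposure drains free
receptors into the desensitized and internalized pools, which lowers
sensing capacity — the single-cell receptor tracks show desensitized >
internalized >> bound at steady exposure.

Above threshold the cell turns with wrapped-Gaussian angular noise of
standard deviation alpha1 = 0.475 rad about the chemotactic target;
otherwise it performs a persistent random walk about its current heading
with alpha2 = 3.8 rad (effectively uniform turning). The chemotactic
target is the normalized *sum* of the occupancy-weighted gradient
direction and the current heading: pure gradient-targeting makes cells
ping-pong across ridge crests (the sampled speed drops ~25% from reversal
chords), whereas retaining polarity momentum lets the gradient steer a
persistent run. Each step displaces the cell by exactly
7.4 um min^-1 x 0.25 min along the new heading; the follicle boundary
reflects (an ellipsoidal boundary mode is available). Turns are clipped
at 180 degrees, which never binds for wrapped draws.

### Outputs

Tracks are sampled every 20 s for 60 min after a 30-min field-only
burn-in (agents enter after burn-in). Per cell we report: total
displacement (path length), net displacement, velocity (total/time),
motility coefficient (net^2 / 6t), corrected meandering index
(sqrt(t) x net/total, which may exceed 1), the scanning rate (distinct
10-um lattice voxels containing any sampled position), and the four
receptor-pool trajectories. Stationary tracks return 0 for the ratio
metrics. Note that sampled-track velocity is below the instantaneous
7.4 um min^-1 because a 20-s sample spans up to two 15-s moves and
records their chord.

## Emergent behaviour and the knockout contrast

Receptor knockout (`knockout()`, r_total = 0) leaves a pure persistent
random walk; a wild-type cell in a chemokine-free follicle follows the
bit-identical trajectory. At physiological density the 6000 agents
together capture ligand roughly twice as fast as the stroma secretes it,
so occupied regions are grazed down, the landscape continuously remodels,
and chemotactic runs keep finding fresh chemokine: wild-type cells scan
~40-50% more voxels than knockout cells. This collective-consumption
feedback is load-bearing: in a sparsely populated follicle (e.g. 500
cells in the full volume) the landscape is static, chemotaxing cells
anchor on the stromal web, and the contrast inverts. Desk-scale
replicates of density-dependent behaviour therefore use
`downscale_params()`, which shrinks the follicle volume and every cell
count by the same factor (the geometry module's density-matched mode),
rather than thinning cells in a full-size follicle.

## Uncertainty and sensitivity toolkit

* `a_test()` — Vargha-Delaney effect magnitude (wins + half-ties over all
  pairs), with effect classes at 0.56 / 0.66 / 0.71 symmetric about 0.5.
  Behavioural significance throughout the package means exceeding the
  medium (0.66) threshold.
* `aleatory_analysis()` — 20 subset distributions per candidate sample
  size, subsets 2..20 A-tested against the first; the recommended
  replicate count is the smallest whose maxima stay below medium effect.
* `oat_robustness()` — one-at-a-time perturbation against the calibrated
  baseline with paired seeds.
* `lhc_prcc()` — Latin-hypercube design (`lhs`), rank-transform, PRCC as
  the correlation of the two rank-regression residual vectors, t-test
  against zero, Benjamini-Hochberg adjustment alongside raw p-values.
* `efast()` — sinusoidal sampling with the maximum frequency
  floor((NS-1)/2M) assigned to the parameter of interest (M = 4
  harmonics), complementary frequencies cycled over
  1..max(1, floor(wmax/2M)), random phase shift per resample curve, an
  inert dummy parameter, and two-sample t-tests of Si/STi against the
  dummy across curves. With 65 samples per curve the indices of additive
  test functions are recovered to ~0.005 when a single complementary
  parameter carries variance; when several complementary parameters share
  the same low frequency their spectra interfere and errors can approach
  0.05 — an inherent property of the frequency budget at this sample
  size, relevant when reading small indices.
* `calibration_score()` — Shapiro-Wilk normality gate (the migration
  statistics are not normal, motivating the non-parametric choice), then
  Mann-Whitney U against the reference; a configuration must pass both
  wild-type and knockout references (`passes_calibration()`). Printed
  references come as median [q1 - q3]; `surrogate_from_quartiles()`
  reconstructs a log-normal sample matching the median and the log-scale
  IQR width (the printed quartiles are not log-symmetric, so both
  quartiles cannot be matched by a two-parameter family; the width is the
  robust choice).

The 13-parameter sampling vector is frozen as: r_total, k_on, k_off,
k_des, k_i, k_r, fdc_secretion, rc_secretion, decay_rate,
diffusion_coeff, displacement_constant, alpha1, signal_threshold.
signal_threshold is a constant carried in the vector for structural
completeness; design code holds constants at their single value, and the
emulator's input normalization maps them to 0.5. The diffusion range
[0, 146] um^2 s^-1 and decay range [2e-4, 0.05] s^-1 are used as printed.
`cognate_fraction` (5%) is carried in the configuration but drives no
implemented behaviour.

## Emulation and multi-objective optimization

`build_training_set()` draws an LHC design over the 13 ranges, executes
each set with replicate seeds, and uses the median of per-run medians of
the four behaviour outputs (velocity, meandering index, motility
coefficient, scanning rate); rows split 75/15/10 into train/test/
validation. `train_emulator()` min-max normalizes inputs over the
sampling ranges and outputs over the training rows, selects the network
depth (1-4 hidden layers of 8 logistic units; linear outputs) by ten-fold
cross-validated RMSE, refits, and reports held-out MSE. The network is
trained by full-batch backpropagation with Adam updates and a small L2
penalty; it is written in-package because no installed fitter spans
multiple hidden layers. Trained emulators predict deterministically.

`optimize_receptors()` runs NSGA-II (non-dominated sorting, crowding
distance, binary tournament, SBX crossover eta = 15, polynomial mutation
eta = 20, mutation probability 1/13) over the 13-parameter box with four
objectives: minimize |emulated - reference| for speed (8.0), meandering
index (1.1) and motility coefficient (15.6) — the wild-type calibration
anchors, configurable, with a simulator-in-the-loop adapter possible via
the objective closure — and maximize emulated scanning. The returned
front is re-filtered by an exhaustive non-domination check.
`front_parameter_distributions()` min-max scales front members to the
sampling ranges and reports normalized histograms and sample skewness;
positive skewness means mass piled at the low end of the range. Defaults
(population 100, 300 generations, crossover 0.9) follow common NSGA-II
practice; the upstream analysis selected its settings by a sweep over
crossover/mutation in [0.1, 1] and 200-500 generations, and all settings
are exposed.

## Problem sizes used by the test-suite replicates

The full-scale analyses behind the published figures used 1000 LHC sets
x 100 replicates on a cluster; the package's acceptance checks rerun the
same pipelines at desk scale on one CPU: calibration uses 10 replicates
of a density-matched 500-cell follicle (60 min tracks); the knockout
contrast uses 20 paired runs at quarter scale; the end-to-end emulation
uses 50 LHC sets x 5 replicates of a density-matched 100-cell follicle
with 30-min tracks, 15-min burn-in, and 100 NSGA-II generations. At this
scale the k_off front distribution robustly skews low; weaker effects
(e.g. the k_on skew direction) sit near the resolution limit of a
100-member front built on 50 training points, and the emulator's partial
dependences (scanning increasing in k_on and r_total, decreasing in
k_off) are the more stable readout of the optimization direction.

## Numerical and degenerate-input conventions

* One master seed drives a run; batch replicate i uses master + i. Runs
  are bit-reproducible given (parameters, seed).
* Update order within a molecular step is fixed: secretion, diffusion,
  decay, receptor exchange; motility every 15th step.
* Receptor capture can momentarily exceed a voxel's content when many
  cells share a voxel; the voxel is floored at zero and the correction is
  reported in the `clamped` budget entry (zero in all tested regimes).
* A uniform field gives a degenerate direction sum; the cell keeps its
  heading and (below threshold) walks randomly. alpha -> 0 reduces the
  heading draw to the target exactly.
* `r_total = 0` short-circuits receptor work; an empty field and a
  knockout produce identical trajectories by construction.

## Known limitations

* The stromal graph is a zoned Poisson/k-NN surrogate matching subset
  counts and compartments, not the imaged network topology; edges beyond
  secretion placement carry no physics (no haptotaxis, no adhesion).
* A single effective diffusion coefficient; no immobilized
  matrix-bound chemokine fraction.
* Mean-field (deterministic) receptor kinetics per cell; no stochastic
  binding noise, no intracellular signalling cascade.
* No cell-cell collisions or shape dynamics; agents are points with a
  sensing radius.
* The printed secretion/decay baselines yield a ~1.5 nM mean follicular
  concentration, at the lower end of the experimentally supported 1-50 nM
  window; sensing calibration accounts for this via the equilibrium
  probe.
* Baseline wild-type dispersal is under the imaging medians: sampled
  velocity ~6.9 um min^-1 (printed 8.0 [2.3-10.3]) and meandering index
  ~0.64 (printed 1.1 [0.1-2.4]) sit inside the experimental
  interquartile ranges and pass the Mann-Whitney comparison, but the
  motility coefficient (~3.4 vs 15.6 um^2 min^-1, IQR [0.1-96.7]) does
  not: chemotactic runs steered along the tortuous surrogate web
  decorrelate direction faster than the imaging data imply, shortening
  net displacement. Matching the printed motility coefficient would
  require longer-range gradient alignment than the zoned Poisson/k-NN
  stromal surrogate can produce.
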