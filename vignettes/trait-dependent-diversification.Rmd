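---
title: "Methods: ranking and confirming drivers of diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ranking and confirming drivers of diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Given a time-calibrated, ultrametric phylogeny and a species-by-variable
table of candidate ecological and morphological predictors, which
variables actually shape speciation rates?  `divdrivers` implements a
two-arm strategy used in macroevolutionary studies of large plant
radiations such as the cacti:

1. **Screening** — estimate a per-tip speciation rate, then rank dozens
   of mixed-type predictors by their bootstrapped relative importance in
   a gradient-boosted regression of log rate, with a quantile rule for
   significance and an explicit contrast that quantifies how much
   variable *interactions* contribute.
2. **Confirmation** — for each variable that survives screening, fit
   quantitative-trait state-dependent speciation–extinction (QuaSSE-type)
   models by maximum likelihood and compare seven functional forms by
   AIC, which accounts for shared ancestry in a way the learner cannot.

A trait-dependent birth–death simulator and synthetic table/occurrence
generators close the loop: every stage can be exercised, and its
statistical behaviour validated, without any external data.

# Tip rates

`dr_statistic()` computes the DR statistic, the inverse of the
equal-splits measure: for a tip whose root path has edge lengths
$l_1, l_2, \dots$ ordered pendant-first,
$\mathrm{ES} = \sum_j l_j (1/2)^{j-1}$ and $\mathrm{DR} = 1/\mathrm{ES}$.
Indexing direction matters and published descriptions vary; here $j = 1$
is the pendant edge, so recent splits dominate.  A root edge above the
basal split is excluded — there are no splits above it to weight.  DR
applies no sampling-fraction correction; externally computed rates (e.g.
BAMM posterior mean tip rates, which can carry per-genus sampling
fractions) can be imported with `read_tiprate_table()` and validated
against the tree.

# The importance-ranking protocol

The response is $\log(\text{rate})$: rates are strictly positive and
right-skewed, and accuracy metrics (bias, $R^2$) are reported on this
scale.  Missing predictor values are passed to the boosted-tree
learner's native sparse handling rather than imputed; categorical
variables are one-hot encoded and their importance summed back to the
source variable.  Relative importance is normalized total split gain —
the conventional default among the gain/cover/frequency options, and the
only one that sums meaningfully across variables.

Tuning is two-stage (`tune_two_stage()`): a predefined grid (learning
rate {0.01, 0.05, 0.1, 0.3} × depth 2–7 × row subsample {0.5, 0.8, 1} ×
column subsample {0.5, 0.8, 1} × minimum child weight {1, 5}, boosting
rounds by early stopping on 5-fold cross-validated rmse), then 1000
uniform draws within ±10% of the stage-one optimum (integers rounded,
ranges clamped, depth kept in [2, 7]).  All evaluations share one fold
assignment and the stage-one optimum is a stage-two candidate, so stage
two can never end worse than stage one.  Parameter-perturbation
refitting (stage two) and data-perturbation bootstrapping (below) are
deliberately distinct procedures.

`bootstrap_importance()` resamples rows with replacement, fits on a
random 80% and evaluates on the held-out 20% of each resample, and
records the per-variable importance distribution over `B = 1000`
replicates (desk-scale runs in the test-suite use B in the tens to low
hundreds).  A variable is significant when its 25% importance quantile
strictly exceeds the chance-expectation threshold $1/p$ — with the
reference table of $p = 39$ variables, 1/39.  `stump_contrast()` reruns
the identical protocol with depth forced to 1; since a stump ensemble
cannot represent interactions, the drop in mean $R^2$ measures the
interaction contribution.  `prediction_curve()` profiles the fitted
model over 250 evenly spaced values of one variable with all others
pinned at their median (continuous) or mode (discrete).
`sensitivity_filter()` drops species with rates above a cutoff (default
0.65) so the whole protocol can be re-run without fast-rate outliers.

# The QuaSSE-type likelihood

For a trait $x$ evolving by Brownian motion with diffusion variance
$\sigma^2$ and drift $\phi$ per Myr, speciation rate $\lambda(x)$, and
constant extinction $\mu$, the likelihood propagates two functions
backward in time along every branch: $E(x, t)$, the probability that a
lineage in state $x$ at time $t$ leaves no sampled descendant, and
$D(x, t)$, the density of the observed subtree data.  The governing
equations combine a pointwise "reaction" part

$$\frac{dE}{dt} = \mu - (\lambda + \mu) E + \lambda E^2, \qquad
  \frac{dD}{dt} = -(\lambda + \mu) D + 2 \lambda E D,$$

with advection–diffusion of both functions in $x$.

**Numerics.**  `propagate_branch()` uses symmetric (Strang) operator
splitting on a regular grid of `nx` points (default 1024, power of two):
a half reaction step, then alternating diffusion and reaction steps,
then a closing half step.  The reaction part is solved *exactly* at each
grid point with the constant-rate birth–death closed form, so the only
time-discretization error is the splitting commutator, which is second
order in the step.  The diffusion part is applied spectrally (FFT): one
step multiplies the transform by the characteristic function of a
Gaussian with variance $\sigma^2 \mathrm{d}t$ and mean $-\phi\,
\mathrm{d}t$.  Because the reaction update is exact for any step and the
splitting is second order, a step of tree height/200 (the fitting
default; height/1000 for one-shot evaluations) gives log-likelihoods
stable to well under 0.05 — the suite checks both step-halving and
nx-doubling stability on a 50-tip fixture.

Spectral convolution is circular, so after each step a guard band of
width `max(4, ceil((8 sqrt(sigma2 dt) + |phi| dt)/dx))` cells at each
edge of the grid is zeroed for $D$, absorbing wrapped mass.  $E$ is
deliberately *not* zeroed: it is nearly flat at the boundary (both ends
approach the same state-independent extinction probability), so wrap is
harmless there while zeroing would bias extinction downward.  The grid
is built with margin $5\sqrt{\sigma^2_{\max} h}$ beyond the observed
states (`quasse_grid_auto()`), and the optimizer's upper bound on
$\sigma^2$ is tied to what the grid supports.

Tips are initialized as $D(x) = \rho\, N(x;\, x_{\mathrm{tip}},
(2\,\mathrm{d}x)^2)$ — the Gaussian is a numerical mollifier, not a
claim about measurement error; its width is configurable — and
$E(x) = 1 - \rho$, which is how the sampling fraction $\rho$ enters.  At
internal nodes $D \leftarrow D_{\mathrm{left}} D_{\mathrm{right}}
\lambda(x)$.  At the root the default weighting integrates $D$ against
$w = D / \int D$ (the "observed" weighting); a flat weighting is also
exposed, and is the one under which the constant-$\lambda$ likelihood
factorizes exactly into birth–death × Brownian terms (used by the oracle
tests).  Conditioning on survival of the two root lineages (dividing by
$\int w\, \lambda (1 - E)^2$) is on by default and exposed as a toggle,
since published analyses rarely state their choice.

**Drift sign.**  The convention is fixed by a round-trip property rather
than by notation: simulating forward with $\phi > 0$ (traits tend to
increase toward the present) must make $\phi > 0$ the better-supported
value when refitting.  Backward in time this means the $D$ and $E$
functions shift by $-\phi\, \mathrm{d}t$ per step — an ancestor most
likely sat below its descendants.  The suite asserts this round trip.

**Closed-form anchors.**  With $\lambda$ constant the trait cannot
influence the tree, and the joint likelihood factorizes (flat root) into
the Nee-type constant-rate birth–death likelihood with sampling
(`bd_loglik()`) times a Brownian REML likelihood of the states
(`bm_reml_loglik()`, Felsenstein pruning with the mollifier's variance
added at the tips).  The grid machinery reproduces this sum to better
than $10^{-3}$ on 2–50-tip fixtures, and the tree component is invariant
to states, $\sigma^2$ and $\phi$ — which is the meaningful form of
"state independence" for a likelihood that is joint over tree *and*
states.

A numerical caveat worth recording: $D$ values are only trustworthy down
to roughly $10^{-15}$ of the local maximum (FFT round-off).  Tip
configurations *astronomically* inconsistent with the model (sister
species whose true Gaussian overlap is below that floor, e.g. states
drawn independently of the tree at tiny $\sigma^2$) are penalized less
than exact arithmetic would dictate.  Any parameter region a fit
actually visits is orders of magnitude away from this regime, and the
inconsistent region remains heavily penalized, so optimization is
unaffected; but exact-arithmetic comparisons there would require
extended precision.

# Fitting and the seven-model comparison

`fit_model()` optimizes with `nlminb` on a transformed scale (log for
rates, variances and the sigmoid slope; identity for midpoints, linear
coefficients and drift) under explicit bounds: $\lambda$ parameters in
$(10^{-6}, 20)$, $\mu \in [0, 20)$, $\sigma^2 \in (10^{-8},
\sigma^2_{\max})$, modal width $s^2 \in (10^{-6}, 10^4)$, $\phi \in
(-5, 5)$, midpoints within the grid.  Default starts come from the
data: a Yule-type $\hat\lambda = (n - 2)/L$ from tip count and total
branch length $L$, $\hat\sigma^2 = \mathrm{Var}(x)/h$ from trait
variance over tree height, midpoint at the trait median.  `nstart`
controls jittered restarts (default 5; desk-scale runs use 1–2, which
the warm-started surface tolerates well).

`compare_models()` fits the seven members — constant; linear, sigmoid,
modal, each with and without drift (the constant model has no drift
variant: with a state-independent $\lambda$ the drift is unidentifiable
from the tree side) — on **one shared grid and step size**, so AICs are
directly comparable.  Later members warm-start from earlier ones
(drift variants from their no-drift fit; all forms take $\mu,
\sigma^2$ from the constant fit).  Parameter counts are 3; 4/5; 6/7;
6/7, AIC $= 2k - 2\ln L$, and support is flagged decisive when the
best-versus-second margin exceeds 4 AIC units.  Variables that entered
the analysis log-transformed have their fitted midpoints back-transformed
with `exp` in reports (`modal_optimum()`).

# The simulator and synthetic generators

`simulate_quasse_tree()` is the forward counterpart of the fitted model
class: discrete-time Euler steps of size
$\min(0.001\,T_{\max},\ 0.01/\max(\lambda + \mu))$ in which each lineage's
trait takes a Brownian-with-drift increment, then speciates with
probability $\lambda(x)\mathrm{d}t$ or dies with probability
$\mu\,\mathrm{d}t$.  Both daughters inherit the parent trait exactly —
anagenetic change only, matching the fitted model class (no cladogenetic
jumps, no protracted speciation, no fossilized birth–death).  Extinct
lineages are pruned, extant tips are subsampled with probability $\rho$,
and the returned tree is extant-only and ultrametric to $10^{-8}$.
Stopping is at a target extant count (preferred for benchmarks: fixes
the information content) or a time horizon; total extinction raises an
explicit error so callers can retry with the next seed
(`simulate_quasse_tree_retry()`).

`generate_predictor_table()` emulates the structure of a real
macroevolutionary predictor table: correlated latent normals, binary
variables thresholded at a stated prevalence (the analogue of
growth-form or pollination binarisation), quantile-binned categorical
variables (biome-like), missingness inserted completely at random at a
configurable fraction (default 0.2159; real tables' missingness is
unlikely to be MCAR, but no mechanism is documented for the reference
dataset, so MCAR is the honest default), and a positive response rate
built as the sum of planted speciation-function responses (plus an
optional product interaction) times mean-one lognormal noise.  What it
does *not* emulate: phylogenetic autocorrelation among rows, shared
spatial structure among predictors, and informative missingness — so a
passing screen here demonstrates the protocol's statistical behaviour,
not robustness to those real-data pathologies.
`generate_occurrences()` produces clustered points with optional planted
exact duplicates and off-mask records for exercising the cleaning
filters.

# Spatial conventions

"One record per km²" and AOO are *area* statements, so grids are built
in a world cylindrical equal-area projection
($x = R\,\mathrm{lon}$, $y = R \sin(\mathrm{lat})$, $R = 6371.0088$ km)
rather than by degree rounding, anchored at the projection origin (grid
anchoring affects boundary points and is otherwise arbitrary; it is
fixed and recorded).  Within-cell retention during thinning is the first
record under a deterministic (species, lat, lon) sort — reproducibility
over randomness.  AOO uses cleaned but *unthinned* records at a 0.1 km
cell (small cells resolve the many tiny ranges typical of cacti;
cross-checking against 2 km cells via `compare_aoo_cellsizes()` confirms
rank stability), reported in km² and log-transformed when it enters
state-dependent fits.  Manual curation steps used in real workflows
(visual inspection, expert range corroboration) are approximated by the
polygon mask filter; they are not algorithmically reproducible.

# Benchmark conditions

`benchmark_conditions()` pins five simulate-then-refit configurations,
one per variable scale: optima at 10.20 °C (diurnal temperature range),
48.38% (soil sand content), 45.74 cm (plant size, log scale), 0.55
(isothermality) and 0.23 (range-size AOO, log scale).  Chosen once, on
design grounds: peak-to-baseline speciation ratio 4.5 (0.45 vs 0.1 per
Myr) — a strong but not caricatured signal, above the ratio-3 floor the
discrimination benchmark requires; mode width and diffusion set so the
realized trait spread is two to three mode widths (informative about
both sides of the optimum); root at the optimum; drift small on each
variable's scale (for the range-size analogue a small −0.02 rather than
a published −0.45 whose scale is undocumented and which would sweep the
clade far off the optimum within the simulated timespan); extinction at
0.03 per Myr.  `recover_modal_optimum()` refits the generating family
and reports back-transformed optima.

`benchmark_discrimination()` is designed differently, because its
question is different: can the seven-model comparison separate the
generating modal-with-drift model *decisively* from every alternative,
including its own no-drift nested sibling?  That requires the drift to
be part of the detectable signal, so the root starts 1.5 mode widths
below the optimum and the drift (0.15 per Myr) carries the clade up
through the peak over the tree's depth; the mode (width sd ≈ 0.7) is
narrower than the realized trait spread so the downslope past the
optimum is observed and a hump cannot be mimicked by a sigmoid.  With a
near-zero planted drift the runner-up would necessarily be the same
modal family without drift, sitting ~2 AIC away by the parameter
penalty alone — no configuration could then clear a 4-AIC margin.

# Problem sizes

Production-scale defaults (1000-tip trees, B = 1000, 1024-point grids,
five restarts) are the reference protocol.  The shipped test-suite and
acceptance script run the same code at desk scale, a deliberate
package-design choice: recovery benchmarks use 150–200-tip trees with
3–5 seeds per condition and single (screened) starts; the discrimination
benchmark uses one 250–300-tip tree; importance checks use 8 generator
seeds with B = 50 and full-size (850 × 39) tables.  The suite's
state-dependent fits run on 512-point grids (the reproduction script
keeps 1024; the grid-convergence check bounds the difference far below
any tolerance in play).  Tolerances are never scaled — only replicate
counts, grid sizes and tree sizes are.

# Known limitations

- DR is a tree-shape proxy; it carries no sampling-fraction correction
  and saturates for deep, slow clades.  Sampling-corrected rates should
  be imported from a dedicated estimator.
- Extinction is constant (trait-independent) throughout; the model class
  confirms *speciation* dependence only, and no hidden-state models are
  provided.
- The learner's importance is predictive, not causal; correlated
  predictors share gain, and the 1/p threshold is a chance-expectation
  heuristic rather than a formal test.
- The occurrence tooling assumes WGS84 point records; no coordinate
  uncertainty, no name resolution, no API clients.
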