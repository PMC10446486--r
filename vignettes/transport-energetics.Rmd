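---
title: "Transport energetics: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport energetics: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transportfe)
```

transportfe quantifies the energetics and ion coupling of substrate transport
by membrane proteins — the motivating system is cholesterol export through
RND-family transporters such as PTCH1 — from the sampled output of molecular
simulations. This vignette documents the statistical models, the tunable
parameters and their defaults, and the design choices made where more than one
reasonable convention exists.

## Potentials of mean force by WHAM

Umbrella sampling restrains the substrate at a ladder of positions along a 1D
reaction coordinate with harmonic biases $w_i(x) = \tfrac12 k_i (x - c_i)^2$.
`solve_wham()` removes the biases with the weighted histogram analysis method,
iterating the coupled equations

$$p_j = \frac{\sum_i n_{ij}}{\sum_i N_i \, e^{(f_i - w_i(x_j))/RT}}, \qquad
  f_i = -RT \log \sum_j p_j \, e^{-w_i(x_j)/RT}$$

to self-consistency, where $n_{ij}$ is window $i$'s histogram and $N_i$ its
sample count. The profile is $-RT\log p_j$.

Parameters that matter, with defaults:

* **Bins** — 200 over the sampled range (the common default of the gmx wham
  tool this mirrors). The bin grid can be pinned with `range =` so profiles
  from different data sets are comparable bin-by-bin; all replicate
  comparisons in the test suite do this, since a profile's steep flanks can
  differ by ~1 kJ/mol when two data sets define slightly different grids.
* **Convergence** — maximum change in the window constants $f_i$ below
  `tolerance` (default 1e-6 kJ/mol), capped at 1e5 iterations;
  non-convergence is an error carrying the last residual, never a silent
  result.
* **Anchoring** — profiles are defined up to a constant. The default anchor
  zeroes the minimum over the last 10% of the coordinate range, which for
  ligand-extraction coordinates is an unbound plateau; any interval can be
  supplied. Re-anchoring shifts the profile by a constant only.
* **Empty bins** — interior bins with no samples are flagged `NaN` and
  skipped downstream; interpolating across them would hide a sampling gap.
* **Temperature** — a required per-window field (coarse-grained lipid
  systems are conventionally run at 323 K, atomistic ones at 310 K), never a
  global constant. All windows entering one WHAM solve must agree.

### Bayesian bootstrap errors

`bootstrap_pmf()` repeats the WHAM solve under random re-weightings and
reports the per-bin standard deviation of the anchored profiles; 2000 rounds
is the conventional production choice, and 200 rounds already stabilises the
error field on the synthetic systems used here. Two granularities are
offered because published descriptions rarely say which was used:

* `method = "bayesian"` (default): Dirichlet(1, …, 1) weights over *complete
  windows*, matching the complete-histogram scheme of gmx wham. This treats
  the window as the exchangeable unit.
* `method = "samples"`: multinomial resampling of data points within each
  window.

On the synthetic systems both agree with errors measured across independently
seeded replicate data sets to well within a factor of two (the acceptance
suite checks the ratio), provided samples are approximately decorrelated —
the generator's Metropolis chains are thinned (`stride`, default 5) for this
reason. On real, strongly autocorrelated window time series both schemes
share the usual caveat that they see only the variability present in the
retained samples.

### Extracting numbers from profiles

`binding_free_energy()` reports (minimum over a bound region) − (mean over a
reference region) with the two errors combined in quadrature.
`profile_barrier()` estimates extrema with a local quadratic fit (±5 bins by
default) rather than a raw max/min, because the maximum of noisy bins is
biased upward by the noise itself; with per-bin errors of ~0.3 kJ/mol the raw
max over ~80 candidate bins overestimates a barrier by ~1 kJ/mol, which the
fit removes. `convergence_series()` recomputes the profile on cumulative
time prefixes and reports the largest change between the last two — the
standard convergence diagnostic for umbrella runs.

## Alchemical legs: MBAR, BAR and exponential averaging

Alchemical legs (decoupling a ligand over a λ schedule; perturbing Na⁺ to
K⁺) are estimated from the reduced-potential matrix $u_{kn}$ — each pooled
sample evaluated at every state. `estimate_mbar()` solves the MBAR equations

$$f_k = -\log \sum_n \frac{e^{-u_{kn}}}{\sum_l N_l \, e^{f_l - u_{ln}}}$$

by quasi-Newton minimisation of the MBAR objective followed by
self-consistent polishing to 1e-8 (dimensionless), with asymptotic errors
from the weight-matrix covariance (the eigendecomposition form). The
smallest adjacent-state element of the overlap matrix is reported and a
warning raised below 0.03 — below that, neighbouring λ windows barely share
phase space and the estimate is untrustworthy. BAR (`estimate_bar()`, exact
antisymmetry under state swap) and exponential averaging (`estimate_exp()`)
serve as cross-checks; in the high-overlap limit all three agree within
statistical error, and this is tested.

Units are reduced internally and kJ/mol at the interface. Equilibration
discard is a parameter (`discard_fraction`): 0 for exactly-distributed
synthetic samples, while the `fep`/`abfe` command-line legs default to 4%,
mirroring the convention of discarding the first 200 ps of 5-ns production
windows.

Cycle book-keeping is deliberately dumb arithmetic: `combine_abfe()` computes
site − reference − restraint terms with quadrature errors (restraint
contributions are accepted only as supplied values — the package never
computes restraint volumes analytically, since production workflows carry
them as an explicit gas-phase λ leg); `perturbation_cycle()` subtracts bound
and free legs; `replicate_statistics()` reports mean ± SD between repeats;
`check_inverse_perturbation()` verifies that forward and reverse
transformations agree in magnitude and differ in sign.

## Transport cycles

`compose_path()` chains directed legs (auto-reversing where needed), sums
values and combines errors in quadrature — appropriate because the component
PMFs/legs are statistically independent. Raw floats are preserved; reporting
rounds half-up to integer kJ/mol (`format_reported()`), the precision at
which such values are conventionally printed. `cycle_closure()` compares an
independent direct estimate against a composed indirect one and reports the
discrepancy, whether zero lies in the combined 1σ interval, and whether the
signs agree. The canonical SSD→membrane leg is the OH-up cholesterol
orientation; alternative legs (OH-down, non-physiological paths) can be
represented but are never composed automatically.

## Electrochemical gradients and stoichiometry

The free energy of moving one mole of ion from outside to inside is

$$\Delta G = RT \ln\!\frac{[X]_\text{in}}{[X]_\text{out}} + zF\,\Delta V,$$

with $R$ = 8.314 J mol⁻¹ K⁻¹, $F$ = 96 485 C mol⁻¹, concentrations treated
as activities, and the sign convention $\Delta V = V_\text{in} -
V_\text{out}$ (physiological resting potentials are negative; negative
$\Delta G$ means influx is favourable). This convention is stated explicitly
because the equation alone does not fix it. Standard cellular gradients are
built in (`ion_na()`: 12/145 mM; `ion_k()`: 150/4 mM); temperature defaults
to 310 K.

`coupling_ions()` converts an export cost into the number of ions whose
downhill movement must be harnessed: the transport direction (influx for
Na⁺-coupled, efflux for K⁺-coupled models) is always an explicit argument,
never inferred. Both the continuous ratio (export ΔG / per-ion driving
energy) and its ceiling are reported — the integer is what a mechanism needs,
the ratio is what a plotted curve shows. Where the driving energy is ≤ 0
(e.g. K⁺ efflux beyond its Nernst potential, ≈ −96.8 mV at 310 K) the result
is flagged infeasible rather than returning a negative count.

## Trajectory geometry

All probes operate on an in-memory `trajectory` (nm coordinates, orthorhombic
box, constant atom table); multi-model PDB is the interchange format (read
via bio3d), keeping fixtures plain-text. Conventions, each chosen once and
documented:

* Cylinder boundaries are **closed**: a point exactly on the radius or end
  cap counts as inside. The default axis is the membrane normal (z);
  rule-based centres ("midpoint of two residues' CA atoms") are re-evaluated
  every frame. The extracellular half is the positive axial side.
* Contacts use **all atoms** of a residue (a side-chain-only view can be had
  by pre-filtering the selection); water positions are represented by the
  oxygen atom, ions by the monatomic particle.
* Distances use the orthorhombic **minimum-image** convention; triclinic
  boxes are rejected outright rather than silently mishandled.
* Trailing-window summaries ("mean over the final 10 ns") take the window as
  a parameter (`tail_time`), and replicate aggregation is mean ± SD across
  trajectories.
* Density grids conserve mass exactly: voxel values are frame-averaged
  counts, so the grid total equals the mean selected-atom count per frame.
  Grids export to OpenDX text.

Every geometric operation is tested against brute-force enumeration
(point-in-cylinder over all atoms; 27-image minimum distances) on planted
fixtures, where agreement must be exact.

## Synthetic data and what passing tests mean

The generators provide every input class with a closed-form answer attached:

* `gen_umbrella_windows()` — Metropolis Monte Carlo on $U(x) + \tfrac12
  k(x-c)^2$. Defaults mirror production umbrella set-ups: $k$ = 1000
  kJ mol⁻¹ nm⁻², 0.05-nm window spacing, 323 K. The proposal step is tuned
  towards ~40% acceptance during a discarded burn-in; production steps are
  thinned (stride 5). Analytic landscapes include flat, harmonic, symmetric
  double-well (barrier exactly parameterised) and a well-plus-plateau shape
  emulating extraction of a lipid from a favourable environment.
* `gen_reduced_potentials()` — λ-interpolated harmonic states sampled
  *exactly* (Gaussians), with $\Delta G = (RT/2)\ln(\kappa_1/\kappa_0)$
  attached. A 29-state decoupling schedule (0.05 steps to λ = 0.6, 0.025
  after) round-trips through the file formats.
* `gen_toy_trajectory()` — planted scene: two 5-residue helix scaffolds with
  a prescribed separation schedule, an ion on an approach-and-bind path (a
  14-of-15-frame contact gives exactly 93.3%), a binding-site probe residue
  and bulk waters, written as multi-model PDB at 310 K conditions.

These fixtures establish estimator *correctness*: unbiasing, self-consistency,
error propagation, boundary conventions and determinism under a fixed seed.
They do not emulate force-field realism, sampling autocorrelation of real MD,
anisotropic water structure, or conformational heterogeneity — so passing
tests certify the analysis layer, not the simulations feeding it. Problem
sizes used by the test and acceptance runs — 21 windows × 5000 samples for
the double-well recovery (RMSE and barrier error well under 1 kJ/mol), 200
bootstrap rounds against 8 independent replicates, 10 000 samples/state for
MBAR/BAR — were chosen as the smallest sets at which the statistical
assertions have comfortable margins.

## Known limitations

* 1D, non-periodic reaction coordinates only; no 2D/periodic WHAM, no
  replica exchange, no nonequilibrium (Jarzynski) work analysis.
* MBAR input must be finite reduced potentials; the package never evaluates
  force fields, soft-core potentials or restraint volumes.
* Chain composition resolves a stated leg sequence; it does not search a leg
  graph for paths.
* Statistical-inefficiency subsampling before MBAR is not automated; the
  equilibration discard is a plain fraction.
* Geometry supports orthorhombic boxes only.
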