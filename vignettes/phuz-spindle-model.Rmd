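---
title: "Modeling PhuZ spindle positioning of the jumbo phage nucleus"
author: "phuzsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling PhuZ spindle positioning of the jumbo phage nucleus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phuzsim)
```

## The biological problem

Nucleus-forming jumbo phages of *Pseudomonas aeruginosa* (the phiKZ
family) inject their DNA at a cell pole and enclose the replicating
genome in a proteinaceous "phage nucleus". A spindle of tubulin-like
PhuZ filaments, nucleating at both cell poles, then pushes this
compartment to midcell. The filaments show dynamic instability:
episodes of steady growth ending in stochastic catastrophes (fast
depolymerization), followed by recovery. Treatments that elongate the
host cell — certain beta-lactam antibiotics, or induction of the
division inhibitor SulA — leave the spindle intact yet degrade
centering, which motivates a quantitative question: for which
combinations of cell length and filament kinetics does pushing by
dynamically unstable filaments center a cargo?

`phuzsim` implements a 1D stochastic model of this system, the
statistics used to quantify nucleus positioning in single cells, a
distribution-RMSD calibration of the unknown kinetic parameters, and
phase-space sweeps of centering efficiency.

## The model

The cell is the interval $[0, L]$. Two filaments nucleate at $x = 0$
and $x = L$ and grow toward midcell. The tip of a filament moves at

$$\frac{dx}{dt} = v_\mathrm{poly} - v_\mathrm{depoly} - v_\mathrm{cat},$$

where $v_\mathrm{cat}$ is zero during growth and becomes non-zero
during a catastrophe. Each speed is drawn from a Gaussian with a
configurable mean and standard deviation, truncated below at zero.
Growth lasts a Gaussian-distributed time $t_\mathrm{cat}$, after which
catastrophe begins; a Gaussian recovery time $t_\mathrm{rec}$ later,
the filament resumes growth with freshly drawn speeds. Interval draws
are truncated at zero and floored at one time step. A filament never
retracts past its own pole.

The nucleus is a hard segment of half-length $r$ (default 0.5 µm)
whose centre starts at 90% of the cell length, near the pole where the
phage DNA is injected (clamped into $[r, L-r]$). It moves in two ways:

* **Pushing.** If a growing tip would cross the near face of the
  nucleus within a step, the overshoot is transferred to the nucleus —
  unless the opposite tip is in contact with the far face, in which
  case nothing moves (a *jam*). A jam persists until a catastrophe
  retracts one of the tips. Pushing is also limited by the cell wall.
* **Diffusion.** Between contacts the nucleus diffuses with
  coefficient $D$, applied as a displacement
  $\sqrt{2 D \Delta t}\,\xi$, $\xi \sim N(0,1)$, clamped so the
  nucleus can pass through neither a touching tip nor the cell wall.

Each run integrates these rules with a time step of 0.01 s for 30
simulated minutes; an ensemble (default 500 runs) records the final
nucleus position of each run, optionally drawing each run's cell
length from a per-treatment Gaussian.

```{r single-run}
cfg <- phuz_default_config()
cfg$record_trajectory <- TRUE
run <- run_simulation(cfg)
run
```

## Parameters, units, and defaults

All lengths are in µm, times in s, speeds in µm/s. The shipped
defaults (`inst/extdata/phuz_default.yaml`, also the constructor
defaults of `kinetic_params()`) are an *illustrative calibrated set*:
the measured kinetic rates of PhuZ are not available to the package,
so the defaults were produced with the package's own calibration
module (below) against a control-like target distribution — 24%
off-center nuclei in cells of length $N(3.5, 0.6^2)$ µm — with the
polymerization rate and catastrophe interval free and the remaining
parameters fixed at magnitudes typical of tubulin-family dynamic
instability (fast catastrophic shrinkage ≈ 0.5 µm/s, brief recovery
≈ 6 s, slow basal depolymerization 0.01 µm/s).

Two radii are deliberately distinct:

* `stokes_radius` (1 µm) enters only the Stokes–Einstein closed form
  `stokes_einstein_D()` = $k_B T / 6 \pi \eta r$, with defaults
  $T = 310$ K and $\eta = 10^{-3}$ Pa·s (water).
* `nucleus_radius` (0.5 µm) is the collision half-length.

The calibrated configuration overrides the diffusion coefficient to
$10^{-3}$ µm²/s rather than the water value of 0.227 µm²/s. This is a
deliberate physical choice: Stokes–Einstein in water overestimates the
mobility of micron-scale compartments in bacterial cytoplasm by
orders of magnitude (crowding makes the effective viscosity for large
cargo hundreds of times that of water), and at the water value thermal
motion overwhelms pushing entirely — no kinetic parameter set centers
anything. Both the closed form and the direct override are exposed so
the assumption is explicit and revisable.

The speed re-sampling schedule follows the simplest reading of the
model: speeds are re-drawn at every phase change. An optional
`resample_interval` re-draws them on a fixed clock as well, so an
event-driven interpretation ("positions are updated if the random time
sampling associated with their movement has passed") can be emulated;
it defaults to off.

## Why this centers — and when it fails

With full collapses and regrowth from the pole, each growth episode
re-measures the nucleus position: a filament from the near pole
reaches the nucleus sooner and spends more of its growth interval
pushing, so pushes are biased toward the far pole — a restoring force.
Centering is efficient when the distance grown per episode,
$(v_\mathrm{poly} - v_\mathrm{depoly})\,t_\mathrm{cat}$, slightly
exceeds the half-length $L/2$: the filaments can reach the nucleus
from either pole but overshoot little. Elongating the cell at fixed
kinetics breaks this tuning — distal filaments no longer reach within
one growth interval — and the nucleus drifts, the model's explanation
for antibiotic-induced mispositioning. `centering_sweep()` maps this
as the fraction of endpoints inside the central 20% window over a
cell-length × polymerization-rate grid, classifying cells as centering
when that fraction exceeds 80%.

```{r sweep, eval = FALSE}
sw <- centering_sweep(sweep_axis("cell_length", 2.5, 14, 8),
                      sweep_axis("v_poly_mean", 0.02, 0.16, 6),
                      phuz_default_config(), runs_per_cell = 100, seed = 1)
sw$fraction
```

## Position statistics

Measured or simulated single-cell tables (columns `treatment,
timepoint_min, cell_length_um, nucleus_position_um`) are normalized to
$p = x/L \in [0,1]$. A nucleus is *off-center* when
$|p - 0.5| > w/2$ with window $w = 0.2$; the boundary itself counts as
centered (the strict convention is a package choice — the boundary
convention is not standardized). Histograms use 10 equal-width bins on
$[0,1]$ by default (binning is configurable and the calibration
objective depends on it; 10 bins resolves the central window while
keeping per-bin counts stable at a few hundred cells).
`length_position_correlation()` correlates per-cell length with the
centering deviation $|p - 0.5|$ by default, which is monotone with
mispositioning; the raw-position convention is available via a flag.
When the recording pole of a dataset is unknown, the `fold` option
maps $p \mapsto \min(p, 1-p)$; all off-center statistics are
fold-invariant.

## Calibration

Free kinetic parameters are fitted by minimizing the RMSD between the
binned measured distribution and the model's,

$$\mathrm{RMSD}(a, b) = \sqrt{\tfrac{1}{B}\sum_i (a_i - b_i)^2},$$

averaged over replicate ensembles (default 3). The optimizer
formalizes a random-mutation / estimated-partial-derivative scheme as
stochastic finite-difference descent: each iteration (i) evaluates a
Gaussian mutation of the best-seen point, (ii) estimates the partial
derivatives by central differences (one-sided at bounds; a
simultaneous-perturbation mode is available), with both evaluations of
a difference pair sharing derived seeds (common random numbers), and
(iii) takes a per-coordinate sign step of geometrically decaying
length. Sign steps rather than gradient-magnitude steps are used
because the Monte-Carlo gradient magnitudes are noisy and the
objective can be badly scaled across parameters; the decaying step
length then controls the resolution. The best-seen value is tracked,
so the reported trace is non-increasing by construction. Convergence
is declared when the best RMSD improves by less than 1% (relative)
over 5 iterations.

Because the endpoint distribution depends on the *net* growth rate,
the polymerization-vs-depolymerization surface contains a valley of
near-constant RMSD along $v_\mathrm{poly} - v_\mathrm{depoly} =
\mathrm{const}$; `rmsd_surface()` visualizes such degeneracies by
evaluating 200 random points and interpolating them linearly
(an in-package Delaunay triangulation with barycentric
interpolation). Fixing some rates from independent measurements is
what breaks this degeneracy in practice.

## The synthetic-data generator

`generate_measurement_table()` emulates deposited single-cell tables.
Cell lengths are Gaussian per treatment (rejection-resampled to exceed
the nucleus diameter). Positions come either from full simulations
("simulator" mode — ground truth for end-to-end recovery tests) or
from a parametric mixture ("parametric" mode): a centered Gaussian
around midcell plus a uniform component over the cell interior
(default support excludes the outer 5% per pole, where a nucleus
centre cannot physically sit), with closed-form off-center expectation
`expected_off_center_parametric()` and an inverse
`tune_uniform_weight()`. Parametric mode isolates the statistics and
calibration modules from the simulator, and lets fixture tables be
tuned to published summary fractions (24% off-center control-like,
60% piperacillin-like). The shipped fixture suite
(`make_fixture_suite()`) is *synthetic and illustrative*: per-treatment
length means are plausible choices (control 3.5 µm; elongated
conditions 2–4×), not measurements.

What parametric tables do not emulate: any correlation between an
individual cell's length and its position error (each cell draws
independently), measurement error structure beyond optional Gaussian
noise, and inter-replicate variability. Tests passing on them validate
the statistics pipeline, not the biology; simulator-mode tables add
the length→mispositioning coupling but inherit every model idealization
below.

## Numerical choices and degenerate inputs

* Time step 0.01 s; displacement per step is well below the collision
  geometry scale, and a convergence check in the test suite verifies
  that coarsening dt to 0.05 s changes the endpoint distribution by
  less than the seed-to-seed noise floor (heavier test blocks use the
  coarser step for speed and state so).
* Negative Gaussian draws truncate to zero (speeds) or to one step
  (intervals) — physical non-negativity.
* Collision resolution is simultaneous and mirror-symmetric: both
  candidate tip displacements are computed from the pre-step state; a
  double would-cross jams (tips advance only to contact); a single
  would-cross pushes, limited by the opposite tip and the wall;
  diffusion is then clamped between contacts. Ties (exact contact)
  count as contact. This symmetric form was chosen over sequential
  left-then-right updates so that reflecting the initial condition,
  swapping the per-filament RNG streams and negating the diffusion
  stream yields the mirrored trajectory exactly — an invariant the
  test suite asserts, ruling out left/right bias by construction.
* Each run consumes three independent RNG streams (left filament,
  right filament, diffusion) derived from (master seed, run index,
  stream id) with splitmix64, so run $i$ is invariant to the ensemble
  size and every result is reproducible from one integer seed.
* Degenerate inputs rejected with errors: cells shorter than the
  nucleus diameter, dt ≤ 0, empty position vectors, zero-variance
  correlations, mismatched histogram binning, infeasible length
  profiles (bounded rejection retries), unknown config keys.

## Problem sizes in the test suite

The packaged tests run ensembles of 40–500 runs and durations of
4–30 simulated minutes, chosen so the full suite completes in a few
minutes while each assertion retains a 3-sigma margin under its fixed
seeds; the acceptance-style checks state their sizes inline
(500-run ensembles at the paper-scale 30 minutes for the centering
trend; reduced ensembles at dt = 0.05 s for the optimizer recovery
experiment, with the dt-convergence check above justifying the
coarsening).

## Known limitations

* Strictly 1D: no excluded volume, filament bundling, bending, or
  nucleus rotation; no capsid trafficking; no treadmilling.
* No explicit GTP hydrolysis chemistry — catastrophe/recovery are
  phenomenological Gaussian clocks; no length- or age-dependent
  catastrophe rates.
* The two filaments are kinetically identical and filaments per pole
  are collapsed into one effective filament.
* The diffusion coefficient of a phage nucleus in infected cytoplasm
  is unmeasured; the calibrated value is an assumption (see above).
* Calibration fits only the endpoint distribution; kinetic time-series
  information (e.g. filament length traces) is not used, which is
  precisely why degenerate parameter directions exist.
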