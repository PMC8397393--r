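---
title: "Methods: quantifying cation-mediated eDNA adhesion to silica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cation-mediated eDNA adhesion to silica}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednasilica)
```

Extracellular DNA (eDNA) released by bacteria acts as an adhesive in early
biofilm formation: polyanionic DNA sticks to negatively charged silica
because dissolved cations screen and bridge the two surfaces. This package
implements the three quantitative workflows used to characterise that
interaction — AFM single-molecule force spectroscopy (SMFS) curve
processing, radiolabel saturation-binding analysis, and molecular-dynamics
trajectory post-processing — together with a synthetic-data module that
generates inputs with analytic ground truth, so that every stage of the
pipeline is testable without instrument data.

## 1. Force-curve processing

A force–distance curve records cantilever force $F$ (pN) against piezo
displacement $z$ (nm), in an approach and a retraction segment. The
processing chain is:

1. **Baseline.** Mean and SD of $F$ over the farthest 25% of points, where
   the tip is too far from the surface to interact. The fraction is a
   package choice (`window_fraction`, default 0.25): wide enough that the
   SD estimate is stable, far enough that interactions at up to roughly
   half the force distance do not contaminate it.
2. **Alignment.** Vertical: subtract the baseline mean. Horizontal: fit a
   least-squares line to the steepest contiguous 20% of the
   constant-compliance (contact) region, defined as the contiguous run of
   near-surface points with $F > m\sigma$, and shift $z$ so this line
   crosses $F=0$ at $z=0$. Curves with no compliance run are flagged
   non-contacting and receive the vertical alignment only.
3. **Onset.** Scanning from far to near, the first run of $k \ge 4$
   consecutive points deviating from the baseline mean by more than
   $m\sigma$ ($m = 3$). With Gaussian noise the per-point exceedance
   probability is about 0.0027, so a false run of four is vanishingly
   rare (measured < 1% per 500-point curve; in practice orders of
   magnitude lower).
4. **Adhesion force.** Magnitude of the global force minimum, zero if the
   curve never crosses below zero; ties resolve to the smallest $z$.
5. **Work of adhesion.** $W = -\int \min(F, 0)\, dz$ by the trapezoid
   rule, in aJ ($10^3$ pN·nm = 1 aJ). `work_of_adhesion()` integrates the
   whole trace by default. The batch pipeline (`analyze_curves()`)
   integrates only up to the detected onset and scores a retraction with
   no detected rupture event as $W = 0$: the far, non-interacting part of
   a real trace contributes only clamped noise, which would otherwise
   bias $W$ upward by $\sigma z_{\max}/\sqrt{2\pi} \cdot 10^{-3}$ aJ
   (about 1 aJ for $\sigma = 5$ pN over 500 nm) and would make $W > 0$
   on every noise-only curve, contradicting the requirement that positive
   work implies at least one rupture event.
6. **Event census.** The published analysis counted secondary adhesion
   peaks by inspection; the package replaces this with a hysteresis
   detector on a lightly smoothed trace (running mean over 5 points). An
   event arms after `min_points = 3` consecutive points below $-m\sigma$
   and releases when the force recovers by `release_fraction = 0.5` of
   the running event depth for 3 consecutive points; event minima closer
   than `min_separation = 2` nm merge. The smoothing and run-length
   requirements exist because a slow force ramp crossing the threshold
   band chatters: without them, single noise points split one rupture
   into several. All thresholds are parameters of `count_events()`.
7. **Jump-to-contact.** On approach curves, the farthest point where the
   force sits below $-m\sigma$, the local gradient toward the surface
   exceeds `snap_slope` (10 pN/nm), and the attractive well persists for
   3 consecutive points.

## 2. Saturation binding

Bound ligand follows the Langmuir isotherm
$B = B_{\max} F / (K_d + F)$. Two estimators are provided and agree to
$10^{-6}$ relative on noiseless data:

* `langmuir_nls`: nonlinear least squares (port algorithm, positive
  bounds, started at $B_{\max,0} = 1.2\max B$, $K_{d,0} = \mathrm{median}\,F$);
* `scatchard_ols`: ordinary least squares of $B/F$ on $B$; slope
  $-1/K_d$, intercept $B_{\max}/K_d$, parameter SEs by the delta method.
  Points with $F = 0$ are dropped with a warning (the transform is
  undefined there).

Supporting conversions: mass→molar via the fragment length and a mean
base-pair mass of 650 g/mol (a standard dsDNA average, configurable);
radioactive decay correction $\mathrm{cpm} \cdot 2^{t/t_{1/2}}$ with
$t_{1/2} = 25.35$ d for ³³P (standard value, configurable).

Derived worked examples: molecules per cell
($B_{\max} N_A / \text{cells per litre}$); surface coverage of a
cylindrical cell using the lateral area $\pi d L$ only (with end caps
included the same inputs fall below the stated >90% threshold, so the
lateral-area convention is adopted and documented); DNA contour length
(0.34 nm/bp); and the free-eDNA population fraction (eDNA mass per
genome mass per cell).

## 3. Trajectory post-processing

Trajectories are orthorhombic periodic boxes of typed, charged particles;
z is the surface normal and all distances use the minimum-image
convention. Roles (`cation`, `phosphate_O`, `silica_O`, `other`) come
from a species map, never from element symbols, because the bridge
definition must distinguish DNA phosphate oxygens from silica oxygens.

* **Charge density.** Per-frame charge-weighted histogram of heights
  above the surface reference plane (mean z of the topmost 1 Å of Si),
  averaged over frames. Heights are wrapped into $[-L_z/2, L_z/2)$, so
  the profile integral equals the selection's total charge exactly — an
  invariant asserted in the tests.
* **Solvation shells.** First shell: $d \le r_1$ (closed bound); second:
  $r_1 < d \le r_2$. The cutoffs are not printed with the study; the
  defaults (Na–O 3.2/5.6 Å, Ca–O 3.0/5.2 Å) are typical radial
  distribution function minima, are configurable everywhere, and
  `pair_rdf()` lets users derive values from their own trajectory.
* **Bridges.** An O(phosphate)–cation–O(silica) triplet with both oxygens
  inside the cation's second shell, labelled by the shell pair. A
  triplet's lifetime is its longest contiguous run of frames (strict
  continuity by default; a `gap` option tolerates short disappearances)
  times the frame interval; unique triplets are counted under each
  lifetime threshold (50/200/500 ps). Whether published counts are
  unique complexes or per-window averages is ambiguous; unique-complex
  counting is adopted and documented.
* **Energetics.** `energy_barrier()` takes a profile of final
  configurational energies vs centre-of-mass separation (minimum shifted
  to zero), computes the far-field level as the mean over the outermost
  window, and reports the peak above it, floored at zero; it is invariant
  under a common energy offset. `adhesion_energy_density()` converts a
  per-cell energy to mJ/m²; `deprotonation_count()` and
  `neutralizing_cations()` reproduce the surface-charge setup arithmetic.

## 4. The synthetic world

The generators state, once, the conditions the analyses are validated
against; ground truth is always computed analytically from the recipe,
never by running the analysis under test.

**Force curves** (`gen_force_curves()`): baseline noise sd 5 pN (chosen
to make detection nontrivial — no noise magnitude is published), force
distance 500 nm, spring constant 40 pN/nm, a compliance region crossing
zero exactly at $z = 0$, and rupture events as linear ramps (default),
rectangles, or worm-like chains (persistence length 50 nm for dsDNA).
Condition presets mirror the measured scales: calcium presets have one
deep pull-off with mean work 34 aJ (1 mM; 138 aJ at 10 mM) plus a
jump-to-contact at 14.6/44.3 nm; sodium presets have 2–3 small
well-separated ruptures, no snap-in, a 30–50% no-binding fraction, and
mean works near 1 and 0.14 aJ. Per-curve heterogeneity is a mean-one
lognormal scale on rupture forces (sdlog 0.42 Ca, 0.3 Na), floored
(`scale_min`) so every scripted rupture stays above the noise floor —
below it an "event" is undetectable in principle and exact event
recovery is not a meaningful test. The 10 mM calcium pull-off is placed
at 300 nm so the interaction never reaches the farthest-25% baseline
window. What a green test establishes: the pipeline recovers work,
event counts and onsets from curves with realistic noise and the
published scales. What it does not: real curves have correlated noise,
drift beyond linear, and rupture shapes other than the three models.

**Binding data** (`gen_binding_data()`): $K_d = 1.3$ nM, $B_{\max} = 1.9$
nM, a 10–5000 ng/mL ladder of a 688 bp fragment, multiplicative Gaussian
noise (CV 5%), 3 replicates — the published assay design.

**Toy trajectories** (`gen_toy_trajectory()`): a 49 × 39.5 Å lateral
cell with the slab plane at 4 Å, cation heights drawn per frame from a
Gaussian layer (centre 2.2 Å, an organised divalent layer) or a uniform
1–3.5 Å band (diffuse monovalent layer), a polymer strand at the 3.6 nm
bound-state separation, and scripted bridge events that place the
triplet at the midpoints of the requested shell annuli during their
windows and keep partners > $r_2$ apart otherwise. Lateral zoning
(polymer strip, bridge sites, free-cation zone) guarantees no
unscripted bridge can form, which is what makes the census truth exact.
No forces or integrator are involved: these trajectories validate the
post-processing, not the physics.

## 5. Numerical choices and degenerate inputs

* Trapezoid integration throughout; piecewise-linear test fixtures make
  the expected areas exact.
* `estimate_baseline` requires ≥ 8 window points; curves require ≥ 16.
* Noiseless data (sd 0) is legal everywhere except onset detection,
  which needs a positive sd to define its threshold.
* Scatchard fits reject non-saturating (non-negative slope) data with an
  error rather than returning a negative $K_d$.
* The cation count check rejects net charges not divisible by the
  valence (no fractional ions).
* Coverage fractions above 1 are reported as-is with a warning.
* Seeds: every generator is a pure function of (recipe, seed); the RNG
  state of the caller is saved and restored.

## 6. Known limitations

* Dynamic force spectroscopy (loading-rate dependence, experimental
  energy barriers) is out of scope, as are vendor binary formats and
  binary trajectory formats.
* The event census is algorithmic where the original analysis was
  manual; counts on marginal curves (ruptures within a few noise SDs of
  the threshold, e.g. the 20 mM sodium condition) are not guaranteed
  exact — that condition sits at the detection limit by construction.
* Kinetic binding models are not fitted (association was complete at the
  first sampling time); fits are per-dataset, with no joint model across
  wash treatments.
* Entropic contributions to the binding energetics are not estimated;
  the energy profile analysis is purely configurational.
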