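---
title: "Methods: modelling electrostatic tick attraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling electrostatic tick attraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling decisions behind `electrotick`: the
physical assumptions, the numerical scheme and its verification, the
generative model behind the synthetic experiments, and the places where a
genuine design choice had to be made.

## 1. The physical model and its assumptions

A charged vertebrate host (or the laboratory electrode standing in for
one) is a conductor held at a surface potential V₀ of order several
hundred volts; vegetation, soil and the laboratory ground plate are
earthed conductors. Between these equipotentials the air gap carries an
electrostatic field governed by Laplace's equation ∇²V = 0 with Dirichlet
data on every conducting surface.

**Conductor (Dirichlet) treatment.** Because every material surface in the
scenes is either grounded or held at a fixed potential, the interior
conductivity and permittivity of soil, tissue or grass cannot influence
the air-gap solution; they are carried only as metadata on dielectric
shapes. This is the single most consequential simplification in the
package: it reduces a conduction-current problem to a pure boundary-value
Laplace problem. The one genuine dielectric in the rig — the wooden
support rod behind the electrode — is excluded by default
(`include_rod = FALSE`). A sensitivity check with the rod included as an
ε_r = 2 cylinder (the solver supports piecewise permittivity through
harmonic-mean face coefficients) moves the 0.5 mm probe field by well
under 1%: the rod sits behind the electrode, outside the gap region that
controls the probe.

**Scene idealizations.**

* The rectangular 200 × 130 mm ground plate is represented in the
  axisymmetric rig scene as a disc of equal area (radius ≈ 91 mm). The
  probe sits on the axis 0.5 mm above the plate, tens of plate radii from
  the edge, so edge shape is negligible there.
* The grass blade's cross-section is only loosely constrained physically
  ("about a millimetre thick"); the default is a 1 mm × 5 mm ribbon, and
  both dimensions are exposed as parameters. Doubling the width changes
  the tip probe field by a few percent — well inside the slack of the
  "field exceeds 300 kV/m" claim it supports.
* The tick is a point particle at its mid-height (0.5 mm above the
  substrate). Averaging the field over a finite body is out of scope.
* Exterior boundaries: the domain bottom is grounded (Dirichlet 0, the
  physical earth); sides and top carry zero normal flux, the usual default
  for open boundaries when the true far-field condition is unknown.

**Geometry note.** The rig electrode is a 1.5 cm diameter sphere. (A
1.5 mm figure also circulates for this apparatus; only the 1.5 cm value
is consistent with the ~222 kV/m probe field, and the image-charge oracle
confirms it: 221.6 kV/m analytically.)

## 2. Numerical scheme

**Discretization.** Finite volumes on uniform grids: in cylindrical
(r, z) coordinates the face transmissibility between radial neighbours i
and i+1 is (i + ½)h and the z-face weight is the control-volume integral
of r (i·h², with h²/8 on the axis node, whose control volume is the half
cell [0, h/2]); this keeps the operator symmetric positive definite and
builds the axis symmetry condition ∂V/∂r = 0 in naturally. The 3-D scheme
is the standard 7-point stencil. Curved conductors are rasterized first
order: every node inside the shape is fixed at the conductor potential,
so the effective surface is accurate to one cell — the reason the grids
below resolve the gap with 60 cells.

**Nested two-level solve.** The vegetation scene spans 1 m while its gap
is 2.5 mm; a uniform grid at gap resolution is out of reach. The package
therefore solves a coarse pass over the whole domain (default h = 5 mm in
3-D, 0.5 mm in the rig), then a fine pass on a refinement box around the
gap (default h = gap/60, capped at 0.05 mm in the rig; 0.1 mm in 3-D)
with Dirichlet boundary values interpolated multilinearly from the coarse
solution. The refinement box must enclose the whole gap segment; boxes
that fail to are rejected. Conductor nodes on box faces take their
conductor potential, overriding interpolation.

**Linear solver.** Matrix-free conjugate gradients on the finite-volume
operator (implemented in C++), relative residual 1e-8 by default. Coarse
passes use 1e-6: they only feed boundary values whose accuracy is limited
by the coarse discretization itself, not by the algebraic residual.
Non-convergence within the iteration budget is an error carrying the
final residual, never a silent return.

**Fields and probing.** E = −∇V by central differences (one-sided on grid
edges, E_r = 0 on the axis). Probes interpolate the field components
multilinearly and report the norm of the interpolated vector; points
outside the grid or within one cell of a conductor are rejected, because
the one-sided gradient against a Dirichlet surface is not probe quality.

**Verification.** Three independent routes, all in the test suite:
the parallel-plate scene (exact linear solution, reproduced to 0.1% at
every interior node); the classical image-charge series for the
sphere–plane capacitor (the rig solver agrees on the axis to better than
1% at h = gap/60, against a required 2%); and Richardson grid-convergence
reports (first-order or better observed, <1% change between the two
finest spacings of the default ladder). Structural invariants — the
discrete maximum principle (up to iterative-solver slack of order the
residual tolerance), exact linearity in the boundary data, and polarity
symmetry of |E| — are asserted on every solved scene.

**Problem sizes.** The shipped defaults solve the rig on a
301 × 601 coarse / 401 × 401 fine node pair (about five seconds) and the
vegetation scene on 201³ coarse / 121³ fine nodes (about two minutes).
These sizes were chosen as the smallest at which the verification suite's
accuracy statements hold with margin; the test suite uses the same or
slightly lighter grids.

## 3. The threshold law

By physical definition a zero gap needs zero voltage, so the
distance–voltage law is fitted through the origin: Ĝ = Σ dV / Σ d².
Two conventions needed fixing for forced-origin models:

* R² is computed about zero (uncentered) — the standard summary for
  no-intercept regression, and the one consistent with an F statistic on
  (1, n − 1) degrees of freedom (n = 72 gives F₁,₇₁ for the full
  staircase design).
* The free-intercept model is always fitted alongside, and both its
  intercept confidence interval and the ANOVA model comparison are
  reported, so the forced origin is a checkable assumption rather than a
  silent one.

`predict()` inverts the law in both directions: threshold voltage at a
gap (G·d) and attraction range of a surface voltage (V/G). The
`average_threshold_field()` operation closes the loop with the solver: it
drives the rig model at each tested distance with the fitted law's
voltage and averages the 0.5 mm probe fields, which lands a few percent
*below* the fitted gradient — the rig's field at the tick is about 0.85–0.96
of V/d across the tested gaps (the `rig_geometry_factor()`), which is
exactly why the gradient of the voltage law slightly overestimates the
true threshold field.

## 4. Mechanism forces

At a probed point the package evaluates the fixed-charge force qE and the
induced-dipole (dielectrophoretic) force α∇(|E|²)/2, the gradient taken
by central differences of probed fields one cell apart (stencils that
would touch a conductor are rejected; on the axisymmetric axis the radial
stencil uses mirror symmetry). The polarity contract — dipole force
invariant, charge force negated under V → −V — is asserted exactly. No
measured polarizability exists for tick nymphs, so α is a free parameter
used only for sign and direction statements, never for force magnitudes.

## 5. The synthetic experiments

The generators produce datasets with the statistical structure of the
three experimental designs; they are generative stand-ins, not fits to
the (external) raw data.

**Between-tick variability.** Each tick's threshold field is E* times a
unit-mean lognormal multiplier with coefficient of variation `cv`
(default 0.15). Lognormal keeps thresholds positive; no distributional
information on the real variability exists, and the default cv was chosen
once so that simulated staircase scatter resembles the published
scatter's visual spread. It is labelled a stand-in throughout.

**Staircase quantization.** The protocol records the first voltage on the
lattice start + k·step (50 V steps) at or above the true threshold —
recorded values are biased upward by at most one step. The consequence,
reproduced and tested by simulation: the fitted gradient over-estimates
E* by up to step/min(d) (≈ 33 kV/m at the 1.5 mm closest distance), and
recovered gradients fall in [E*, E* + step/min(d)] in ≥95% of replicate
seeds under the 6 × 12 design.

**Lift trials and the live-tick calibration.** A treatment tick fully
lifts when the applied field (V/d times the solver-derived geometry
factor) exceeds its threshold, partially lifts within a band just below
threshold, and otherwise can show a spontaneous "partial lift" by
locomotion (default rate 0.05, one in twenty). The dead-tick staircase
population (E* = 258 kV/m) is *not* used as the default here: at the
+750 V / 3 mm condition the applied field is ~222 kV/m, which that
population would rarely exceed, while the live-tick experiment observed
75% full lifts. The package treats this as a real difference between the
populations (live ticks lift more readily than freshly dead ones) and
calibrates the lift-trial default in closed form so that
P(full) = 0.75 and P(full or partial) = 0.90 at the applied field
(`calibrate_lift_population()`). Simulated tables then give χ² values
centred near the experimental one, which the test suite checks over
replicate seeds.

**Polarity groups.** Both groups draw |threshold| from one distribution
(the induced-polarization null); a `negative_scale` parameter emulates a
fixed-charge alternative. Under the null the permutation Mann–Whitney
rejects at the nominal 5% rate; at a ×2 threshold asymmetry it detects
the effect with ≥80% power at n = 12 per group — both verified by
simulation in the suite.

**Humidity covariates** are Gaussian (median 58.5%, sd 3%, clipped to a
physical range), matching the reported experimental conditions in
location and spread.

**What the generators do not emulate:** tick behaviour (questing
posture, grip, desiccation drift within a session), within-tick
correlation across repeated steps of the staircase (each recorded value
is one tick, as in the design), humidity *effects* on thresholds (the
covariate is carried but independent), and any polarity asymmetry beyond
the explicit `negative_scale` dial. Passing tests therefore validate the
pipeline's statistical behaviour under the stated generative model, not
the biology of real ticks.

## 6. Statistical conventions

* **χ² test:** Pearson, no continuity correction; adjusted standardized
  residuals (O − E)/√(E(1 − row/N)(1 − col/N)) as post hoc, with
  Bonferroni correction over all r·c cells (six for the 2 × 3 outcome
  table). Recomputing χ² from the published 2 × 3 outcome counts gives
  29.76, not the published 29.6 (and the published post-hoc residual 4.6
  recomputes to 4.9); the package reports the standard Pearson values and
  documents the discrepancy rather than matching the print.
* **Wald binomial CI:** p̂ ± 1.959964·√(p̂(1−p̂)/n) at 95%. For 15/20 the
  margin is ±19.0 percentage points; a published ±3.8% for that count is
  not reproducible by any Wald-type formula we know and is not
  reproduced.
* **Permutation Mann–Whitney:** midranks for ties; two-tailed p is the
  proportion of permutations with |U − n₁n₂/2| at least the observed,
  observed included, so p is never 0; exhaustive enumeration whenever
  the assignment count is ≤ 20 000, else 10 000 random permutations.
* **Levene's test:** classical form, absolute deviations from the group
  *means* (not the Brown–Forsythe median variant), F on (1, n − 2) df.
* **Bootstrap median CI:** percentile interval, 10 000 resamples by
  default, bit-reproducible under a seed.

## 7. Known limitations

* First-order conductor rasterization limits field accuracy near highly
  curved surfaces to ~1% at the default grids; fields *at* conductor
  surfaces are deliberately not probe-able.
* The nested solve's fine-level accuracy inherits coarse-level error
  through its boundary values; with the default box sizes this
  contributes less than the discretization error, but very small boxes
  hugging the conductors would not be safe.
* The vegetation scene is the simplified single-blade geometry; the
  multi-blade tuft and full host-animal geometries are qualitative
  variations only, with no quantitative claims attached.
* The threshold model is quasi-static: no tick dynamics after lift-off,
  no adhesion of tarsal claws, no charge relaxation during approach.
* All statistical procedures assume the experimental design sizes
  (groups of 12–20); the generators warn rather than stop when a
  staircase start voltage would saturate the design.
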