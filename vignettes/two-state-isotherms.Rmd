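---
title: "Two-state reorientation isotherms: model, numerics, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state reorientation isotherms: model, numerics, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(langmuir2s)
```

## The physical picture

A Langmuir monolayer of molecules that can either lie flat (horizontal, large
cross-section ξa₀, low energy) or stand upright (vertical, cross-section a₀,
energy λ k~B~T higher) responds to lateral compression by re-orienting: as the
available area shrinks, more molecules stand up. The signature in the surface
pressure–area isotherm is a shoulder bounded by inflection points. The model
implemented here captures exactly this mechanism and deliberately nothing
else: molecules interact only sterically, there are exactly two orientational
states, and the interface is a lattice of M unit cells (one vertical molecule
each) partitioned into M/ξ super-cells (one horizontal molecule each).

Counting the arrangements of N~h~ horizontal molecules on the super-cells and
N~v~ vertical molecules on the remaining sites, applying Stirling's
approximation, and adding the reorientation energy gives the free energy per
site (k~B~T units) in terms of the covered fractions φ~h~, φ~v~:

$$f(\varphi_h,\varphi_v) = \lambda\varphi_v
  + \frac{\varphi_h}{\xi}\ln\varphi_h
  + \Big(\frac{1}{\xi}-1\Big)(1-\varphi_h)\ln(1-\varphi_h)
  + (1-\varphi_h-\varphi_v)\ln(1-\varphi_h-\varphi_v)
  + \varphi_v\ln\varphi_v$$

`entropy_per_site()` and `free_energy_per_site()` expose the two pieces; a
test verifies the Stirling form against exact factorial counting on growing
lattices. Conservation of molecules fixes the scaled molecule number
φ₀ = φ~h~/ξ + φ~v~, so the physical state at given compression is the
minimizer of $\tilde f(\varphi_0,\varphi_v) = f(\xi(\varphi_0-\varphi_v),
\varphi_v)$ over the feasible interval of φ~v~.

Differentiating $\tilde f$ symbolically (the package carries all partial
derivatives up to third order in closed form) gives the stationarity
condition

$$\lambda + \ln\frac{\varphi_v}{\varphi_h}
  + (\xi-1)\ln\frac{1-\varphi_h-\varphi_v}{1-\varphi_h} = 0,
  \qquad \varphi_h = \xi(\varphi_0-\varphi_v).$$

The condition is re-derived from the free energy rather than copied from any
printed rendering, because typeset versions of this equation are easy to
misread (the orientation of the two ratios is exactly what a typo flips);
its correctness is pinned by two closed forms it must reproduce: the
decoupled case ξ = 1, where φ~v~ = φ₀/(1+e^λ^), and the special point
φ₀ = 1/ξ, where

$$\varphi_v^\star = \frac{1}{e^{\lambda}\big(\frac{\xi-1}{\xi}\big)^{\xi-1} + \xi},
\qquad
a_0\Pi^\star = -\ln(\xi-1) + \frac{1}{\xi}\ln\!\big[e^{\lambda}(\xi-1)^{\xi-1} + \xi^{\xi}\big].$$

Both are verified to 10⁻¹⁰ and better against the numerical pipeline in the
test suite.

## From free energy to pressure and inflections

The lateral pressure is the negative area-derivative of the total free
energy, which in scaled variables reads a₀Π = φ₀ f′~opt~(φ₀) − f~opt~(φ₀).
Differentiating the optimized free energy numerically would waste the
precision of the solver, so the package uses the envelope/implicit-function
route throughout: with $\tilde f$ known in closed form,

$$a_0\Pi = \varphi_0\Big(\tilde f_{\varphi_0}
 - \tilde f_{\varphi_v}\,\frac{\tilde f_{\varphi_v\varphi_0}}{\tilde f_{\varphi_v\varphi_v}}\Big) - \tilde f ,$$

where only the *value* of the equilibrium φ~v~ is inserted. At exact
equilibrium the correction term vanishes; keeping it makes the expression
first-order insensitive to solver error and valid for *imposed* distributions
such as the piecewise-linear approximation (`piecewise_linear_phi_v()`),
which interpolates φ~v~ linearly from 0 through φ~v~^★^ at the kink φ₀ = 1/ξ
up to 1.

Total derivatives of f~opt~ follow the same philosophy:
f″~opt~ is the Schur complement
$\tilde f_{00} - \tilde f_{v0}^2/\tilde f_{vv}$, and f‴~opt~ is obtained by
differentiating that expression along the equilibrium path, eliminating
dφ~v~/dφ₀ with the implicit function theorem. Inflection points of the
isotherm *in area coordinates* a/a₀ = 1/φ₀ are then the roots of

$$3 f''_{\mathrm{opt}}(\varphi_0) + \varphi_0 f'''_{\mathrm{opt}}(\varphi_0) = 0,$$

a transformation of the raw second-derivative condition that avoids
amplifying noise through the 1/φ₀ change of variables. `fopt_derivatives()`
ships a second, independent route — 5-point central finite differences of
f~opt~ at a base step of 10⁻³ with one Richardson extrapolation — and the
test suite requires the two routes to agree to 10⁻⁴ relative on randomized
parameters. (A single plain stencil cannot meet that bar: the third
derivative's truncation and rounding errors cross near step 10⁻⁴, which is
why the extrapolated two-step scheme is used.)

## Numerical choices

* **Equilibrium solver** (`solve_phi_v()`): the stationarity residual runs
  from −∞ at the lower end of the feasible interval
  [max(0, (ξφ₀−1)/(ξ−1)), φ₀] to +∞ at the upper end and crosses zero once.
  The solver brackets adaptively (geometric shrink toward whichever end hides
  the root — for |λ| ≈ 30 the root sits within e^−|λ|^ of an end point), runs
  80 vectorized bisection steps, and polishes with safeguarded Newton using
  the closed-form second partial. Default residual tolerance 10⁻¹².
* **Compensated boundary arithmetic**: near a full sublattice (large λ at
  φ₀ ≈ 1/ξ) the free-sublattice fraction u = 1 − ξ(φ₀−φ~v~) is of order
  10⁻⁸ while its naive evaluation loses every significant digit. u and the
  empty-site fraction w are therefore assembled with exact two-product
  (Dekker/Veltkamp) arithmetic, which keeps the pressure accurate to ~10⁻¹⁰
  and preserves the analytic signs of bracket end points.
* **0·ln 0 = 0** is applied explicitly at the boundaries; the empty
  monolayer has exactly zero free energy.
* **Inflection search** (`find_inflections()`): 2001 uniform φ₀ points on
  (10⁻³, 1−10⁻³), sign changes refined by bisection to 10⁻¹⁰ in φ₀, roots
  then mapped to a/a₀. The divergence of the pressure at closest packing is
  truncated at φ₀ = 1−10⁻³ rather than extrapolated.
* **ξ is real** (experimental ratios like 6.75 are not integers); only the
  combinatorial bookkeeping demo (`lattice_config()`) restricts ξ to
  integers. Energies are dimensionless throughout the core; units enter only
  in the landmark estimator and the I/O layer, with k~B~T = 4.14×10⁻²¹ J
  (≈ 300 K) as the default so that published worked arithmetic is reproduced
  digit for digit; a temperature override recomputes k~B~T from the
  Boltzmann constant.
* **Landmark inversion** (`lambda_from_dimensionless()`): evaluated in
  log-space, λ = t₁ + log(1−e^{t₂−t₁}) − (ξ−1)ln(ξ−1) with
  t₁ = ξ(ln(ξ−1) + a₀Π), t₂ = ξ ln ξ, so ξ·a₀Π of several hundred cannot
  overflow. The validity condition t₁ > t₂ ⇔ ξ > 1/(1−e^{−a₀Π}) is reported
  in the error when violated. λ is returned at full precision; published
  comparisons round to the integer or one decimal.

## The inflection-existence threshold

For fixed ξ, inflection points exist only above a critical reorientation
energy; `critical_lambda()` bisects the existence indicator to a default
half-width of 0.005 k~B~T. For ξ = 4 the package obtains **λ~c~ ≈ 2.89**.
A value of 3.85 has been quoted for this threshold in earlier work on the
same model; it is not reproduced here. Three mutually independent routes —
the closed-form implicit-differentiation condition above, finite differences
of f~opt~ computed by direct scalar minimization, and a 40-digit
multiprecision recomputation — all find a genuine (if shallow near onset)
concave dip in the isotherm for λ between 2.89 and 3.85 at ξ = 4, e.g. two
inflection points at λ = 3 near a/a₀ = 3.2 and 3.7. The dip's small
amplitude near onset (the condition reaches only ≈ −3 at λ = 3.0 against
values of +40 nearby) means a resolution-limited detection would first see
it only at larger λ, which is the likeliest origin of the higher quoted
value. The package reports what the stated condition yields; the test suite
asserts the sharpness of the computed threshold (existence at λ~c~+0.1,
absence at λ~c~−0.1) and its stability under grid refinement.

## The synthetic-data generator

`generate_synthetic_isotherm()` dimensionalizes a model curve (a = a₀·(a/a₀),
Π = a₀Π·k~B~T/a₀) on a uniform area-ratio grid and adds seeded Gaussian
pressure noise. It emulates what a plot digitizer produces from a recorded
isotherm: a clean, strictly monotone compression branch. It does **not**
emulate hysteresis, molecule expulsion at collapse, liquid-expanded/condensed
phase transitions, or domain formation — all present in real monolayer data —
so passing recovery tests demonstrate correctness of the pipeline on data the
model can represent, not robustness to physics outside the model. Default
noise of a few tenths of a mN/m matches the scatter of digitized literature
curves.

## Landmark detection and fitting

`detect_first_inflection()` smooths pressure against area with a local
quadratic over a sliding window (default 7 points; an explicit choice, since
by-eye identification has no published procedure), reads the curvature off
the quadratic coefficient, anchors at the strongest concave point (the
shoulder), and interpolates the curvature zero crossing on the large-area
side of that lobe. Anchoring at the dominant lobe rather than at the first
raw sign change keeps noise wiggles on flat stretches from masquerading as
the landmark; for noisy data a window of ~30 points is appropriate.

Two accuracy limits are worth knowing. First, the landmark recipe itself
carries a small bias: the inflection is *close to* but not *at* the analytic
point a/a₀ = ξ, so even exact landmarks of a model curve return λ slightly
off (≈ −1.8 % at ξ = 6.75, λ = 19). Second, for large λ the shoulder is
nearly vertical (at ξ = 6.75, λ = 19 the slope at the inflection is of order
10⁶ mN/m per nm²), so while the inflection *area* is recovered essentially
exactly, the *pressure* read there from sampled data is resolution-limited,
and with it λ (to roughly 15–25 % on noise-free 2001-point curves). This is
an information limit of steep shoulders, not a detector defect; gentle
shoulders (λ ≈ 6–8) recover λ to within 5 %. Full-curve least-squares
refinement (`fit_isotherm()`, Levenberg–Marquardt on the pressure residuals)
does not suffer from this limit because it uses the whole curve; it recovers
(a₀, ξ, λ) to within 5 % from noisy synthetic data in the test suite.

The fit has genuine degeneracies inherited from the physics: at ξ = 1 the
pressure is independent of λ; the same curve family reappears as λ → −∞
(all molecules vertical) and, with only the product a₀ξ identifiable, as
λ → +∞ (all molecules horizontal). `fit_isotherm()` therefore probes the
sensitivity of the residual to λ at the solution and reports λ as
unidentifiable when the data cannot pin it down, rather than returning an
arbitrary number.

## Problem sizes

The test suite runs the solver oracle against 2×10⁵-point grid minimization
on 30 randomized parameter triples, sweeps closed-form equivalences over
5×5 parameter grids, detects landmarks on 200–2001-point synthetic curves,
and performs three Levenberg–Marquardt fits of 40–60-point curves; the whole
suite completes in a few minutes on one core. The acceptance script
recomputes the four case-study energies (single landmark evaluations) and
the ξ = 4 threshold (bisection over 2001-point grids).

## Known limitations

* Attractive inter-molecular interactions (and hence phase transitions and
  domain formation) are outside the model; isotherms dominated by them will
  produce biased λ estimates.
* The limiting area a₀ is user-supplied: automated extraction of the
  collapse area from raw curves is out of scope, mirroring how it is read
  off published figures by eye.
* Exactly two orientational states; multi-shoulder isotherms are not
  representable.
* λ absorbs every orientation-dependent contribution (conformational,
  hydrophobic, electrostatic); the model says nothing about its temperature
  dependence.
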