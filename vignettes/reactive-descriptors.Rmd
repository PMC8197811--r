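---
title: "Reactive descriptors for SN2 catalytic power: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactive descriptors for SN2 catalytic power: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catdesc)
```

## The problem

Haloalkane dehalogenase (DhlA) converts 1,2-dichloroethane (DCE) through an
SN2 step in which the Asp124 carboxylate — modelled as acetate, AcO⁻ —
attacks the substrate carbon C1 while chloride Cl1 leaves. How much of the
enzyme's rate acceleration comes from the aromatic residues lining the
active site (Trp125, Phe172, Trp175), and can that catalytic power be
captured by simple, transferable descriptors instead of a full barrier
calculation for every environment?

`catdesc` implements a descriptor-based answer. Given stationary-point
geometries and atomic partial charges for a series of environments (three,
two, one, zero residues, aqueous solution, ...), it computes two scalar
reactivity descriptors per environment, fits the linear descriptor–barrier
scaling across the series, and uses the fitted line to predict the barrier
of an environment held out of the fit.

## The two descriptors

**Distance difference.** At the transition state, let $d_l$ be the breaking
C1–Cl1 bond length and $d_f$ the forming O1–C1 bond length (both in Å).
The geometric descriptor is

$$D_\mathrm{cat} = d_l - d_f .$$

A larger $D_\mathrm{cat}$ marks a "later", more product-like TS — the
leaving bond already long, the forming bond already short — which in this
series goes hand in hand with a lower activation barrier. Both distances
are TS-internal quantities; no reactant-referenced variant is computed,
because the descriptor is defined as a property of the transition-state
geometry alone.

**Charge transfer.** Let $q_\mathrm{TS}$ and $q_\mathrm{RC}$ be the
nucleophile group charge — the sum of the signed atomic charges over the
nucleophile atom selection, in units of $e$ — at the transition state and
the reactant complex. The electronic descriptor is

$$Q_\mathrm{cat} = q_\mathrm{TS} - q_\mathrm{RC} .$$

As the reaction proceeds, negative charge flows from the nucleophile to the
leaving group; a larger $Q_\mathrm{cat}$ means more of that transfer is
already accomplished at the TS. The package is deliberately agnostic about
the population-analysis scheme behind the charges: they are ingested as
data, and the scheme name is carried only as metadata. A whole-fragment
charge (e.g. a tabulated CH₃CO₂ group value) can be supplied as a single
pseudo-atom row, which the group-sum reduces to correctly.

## The scaling model

Across a series of environments the barrier is modelled as a linear
function of one descriptor,

$$\Delta E^\ddagger = a\,x + b + \varepsilon,
  \qquad x \in \{D_\mathrm{cat},\, Q_\mathrm{cat}\},$$

fitted by unweighted ordinary least squares (`fit_scaling()`, an S3
`"scaling_fit"` object with the usual `coef`/`predict`/`plot`/`residuals`
methods backed by `stats::lm`). Free-energy barriers are the default
response; a config flag (`barrier_kind: potential_energy`) selects
potential-energy barriers instead. Environments flagged `role: predict` in
the series config are excluded from every fit and scored afterwards — this
is how the aqueous environment is treated: fitted on the residue series,
predicted for water.

Prediction (`predict_barrier()`) returns the standard error of prediction
for a new observation,
$s\sqrt{1 + 1/n + (x-\bar x)^2/S_{xx}}$, and *always* flags extrapolation
when the descriptor lies outside the fitted range. Extrapolation is
permitted — the water prediction is one — but never silent.

Design points worth stating explicitly:

* **Unweighted OLS.** Nothing in the ingested data supports weights, and
  with four points any robust alternative is underdetermined. On the
  bundled series the $Q_\mathrm{cat}$ line predicts a water barrier of
  about 23.5 kcal/mol; published descriptor-based estimates for this
  reaction quote ≈24.2 kcal/mol from a graphically fitted line, so
  agreement is at the ~1 kcal/mol level, not exact — the original fitting
  procedure behind such plots is typically unstated.
* **The $D_\mathrm{cat}$ line is fitted on three points** in the bundled
  series: the zero-residue TS geometry (and hence its distance descriptor)
  is not part of the tabulated data, so that environment contributes only
  its charges. A three-point extrapolation is fragile, and its water
  prediction (≈20.8 kcal/mol) should be read with the reported ≈0.55
  kcal/mol prediction SE and the extrapolation flag in mind.
* **Degenerate fits.** Two points give the exact interpolant; $r^2$ is then
  reported as 1 with a warning and the residual SE as 0, since no residual
  degrees of freedom remain. Identical descriptor values across the series
  are a hard error.

## Reaction paths on model surfaces

The descriptor pipeline consumes stationary points; the `neb` and `pes`
modules close the loop by showing how such points are obtained from a
potential-energy surface. Electronic-structure engines are out of scope, so
the path machinery runs on analytic 2-D surfaces — the smallest
dimensionality in which a first-order saddle (one negative Hessian
eigenvalue, the 2-D analogue of one imaginary vibrational frequency)
exists:

* `sn2`: a double-well surrogate
  $V = V_0(x^2-1)^2 + \mathrm{asym}\,x + \tfrac12 k\,(y-cx)^2$ with a
  closed-form symmetric limit (saddle exactly at the origin, barrier
  exactly $V_0$) used as the analytic ground truth in tests.
* `muller_brown`: the standard Müller–Brown benchmark with the
  literature-standard constants fixed as module constants. Its three minima
  and two saddles are located in the test suite by an *independent*
  dense-grid (400×400) + Newton oracle, never hard-coded as truth.

The band optimizer (`neb_optimize()`) uses the improved, energy-weighted
tangent (the standard remedy for kinked bands), nudging in the standard
form — spring force along the tangent only, true force perpendicular only,
no doubly-nudged variant — and a quenched-velocity FIRE-type minimizer with
a capped per-image step (plain steepest descent is available for
debugging). Climbing-image refinement activates only after the plain band
reaches 10× the force tolerance, so the climbing image never launches from
an unequilibrated band; once active, the highest image feels the full force
with its tangent component inverted and converges onto the saddle itself.
Endpoints are immutable throughout. Non-convergence within the iteration
budget is a flagged result, not an exception.

Numerical defaults, all surfaced in `neb_config()` and chosen here (no
external reference prescribes them): 12 images, spring constant 1, force
tolerance 10⁻³ (model units), FIRE time step 0.01, maximum step 0.05,
iteration budget 30 000 — the stiff Müller–Brown surface needs roughly
12–15 k iterations to reach the tolerance, and the budget leaves headroom.
Finite differences use step 10⁻⁵ for gradients and 10⁻⁴ for Hessians,
balancing truncation against round-off in double precision.
`relocate_endpoints()` reproduces the usual protocol of displacing the
saddle along its negative-curvature mode and quenching to the two adjacent
minima. The whole pipeline is deterministic; the config records a seed only
so that any randomized-restart strategy layered on top stays reproducible.

## The synthetic generator

`generate_record()`/`generate_series()` fabricate loadable series whose
descriptors are *exact* by construction: a collinear O–C–Cl transition
state with the forming distance fixed at 2.0 Å and the leaving distance at
$2.0 + D_\mathrm{cat}$, and RC/TS charge tables whose nucleophile group
sums differ by exactly $Q_\mathrm{cat}$ (RC group charge −0.94 $e$ by
default, the typical carboxylate value in this system). Only the barrier —
the genuinely uncertain quantity in a real series — carries noise,
Gaussian with user-set σ under a mandatory seed; σ = 0 reproduces the
prescribed barriers exactly and the emitted files byte-identically.
`charge_evolution()` models the charge flow along the normalized reaction
coordinate as a logistic rescaled to meet its endpoints exactly.

What the generator emulates: the statistical structure of a residue series
— prescribed descriptor spread, a linear descriptor–barrier law, barrier
noise. What it does not: chemical realism (no conformers, no real enzyme
pocket, three-atom geometries), correlated errors between descriptors and
barriers, or uncertainty in the descriptors themselves. Tests passing on
synthetic series therefore validate the *pipeline* — parsing, bookkeeping,
descriptor algebra, fitting, coverage of confidence intervals — not the
chemistry of any particular enzyme. The simulation scale used in the test
suite (50-environment series, 200 replicates for the 95 % CI coverage
check at σ = 0.5 kcal/mol) keeps the Monte Carlo error on coverage near
1.5 percentage points.

## Degenerate inputs and tie-breaks

* Descriptor ties in `reactivity_order()` are reported (warning + `ties`
  field) and void the monotonicity verdict rather than being silently
  ordered.
* An energy tie for the highest band image breaks toward the lowest index,
  with a warning.
* A band whose maximum sits on an endpoint has no interior barrier and
  `locate_ts()` refuses it.
* Charge tables may be missing at load time; the charge-transfer
  descriptor fails late, naming the record and the missing stationary
  point.
* Atom indices are 1-based everywhere a user sees them, following
  chemistry-file convention. Units are fixed — Å, $e$, kcal/mol — with no
  conversion layer.

## Known limitations

* The descriptors are computed from ingested geometries and charges; the
  package neither computes charges from wavefunctions nor validates that a
  supplied TS is a true saddle of any molecular Hamiltonian (that check
  exists only on the 2-D model surfaces).
* Single-descriptor fits only; no joint $D_\mathrm{cat}+Q_\mathrm{cat}$
  regression, no weighted or robust variants.
* The NEB stage is 2-D by design and does not do free-energy sampling
  along the band.
* Linear scaling is an empirical observation on a specific series; nothing
  guarantees transfer to environments far outside the fitted descriptor
  range, which is why every extrapolated prediction is flagged.
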