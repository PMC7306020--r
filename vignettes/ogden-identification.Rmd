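---
title: "Identifying Ogden constants for levator ani tissue and auditing childbirth-simulation inputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying Ogden constants for levator ani tissue and auditing childbirth-simulation inputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ogdenlam)
```

## Scope

Finite-element simulations of vaginal delivery need three desk-scale inputs
before any contact solve can run: constitutive constants for the levator ani
muscle (LAM), a tetrahedral mesh whose element quality will not poison the
solution, and a prescribed fetal-head trajectory. `ogdenlam` implements that
preprocessing pipeline end to end: it simulates and reduces uniaxial tensile
tests, identifies Ogden hyperelastic constants by constrained least squares,
summarizes specimen cohorts, audits tet meshes against standard acceptance
criteria, and tabulates station-indexed head trajectories for
occiput-posterior (OP) and occiput-anterior (OA) presentations.

The FEM solve itself — clinical-scale contact mechanics on a
several-hundred-thousand-element pelvic mesh — is out of scope; it requires
commercial explicit solvers and patient geometry this package does not
carry. What the package does guarantee is every computation feeding such a
solve, each validated against an independent oracle.

## The constitutive model

The LAM undergoes very large strains during delivery, so a hyperelastic
model in principal stretches is the natural choice. We use the N-term
Ogden strain-energy density in the *2μ/α prefactor convention*:

$$ W = \sum_{i=1}^{3}\sum_{j=1}^{N} \frac{2\mu_j}{\alpha_j}
  \left( (J^{-1/3}\lambda_i)^{\alpha_j} - 1 \right)
  + \frac{K}{2}(J-1)^2, \qquad J = \lambda_1\lambda_2\lambda_3 . $$

Two points about conventions deserve emphasis:

* **The prefactor is 2μ/α, not the classical μ/α.** Published constants are
  only meaningful in the convention they were fitted in; a silent
  conversion would double every modulus. `to_classical_ogden()` /
  `from_classical_ogden()` convert explicitly (classical μ = 2 × ours).
* **All stresses are MPa.** Tensile forces in newtons over initial areas in
  mm² give N/mm² ≡ MPa with no conversion constants, and passive muscle
  moduli in the kPa–MPa range are the physiologically plausible scale.
  Every CSV the package writes carries a units header for this reason.

Muscle is treated as exactly incompressible. On the uniaxial path
$\lambda_2=\lambda_3=\lambda^{-1/2}$, $J=1$, the volumetric penalty K
vanishes identically and the nominal (first Piola) stress has the closed
form

$$ P(\lambda) = \sum_j 2\mu_j\left(\lambda^{\alpha_j-1} -
   \lambda^{-\alpha_j/2-1}\right), $$

with $P(1)=0$ and initial tangent $3\sum_j\mu_j\alpha_j$. The tangent
identity is why the admissibility (stability) constraint is
$\sum_j\mu_j\alpha_j > 0$: it is a positive ground-state shear modulus. The
test suite verifies the closed form against central finite differences of
`strain_energy()` for 100 random stable parameter sets at four stretches to
better than $10^{-6}$ relative — the closed form is never trusted on faith.

N = 2 is the default: one low-exponent term carries the compliant toe
region, one high-exponent term the collagen-recruitment stiffening. After
fitting, terms are reported sorted by ascending α so "term 1" is always the
toe term.

### Numerical note

`strain_energy()` evaluates $\lambda^\alpha - 1$ as
`expm1(alpha * log(lambda))`. The naive power loses roughly
$\varepsilon/\alpha$ absolute accuracy once $\alpha\log\lambda$ is small
(the cohort contains α as small as 0.001), which is enough to break
$10^{-6}$-level finite-difference checks; `expm1` removes the cancellation.

## Tensile-test reduction

The emulated protocol is a uniaxial test on cuboid LAM samples (about
6 mm × 4 mm cross-section, 5 or 10 mm gauge length, fibers along the load
axis) at 6 mm/min crosshead speed until rupture, optionally preceded by 20
preconditioning cycles to 15 % strain. Reduction is deliberately simple and
exactly conventional:

* stress = force / **initial** cross-section (nominal, never current area);
* strain = elongation / initial gauge length; stretch = 1 + strain;
* when preconditioning cycles are present, only the final monotone loading
  ramp (the longest suffix with non-decreasing elongation) is reduced —
  that is the curve the identification uses;
* the curve is truncated at rupture.

Rupture truncation is a rule this package had to invent (the protocol only
records that extension continued until rupture): the curve is cut at the
first sample falling more than `drop_fraction` (default 20 %) below the
running stress maximum. On noisy data a relative rule is fragile where the
signal is near zero, so detection is *armed* only once the running maximum
exceeds `min_peak_fraction` (default 50 %) of the curve's overall peak —
rupture is, by definition, a collapse from the peak region. Both knobs are
exposed; at 2 % force noise the 50 % arming point leaves the detection
untouched by noise at better than 4σ.

## Parameter identification

`fit_ogden()` minimizes the unweighted stress error

$$ E = \tfrac12\sum_{i=1}^{ND}\left(P_i^{test} - P_i^{model}\right)^2 $$

over a bounded box by Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with the analytic residual Jacobian, restarted from
`n_multistarts` (default 32) log-uniform feasible points. The default
bounds, μ ∈ [10⁻⁶, 0.5] MPa and α ∈ [10⁻³, 50], bracket every value in the
packaged porcine cohort with at least 2× margin while keeping the whole
feasible box strictly positive — so the stability inequality holds
automatically at every candidate and no nonlinear constraint handling is
needed. Multistart initialization uses one RNG substream per start index,
which makes runs deterministic in `rng_seed` and *prefix-stable*: raising
`n_multistarts` can only improve the returned objective.

A caveat every user of Ogden fits should internalize: the parameters are
only **weakly identifiable from a single uniaxial curve**. Distinct
(μ, α) combinations predict nearly indistinguishable uniaxial stresses, so
fits must be judged by predicted-stress RMSE (`rmse_mpa`), not by parameter
agreement. The package demands parameter recovery only in the 1-term case
(where the test suite cross-checks the optimizer against a brute-force grid
search); for N = 2 the noiseless end-to-end criterion is an RMSE below
0.1 % of each specimen's peak stress. Biaxial or cross-fiber data would be
needed to pin the constants individually — the same reason an isotropic
model fitted from uniaxial data is itself an acknowledged simplification
for this fibrous muscle.

Cohort summaries report the per-parameter mean and **population** standard
deviation (divisor n), matching the convention of the published porcine
constants table that ships in `inst/extdata/` (`porcine_lam_parameters()`).
Two columns of that table's printed summary row are internally inconsistent
with their own columns (the μ₁ mean/SD appear swapped, and the printed α₂
mean does not recompute); the package reproduces the table verbatim and
checks its statistics only against the two columns (α₁, μ₂) that recompute
cleanly.

## Synthetic cohorts

`generate_cohort()` produces test cohorts with the structure of the porcine
experiment: 20 specimens (10 animals × 2 sides), geometry jittered around
6 × 4 × 10 mm (5 % relative SD on the caliper-measured cross-section),
6 mm/min loading sampled at 10 Hz, rupture stretch drawn uniformly from
(1.4, 2.0), additive Gaussian force noise with SD 0.5 % of peak force, and
ground truth taken row-by-row from the packaged constants table. Sampling
rate, rupture range and noise model are the generator's own choices —
realistic for a bench traction machine but not reported by any protocol —
and each is a `cohort_spec()` field.

What the generator emulates: the constant-velocity kinematics (elongation
≡ velocity × time, exactly), the nominal-stress forward model, rupture as a
force collapse (to 30 %, 10 %, 2 % of peak over three samples), optional
preconditioning cycles, and seed-deterministic noise. What it does not
emulate: viscoelastic rate dependence, anisotropy, grip slippage, tissue
dehydration, or any systematic (non-Gaussian) sensor error. Passing the
recovery tests therefore shows the estimator is correct *for the model
class that generated the data*; it cannot show that a two-term isotropic
Ogden law is adequate for real LAM tissue.

## Mesh quality audit

`audit_mesh()` evaluates, per four-node tetrahedron:

* **aspect ratio** — longest edge over the minimum vertex-to-opposite-face
  altitude ("minimum altitude of the smallest side" admits readings; this
  is the standard one in FE preprocessors). Regular tet: $\sqrt{3/2}$.
* **dihedral angles** — all six edge angles, closed form
  $\arccos(1/3) \approx 70.53^\circ$ for the regular tet.
* **scaled Jacobian** — minimum over corners of
  $\det(e_1,e_2,e_3)\sqrt{2}/(|e_1||e_2||e_3|)$. The $\sqrt2$ normalization
  makes the regular tet score exactly 1, which is what gives the 0.2 and
  0.7 magnitude thresholds meaning; sign encodes orientation.

Acceptance criteria (all overridable in `criteria =`): < 5 % of elements
with AR > 3; dihedrals within [30°, 120°]; edges within [1, 3] mm (so node
coordinates must be mm); Jacobians positive, none below 0.2, fewer than 5 %
below 0.7. Percentages are exact rational counts — no float drift can flip
a pass/fail flag. Degenerate elements report AR = ∞ and Jacobian 0 rather
than raising, so an audit of a broken mesh still completes and reports.

Legacy ASCII VTK and Gmsh MSH 2.2 readers are included (tet4 only, other
cell types rejected loudly); these formats are plain text and the parsers
are deliberately minimal.

## Head trajectory

`default_trajectory("OP")` ships a station-indexed waypoint table (station
in cm relative to the ischial-spine plane, negative above) with
component-wise linear interpolation between waypoints —
homogeneous linear progress is the standard simplification in numerical
childbirth models, so piecewise linearity *is* the contract.
The OP defaults anchor the numerically known features: 100.0 mm total
anterior displacement over the descent from station −3 to +8, internal
rotation from 45° at engagement to 0°, and 20° flexion at the midpelvis
waypoint, increasing toward the outlet. Where sources disagree on when OP
internal rotation completes (the ischial-spine plane vs. station +3), the
default follows the trajectory description (+3) and
`rotation_complete_station` is configurable. Intermediate waypoints are
neutral placeholders — the continuous published curves are not tabulated
anywhere — and the shipped JSON says so in its own comment field.

## The pipeline

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  out_dir = "run1",
  cohort  = cohort_spec(force_noise_rel = 0),  # noiseless recovery run
  fit     = fit_config(),
  rng_seed = 42)
res <- run_pipeline(cfg)
print(res$summary)
```

`run_pipeline()` chains simulate → reduce → fit → summarize, validating
every stage configuration before any stage runs, and writes specimen CSVs +
ground-truth manifest, curve CSVs, per-specimen fit JSONs, a cohort summary
CSV (per-specimen constants plus a mean / population-SD row) and a
`run_log.json` with the seed, an MD5 configuration hash and the package
version. Reruns with an identical configuration are byte-identical.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full 20-specimen
noiseless cohort (roughly 600–1000 samples per curve at 10 Hz) with 32
multistarts per fit, 100-parameter-set finite-difference sweeps, and
100-element mesh fixtures; property tests that need many fits (e.g. the
noise-monotonicity check over 10 seeds × 3 noise levels) drop to 6–8
multistarts, which is ample for a 4-parameter problem. Every random draw —
multistart points, geometry jitter, rupture stretch, force noise — flows
from explicit integer seeds through per-index substreams, so all reported
numbers are exactly reproducible.

## Known limitations

* Isotropic, purely elastic model fitted from uniaxial data: no fiber
  anisotropy, no viscoelasticity, no active contraction.
* Ogden constants from a single uniaxial curve are reported as sets, not as
  individually meaningful moduli (see identifiability above).
* The mesh audit checks element shape metrics only; it cannot certify that
  a mesh resolves the physics, and the published clinical-mesh statistics
  (e.g. its 1.19 % AR violation rate) are not reproducible without that
  mesh.
* Trajectory tables interpolate configured waypoints; they are kinematic
  inputs, not predictions of labor mechanics.
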