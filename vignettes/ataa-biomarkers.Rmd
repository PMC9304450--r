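---
title: "Methods: ATAA biomarkers from wall mechanics, lumped hemodynamics and censored regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ATAA biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ataamark)
```

## Scope and design

`ataamark` reproduces the analysis layer of a mouse ATAA biomarker study:
constitutive fitting of the ascending aortic wall, biomarker extraction
from wall-shear-stress (WSS) fields and vessel centerlines, lumped outlet
pressures, and censored regression of biomarkers against lifespan. The
parts of such a study that require imaging hardware or a 3D
fluid–structure interaction (FSI) solver — segmentation, meshing,
prestress, the Navier–Stokes solution itself — are out of scope; a
synthetic-data layer emulates their outputs with known ground truth, so
that every implemented stage has a recovery test. A green test therefore
establishes that each stage computes its quantity correctly on inputs of
the stated form, *not* that the surrogate reproduces solved physics.

## Wall model

The Holzapfel–Gasser–Ogden (HGO) energy combines a neo-Hookean matrix
with two dispersed fiber families at ±γ from the circumferential axis:

$$\Psi = \tfrac{c}{2}(I_1 - 3) + \sum_{i=1,2}\frac{k_1}{2k_2}
\left[e^{k_2\langle\kappa I_1 + (1-3\kappa)I_{4i} - 1\rangle^2} - 1\right].$$

Choices made where a study text is typically silent:

* **Incompressibility** is imposed by eliminating the radial stretch,
  $\lambda_r = 1/(\lambda_\theta\lambda_z)$, inside $I_1$ before
  differentiating. This is equivalent to the plane-stress condition
  $\sigma_r = 0$ with the pressure Lagrange multiplier removed, and gives
  closed-form biaxial stresses
  $\sigma_\theta = \lambda_\theta\,\partial\Psi/\partial\lambda_\theta$,
  $\sigma_z = \lambda_z\,\partial\Psi/\partial\lambda_z$ that the tests
  verify against central finite differences to 1e-6 relative.
* **Tension-only fibers**: the exponential term is active only when
  $\kappa I_1 + (1-3\kappa)I_4 - 1 > 0$, the standard convention for
  exponential fiber models; it is toggleable (`tension_only`).
* **Anisotropic coefficient**: the per-family factor is the standard
  $k_1/(2k_2)$. An alternative reading of compressed notation would
  double it; the choice only rescales the fitted $k_1$ and affects no
  derived biomarker.
* **Dispersion bound**: $\kappa \in [0, 1/3]$ by default (the classical
  admissibility bound for the generalized-structure-tensor model).
  Published cohort fits occasionally report $\kappa$ up to 0.41, so the
  bound is configurable through `upper` in `fit_hgo()`; a fit landing on
  the bound warns.
* **Fitting**: mean squared error over both stress components, all
  protocols pooled, minimized by L-BFGS-B from `n_starts` Latin-hypercube
  initial points inside the bounds, the three best starts polished by a
  tighter PORT (`nlminb`) run; ties broken toward smaller $k_2$. The
  multistart is seeded and therefore deterministic. The five parameters
  are *not* jointly identifiable from stress data in all regimes: the fit
  reports `start_spread`, the relative dispersion of near-optimal starts,
  as a non-identifiability diagnostic; c and k₁ are recovered to < 2%
  only when κ and γ are held fixed (tested).
* **Elastic modulus**: $E = c(1+\nu)$ with ν defaulting to the
  incompressible 0.5 (configurable); a rough stiffness summary, not used
  in any downstream computation.

## Hemodynamic biomarkers

**Windkessel.** Each outlet is a three-element RCR circuit,
$dp/dt + p/(R_dC) = Q(1 + R_p/R_d)/C + R_p\,dQ/dt$, integrated by the
A-stable implicit trapezoidal rule on the waveform's own (possibly
nonuniform) grid, with $dQ/dt$ from a periodic spline. Cycles repeat
until the cycle-to-cycle pressure change is below 0.1 Pa (default cap 10
cycles, matching common FSI practice of discarding transients). Two
invariants are tested: constant inflow settles at $p = Q(R_p+R_d)$, and
the cycle-mean pressure at periodicity equals $\bar Q(R_p+R_d)$ because
the capacitor carries no net charge over a closed cycle. The bundled
outlet parameters print compliance as mm³/Pa (physical compliance);
magnitudes follow the published table.

**Rheology.** Carreau–Yasuda with the plus-sign form
$\eta = \eta_\infty + (\eta_0-\eta_\infty)[1+(\lambda\dot\gamma)^a]^{(n-1)/a}$.
A printed minus-sign variant of this formula is non-physical (negative
base at $\lambda\dot\gamma > 1$) and is not implemented. Defaults:
η∞ = 2 cP, η₀ = 11 cP, λ = 1.5 s, a = 0.2, n = 0.71. The "average"
viscosity μ_avg = 3.35 cP used in Re is a configurable constant — the
shear-rate range it averages over is not specified in the source
material, so it is not recomputed.

**WSS statistics.** TAWSS is the per-node trapezoidal time average of
|τ|; OSI = ½(1 − |∫τ| / ∫|τ|) with the 0/0 case (a node with identically
zero WSS) defined as OSI = 0, i.e. "no oscillation". Field summaries
(min/mean/max, whole surface or per region) are unweighted by node by
default; area weights are optional because it is generally unstated
whether published summaries are area-weighted. Both statistics converge
at second order in the time step (tested on the cosine field, whose
TAWSS is $2\tau_0/\pi$ and OSI exactly ½).

**Dimensionless numbers.** $Re_{max} = \rho V_{max} D_{max}/\mu_{avg}$
with ρ = 1027 kg/m³. The Womersley number uses the radius convention,
$Wo = (d/2)\sqrt{2\pi\rho/(T\mu)}$. Note that with d = 2 mm and
T = 0.1 s this gives Wo ≈ 4.4, above the 1.1–2.3 range published for
murine cohorts; the published range corresponds to smaller effective
diameters (or longer periods) than that example, and since the source
material states neither its period nor which diameter enters Wo, the
formula is tested against arithmetic, not against the range.

## Geometry

ATI = (AL/GL − 1) × 100 with AL the summed segment lengths of the
centerline and GL the **endpoint-to-endpoint chord**. The alternative
reading of "straight-line length between centroids" — summing per-segment
chords — would make GL ≡ AL and ATI ≡ 0, so it is rejected. ATI is
invariant under rigid motion and uniform scaling (tested), and a
semicircular arch gives the analytic (π/2 − 1)·100 ≈ 57.1.

`centerline_from_masks()` replaces perpendicular-plane circle fitting
with per-axial-slice centroids and equivalent-area diameters
$2\sqrt{A/\pi}$ — adequate for the synthetic surrogate at MR-like
resolution (a voxelized tortuous tube recovers its analytic ATI within
5%), but a documented simplification for strongly oblique vessels.
Voxel convention: 0-based indices, voxel-center coordinates in mm.

## Censored lifespan regression

Lifespan is right-censored at 25 months (surviving mice euthanized). The
Tobit model $Y^* = X\beta + u$, $u \sim N(0,\sigma^2)$, observed as
$\min(Y^*, Y_{max})$, is fitted by direct maximum likelihood —
quasi-Newton on $(\beta, \log\sigma)$ from the OLS start — rather than
delegated to a survival package, so the estimator itself is under test;
`survival::survreg` serves as an independent oracle in the suite.

**Pseudo-r² convention.** Two conventions are implemented and the choice
matters. The McKelvey–Zavoina latent-variance ratio
$\sum(\hat Y - \bar{\hat Y})^2 / [\sum(\hat Y-\bar{\hat Y})^2 + N\hat\sigma^2]$
(`method = "latent"`) gives 0.325 on the bundled reference cohort's
ATI–lifespan pair. The squared Pearson correlation between the fitted
linear predictor and the observed (censored-coded) response
(`method = "correlation"`, the default) gives 0.207 → 0.21, which is the
value published for that cohort, and it shares the defining property
claimed for the "modified" statistic: it reduces exactly to the OLS r²
when nothing is censored. The default therefore follows the published
numbers; both conventions lie in [0, 1], are affine-invariant in the
predictor, and agree in the uncensored limit (all tested).

Correlation maps use the Tobit pseudo-r² for every cell involving
lifespan (always with lifespan as the dependent variable — a documented
asymmetry) and plain OLS r² for biomarker–biomarker cells, each signed by
the fitted slope. No multiple-testing correction is applied — none is
standard in this exploratory setting — but the map records the number of
regressions run.

## The synthetic world

The generators encode the study's stated conditions once; they are not
tuned to tests.

* `gen_biaxial()`: the six myograph protocols — inflation 0–175 mmHg at
  axial stretches 1.3/1.4/1.5, extension 1.3–1.5 at 50/100/150 mmHg —
  with the circumferential stretch solved from thin-wall (Laplace)
  equilibrium, truth parameters at the cohort means (c = 1.77 MPa,
  k₁ = 0.43 MPa, k₂ = 2.01, κ = 0.17, γ = 44.95°), unloaded geometry
  1.2 mm outer diameter × 0.142 mm thickness (cohort-typical), and 5 kPa
  stress noise as the default noisy condition.
* `gen_wss_field()`: per-node
  $\tau(t) = A[((1-f) + f\cos\omega t)\hat e_1 + g\sin\omega t\,\hat e_2]$
  on a tubular mesh. The regional profiles (low-amplitude,
  near-unidirectional shear in the ascending region; strong oscillation
  in the descending region) encode the study's qualitative FSI findings
  as configuration, **not** solved physics, and were calibrated once so
  the default summaries land inside the published cohort ranges
  (OSI_mean 0.17–0.38, TAWSS_max 6.1–11 Pa, etc.). Sidecar truth uses
  4096-point quadrature of the continuous field — independent of the
  emitted time sampling; exact closed forms exist only for the pure
  cases (f = 0 → TAWSS = A, OSI = 0; f = 1, g = 0 → TAWSS = 2A/π,
  OSI = ½), which are asserted exactly.
* `gen_vessel()`: a sinusoidally perturbed centerline (default amplitude
  1.9 mm over 20 mm, giving ATI ≈ 37, mid-cohort) with a Gaussian
  aneurysmal bulge (default peak 3.0 mm over a 1.2 mm base). Sidecar
  truth from a 20001-point sampling of the continuous curve.
* `gen_inflow()`: a C¹ half-cycle $\sin^2$ ejection, period 0.1 s
  (murine ≈ 600 bpm; the period is not stated in the source material and
  0.1 s is the field's standard round number), peak 1500 mm³/s and
  systole fraction 0.35, i.e. stroke volume ≈ 26 µL and mean flow
  ≈ 16 mL/min — textbook murine values.
* `gen_cohort()`: six-month biomarkers uniform within the published
  ranges; lifespan $LS^* = \beta_0 + \beta_1 x + \epsilon$ censored at
  25 months. Defaults β₀ = 2, β₁ = 60 on OSI_mean, σ = 2.5 months span
  the published lifespan range (12.4–25) with a plausible censored
  fraction at n = 10. The two-month values subtract a change drawn
  within the published Δ ranges, truncated so earlier values stay above
  the published minima.

Same seed ⇒ identical output (tested with `identical()`); every
generator attaches a machine-readable ground-truth sidecar
(`write_truth_sidecar()` serializes it to `<output>.truth.json`).

What the generators deliberately do **not** emulate: spatial WSS
correlation from real flow, image noise and segmentation artifacts, sex
effects, mouse-to-mouse covariance between biomarkers (columns are drawn
independently, so generated biomarker–biomarker correlations are null by
construction).

## Sensitivity harness

The study design perturbs the wall moduli (c, k₁ at ×0.5, ×0.75, ×1.25,
×1.5) and swaps Carreau–Yasuda for Newtonian rheology inside the FSI
model. Without the solver, `run_sensitivity()` applies a transparent
thin-wall surrogate: effective stiffness $E_{eff} = c(1+\nu) + k_1$ sets
a diameter factor $d_f = 1 + \phi(E_{eff}^{base}/E_{eff} - 1)$ (φ = 0.1
by default), WSS scales as $d_f^{-3}$ (Poiseuille), peak velocity as
$d_f^{-2}$. This reproduces the harness structure and normalization
(values divided by the factor-1 baseline) and the closed-form rheology
ratios on Re (μ ratio) and Wo (√μ ratio), but **not** the magnitudes a
3D solution would give — those are solver-dependent and are not claimed.

## Numerical choices and edge cases

* Trapezoidal quadrature everywhere a time integral appears; nonuniform
  grids supported.
* Tobit optimization: BFGS, relative tolerance 1e-12, OLS start;
  all-censored or constant-predictor inputs error; non-convergence is
  reported, not thrown.
* OSI is clamped to [0, 0.5] against floating-point drift.
* `geometric_length()` warns when the endpoints nearly coincide;
  `tortuosity_index()` errors on a degenerate (closed) centerline.
* Exponents in the HGO fiber term are capped at 700 so optimizer
  excursions return large finite values instead of NaN (0·∞) at extreme
  corners of the search box.
* Units: MPa for wall stress, Pa for WSS/pressure traces, mm/s/mm³
  elsewhere; mmHg and cP converted at I/O (1 mmHg = 133.322 Pa).

## Known limitations

* The headline FSI-derived correlations of the motivating study design
  (e.g. OSI_mean–lifespan r² ≈ 0.70) require the per-subject solver
  outputs, which are not published; they are replaced here by
  property-based and recovery tests, not reproduced.
* The mask-stack centerline extractor assumes near-axial vessels.
* The sensitivity surrogate is a stand-in for solved fluid–structure
  coupling; only its structure and rheology ratios are meaningful.
* Univariate regressions only in the reproduction path (multivariate
  Tobit is fitted by the same likelihood but is not exercised by the
  pipeline), and n = 10 cohorts make every correlation fragile — the
  package reports the number of tests rather than correcting for them.
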