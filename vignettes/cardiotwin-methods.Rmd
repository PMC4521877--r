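---
title: "cardiotwin: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cardiotwin: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardiotwin` is a desk-scale simulator of failing-heart physiology: a
synthetic bi-ventricular anatomy with rule-based fibers carries a monodomain
electrophysiology model whose activation drives a co-rotational
finite-element mechanics model loaded by lumped hemodynamics. Around the
forward models sit the inverse loops that fit the model to clinical-style
measurements, and a virtual-cohort layer that emulates a heart-failure study
population for the statistics pipeline. This vignette documents the models,
their assumptions, the tunable parameters and the numerical and design
choices, in the order the pipeline runs.

## Synthetic anatomy

Image-derived anatomies require segmentation pipelines and patient data;
`build_biventricular_mesh()` instead generates a parametric stand-in that
preserves everything the downstream solvers consume: a truncated-ellipsoid
LV shell (endocardial semi-axes plus a constant wall thickness, default
10 mm), fused with a crescent-shaped RV free wall built by offsetting the
LV epicardium outward over an angular sector and thickening it by a constant
3 mm — the standard assumption when the RV epicardium cannot be resolved.
The base is an open plane orthogonal to the long axis; the four
valve-annulus node sets are rings on that plane (their real geometry is not
modelled; they exist to anchor the basal springs). The LV outflow tract and
RV inflow/outflow tracts are deliberately omitted rather than guessed.

Hexahedral/prismatic structured cells are tetrahedralized by splitting each
quadrilateral face along the diagonal through its smallest global node index
(shared faces therefore split identically on both sides) and fanning the
face triangles to a cell-centroid node. The mesh is conforming by
construction at the cost of ~12 tets per hex; resolution is set by a target
edge length (default 8 mm, giving meshes of a few thousand tets). An
optional seeded jitter perturbs interior (centroid) nodes only, so surfaces
and labels are untouched.

The transmural coordinate (0 = epicardium, 1 = endocardium) solves a Laplace
problem with Dirichlet data on the labeled surfaces. The septum has
endocardium on both sides; we assign the RV-facing septal surface the
epicardial value 0, so the septal wall carries a full 0→1 gradient and
follows the LV fiber rule — the common convention for rule-based fibers,
and well-defined where two endocardial surfaces compete. The thin
(default 1 mm) sub-endocardial fast-conduction layer mimicking the Purkinje
system is tagged by exact element-centroid-to-surface distance; elements
near the RV-facing septal surface belong to the RV layer.

Chamber volumes use the divergence theorem over the endocardial surface
with a planar fan cap at the base, in ml; the measure is invariant to rigid
motion and node ordering, and converges under refinement (tested < 1%
between successive levels on a closed ellipsoid).

## Fibers

The elevation angle of the fiber above the local circumferential direction
is linear in transmural depth: −60° (epi) → 0° (mid-wall) → +60° (endo) in
the LV, −80° → +80° in the RV (passing through 0° at mid-wall, which the
linear law implies). The local frame is circumferential = long axis ×
transmural gradient, with the longitudinal direction completing the triad;
at the apex the frame degenerates (transmural gradient parallel to the long
axis) and a horizontal fallback direction is used, counted and reported in
`n_degenerate`. Sheet directions are not generated — no model component
here uses them.

## Electrophysiology

The two-variable Mitchell–Schaeffer cell model (normalized potential `u`,
recovery gate `h`; parameters `tau_in` 0.3 ms, `tau_out` 6 ms, `tau_open`
120 ms, `u_gate` 0.13 at their standard values, `tau_close` personalized)
is diffused through the monodomain equation. The action potential duration
is approximately `tau_close * log(tau_out / (4 tau_in))`; this closed form
is asymptotic in the time-scale separation `tau_close >> tau_out`, so the
package's tests verify it in that regime (`tau_close` = 300 ms) and verify
the *slope* of APD against `tau_close` at the default range — the slope is
also what the QT personalization step uses, so it is the quantity that has
to be right.

Conductivities are stated in mm²/s and scale the diffusion tensor
`D = c (f f' + (1/r)(I − f f'))`; `c` is the along-fiber diffusivity of the
normalized equation, not an ionic conductivity, and conduction velocity
scales as √c. The anisotropy ratio defaults to 9 (fiber speed three times
cross-fiber). Three tissue classes exist: bulk myocardium (`c_myo`, cohort
mean 413 mm²/s), and the LV/RV fast layers (`c_lv`, `c_rv`, defaults 1600
and 2200 mm²/s — the one printed personalized case; the fast layer shares
the bulk anisotropy ratio). Activation starts at the upper third of both
septal endocardial surfaces (His-bundle surrogate; the exact entry points
are configuration, not anatomy).

Numerics: operator splitting with the explicit reaction step (stability
bound `dt <= tau_in / 3`, violated with an informative error) and implicit
lumped-mass P1 diffusion (one sparse Cholesky factorization per parameter
set), no-flux boundaries, default `dt` 0.1 ms. The original work used a
Lattice–Boltzmann solver; the contract here is the PDE solution, not the
scheme, and the tests (plane-wave speeds, √D scaling, anisotropy ratio)
check exactly that. Activation time is the first upward crossing of
u = 0.5; repolarization the last downward crossing of 0.5, chosen for
consistency between APD and the QT interval.

Pacing protocols for resynchronization therapy place lead node sets at the
nearest mesh nodes to given coordinates (defaults: LV lateral epicardium,
RV endocardial apex): biventricular (LV first, RV after 20 ms), RV-only,
and an LV-triggered mode that adds an LV stimulus on top of native
conduction after a sensing delay.

## Pseudo-ECG and features

Electrode potentials are infinite-homogeneous-medium lead-field integrals
of the diffusion current, `phi(e) = −Σ vol (D ∇u) · ∇(1/|x_e − x|)`; global
features (QRS duration, QT duration, electrical axis) are only weakly
sensitive to torso heterogeneity, which justifies the simple forward model
as the default. The torso is a parametric ellipsoid scaled around the
heart, with the ten standard electrodes at fixed fractional surface
positions and the apex pointing left–inferior–anterior. The 12 leads follow
Einthoven/Goldberger/Wilson algebra, so I + III = II holds to machine
precision.

Feature extraction has no canonical definition; the package uses the RMS
temporal-derivative envelope across leads with a threshold of 5% of its
peak (configurable): QRS onset is the first crossing, QRS offset the start
of the first sustained (40 ms) quiet gap, T-wave end the last crossing.
The electrical axis is `atan2(net aVF area, net lead-I area)` over the QRS
window — degrees, 0° along lead I, positive toward aVF (clinical
convention). These are stated conventions of this implementation, not
reconstructions of any particular clinical algorithm; features are
invariant to amplitude scaling and time shifts by construction. T-wave
morphology is explicitly not a fidelity target — only its timing enters
(via the QT interval).

## Biomechanics

A two-element Hill arrangement, interpreted as: isotropic linear-elastic
passive tissue (Young's modulus `E`, cohort mean 590 kPa; Poisson ratio
0.48 for near-incompressibility) in parallel with an active fiber stress.
The passive element is evaluated co-rotationally — each tetrahedron's
rotation is extracted by polar decomposition of its deformation gradient
and the linear stiffness acts in the rotated frame — so large rotations
produce no spurious force (tested to 1e-8 relative). The active stress is
zero before local activation, rises exponentially toward `sigma0` (cohort
mean 295 kPa) at rate `k_atp` (default 0.02/ms), and decays
value-continuously at rate `k_rs` (default 0.03/ms) after local
repolarization; timing comes per element from the EP activation and
repolarization maps. The published active-force model carries more
internal state; this rise/plateau/decay law is the minimal concrete form
preserving the three parameters and their roles. The heart is held by
one-sided penalty springs toward the end-diastolic epicardial bag
(pericardium surrogate) and by basal springs at the valve-annulus rings.

Time integration is explicit (semi-implicit Euler with mass-proportional
damping). Two numerical parameters deserve honesty: the density default
(0.4 g/mm³) is mass-scaled well above the physical value to lift the
stable time step to 0.25 ms, and the damping rate (0.25/ms) sets how
tightly the quasi-static response is tracked. Stroke volume still varies
by a few per cent across reasonable damping choices; the defaults were
fixed once, before the self-consistency tests were written, and all
recovery tests are run at matched settings, so the personalization
contract is unaffected. Solver divergence (element inversion under extreme
active stress) is an error with diagnostics; the optimizers treat it as a
penalized objective value.

## Hemodynamics and the coupled beat

Each ventricle sees a 3-element Windkessel afterload (compliance C,
peripheral resistance Rp, characteristic resistance Rc, remote pressure
Pr; aortic defaults 2269 mm³/mmHg, 3.64e-4, 4.72e-5 mmHg·s/mm³, 52 mmHg
and pulmonary analogues — the printed population means). The printed
resistance unit omits time; flows in mm³/s (seconds) are the only
convention that closes the ODE dimensionally, and all code uses it.
Preload is a constant atrial pressure plus a timed half-sinusoid bump — a
surrogate for the published lumped atrial model whose details are not
reproduced here. There is no closed-loop circulation and the ventricles
are not hemodynamically connected (they are mechanically coupled through
the septum).

The four phases are resolved per step: during filling the atrial pressure
is applied; the transition to isovolumetric contraction occurs when the
pressure that would hold the current volume exceeds the atrial pressure;
isovolumetric phases use a prediction–correction pressure — within a step
the trial displacement is affine in the applied pressure, so the
isovolumetric pressure solves a linear equation, with one correction
iteration against the true (nonlinear) cavity volume; ejection couples the
same affine volume response implicitly to the semi-implicit Windkessel
update (again a scalar linear solve), and ends when forward flow would
reverse. Volume drift within isovolumetric segments stays below 1% of
stroke volume in the tests, and ejected flow integrates to the stroke
volume to 1%. `isovolumetric_pressure()` exposes the same constraint as a
bracketed root find for direct use.

## Personalization

Three loops, all using derivative-free local optimizers (Brent's method
and Nelder–Mead; the original work used a NEWUOA-class optimizer — the
contract is "derivative-free with bounds", which any such method
satisfies):

* **Electrophysiology** (three steps, iterated): bulk conductivity from
  the QRS duration (scalar search on log c_myo; QRSd is monotone
  decreasing in conductivity, asserted as a sanity sweep in the tests);
  LV/RV fast-layer conductivities from the electrical axis (2-D
  Nelder–Mead on the *absolute* circular EA error — whether a signed error
  was used originally is unstated, and the absolute error is the choice
  made here); `tau_close` directly from the QT residual divided by the
  closed-form APD slope. Convergence tolerances default to 5 ms (QRSd) and
  10° (EA), with at most 5 outer iterations; self-consistent synthetic
  targets converge in 2–3.
* **Windkessel**: least-squares fit of the simulated proximal pressure to
  measured samples, initialized from the mean-pressure identity
  Rp + Rc = (mean p − Pr)/mean Q.
* **Mechanics**: (E, sigma0) by Nelder–Mead on the sum of squared
  residuals of EF, SV, EDV, ESV, EDP, ESP, each normalized by its measured
  value with unit weights (weights are configurable; none are prescribed).
  Missing targets are dropped from the objective and flagged.

## Virtual cohort and statistics

`sample_cohort()` draws model parameters from truncated normal priors
centred on the published population statistics (c_myo 413 ± 232 mm²/s,
E 590 ± 135 kPa, sigma0 295 ± 100 kPa, the Windkessel table rows); the
distribution *shape* is not published (only histograms), and truncated
normal is the choice made here, with truncation bounds wide enough to
matter only in the tails. One bound is a genuine numerical support limit
rather than a tail cut: below roughly c_myo = 150 mm²/s the depolarization
front (fractions of a millimetre wide) can no longer be carried by
desk-scale meshes and the discrete wave blocks, so the prior truncates
there; the excluded tail corresponds to conduction slower than anything
the generating population's QRS durations imply. Covariates — an NT-proBNP-like biomarker
(log-normal, matching the heavily skewed printed mean ± SD), heart rate,
systolic pressures at rest and after exercise, and a bounded outcome score
— are *statistical surrogates*, not biophysical outputs: they are drawn
through a one-factor Gaussian copula anchored on sigma0 with configurable
effect sizes (defaults −0.5, −0.5, +0.5, +0.5, and +0.77 for the outcome
score). The exercise-pressure marginal (165 ± 25 mmHg) is not published
and was chosen once as a plausible value. Observations come from the
actual forward models on a per-patient scaled anatomy, plus seeded
Gaussian noise with configurable SDs.

What passing tests show — and what they do not: the cohort layer
demonstrates that the *pipeline* (generation → forward simulation →
personalization → correlation/outlier statistics) recovers known ground
truth at realistic effect sizes and sample sizes (n = 39–46). It does not
validate the priors against real patients, and real cohort values are used
only as generator settings, never as reproduction targets.

The statistics layer implements sample Pearson correlation with the exact
t-transform p-value, the Grubbs single-outlier test from the
max-studentized-deviate formula (at most one outlier per call), and
mean ± SD summaries with the sample (n−1) SD. Calibration tests check the
type-I error of both tests against the nominal level by seeded simulation.

## Problem sizes and runtimes

The package targets interactive desk-scale use: default anatomies of
5–8k tetrahedra solve a full EP beat in ~1–2 s and a coupled mechanical
beat in ~5 s; the test suite uses meshes of 1–8k tets, slabs of up to
~3k nodes for conduction-velocity studies, and 10-patient cohorts for the
personalization study, chosen as the smallest sizes at which the
asymptotic behaviours under test (CV ratios, √D scaling, recovery
correlations) are comfortably resolved.

## Known limitations

* Linear isotropic passive tissue; real myocardium is orthotropic and
  hyper-elastic. Regional (per-segment) parameters are not estimated; all
  fits are global.
* The synthetic anatomy omits outflow/inflow tracts and papillary
  structure; the RV is a thin crescent with modest stroke volumes.
* The atrial model is a two-parameter surrogate.
* T-wave morphology is out of scope; only global ECG features are
  meaningful.
* The explicit mechanics uses mass scaling; absolute stroke volumes carry
  a numerical-viscosity dependence of a few per cent (self-consistency and
  monotonicity are unaffected).
* EA fitting can be weakly identified when the axis is insensitive to the
  endocardial conductivities; the loop then converges by tolerance rather
  than by sharp recovery of (c_lv, c_rv).
* The (E, sigma0) inverse problem is rank-deficient: because the mesh is
  the end-diastolic reference, passive filling is small and EDV carries
  almost no stiffness information, so the global targets constrain mostly
  one combination of the pair. Fits reproduce EF/SV essentially exactly
  while individual parameter recovery saturates (sigma0-truth correlation
  ~0.85 on noiseless cohorts); parameter non-uniqueness of this kind is a
  recognized property of globally personalized cardiac models.
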