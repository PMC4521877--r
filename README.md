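# cardiotwin

A desk-scale, personalizable multi-scale simulator of the failing human
heart, for computational-cardiology work on model personalization and
virtual cohorts: synthetic bi-ventricular anatomy with rule-based fibers,
monodomain Mitchell–Schaeffer electrophysiology with fast sub-endocardial
conduction layers, 12-lead pseudo-ECG synthesis, co-rotational
finite-element biomechanics coupled to 3-element Windkessel hemodynamics
with four-phase valve logic, inverse-problem loops that fit the model to
clinical-style targets, cardiac-resynchronization pacing protocols, and a
virtual-cohort generator with a small statistics pipeline.

## The models in brief

* **Electrophysiology** — monodomain reaction–diffusion for the normalized
  transmembrane potential *u* with the two-variable Mitchell–Schaeffer
  kinetics: du/dt = h u²(1−u)/τ_in − u/τ_out + J_stim, dh/dt = (1−h)/τ_open
  below the gate, −h/τ_close above it. The diffusion tensor is
  D = c (f fᵀ + (I − f fᵀ)/r) with along-fiber diffusivity *c* per tissue
  class (bulk c_Myo, LV/RV fast layers c_LV, c_RV) and anisotropy ratio
  r = 9 (fiber conduction three times faster than cross-fiber). APD ≈
  τ_close · ln(τ_out / 4 τ_in) links τ_close to the QT interval.
* **ECG** — infinite-medium lead fields φ(e) = −Σ vol (D∇u)·∇(1/‖x_e−x‖)
  on an ellipsoidal torso with the 10 standard electrodes; features QRSd,
  QTd and the frontal-plane electrical axis EA = atan2(∫aVF, ∫I).
* **Mechanics** — two-element Hill tissue: isotropic linear elasticity
  (E, ν = 0.48) in a per-element co-rotational frame, in parallel with an
  active fiber stress rising exponentially to σ₀ (rate k_ATP) after local
  activation and released (rate k_RS) after local repolarization;
  pericardial penalty bag and valve-annulus springs anchor the heart.
* **Hemodynamics** — per ventricle: atrial preload, isovolumetric
  prediction–correction pressures, and a 3-element Windkessel afterload
  C dp/dt = Q − (p − Pr)/Rp, p_prox = p + Rc Q, giving
  pressure–volume loops and EF/SV/EDV/ESV/EDP/ESP.
* **Personalization** — derivative-free loops: c_Myo from QRSd, (c_LV,
  c_RV) from EA, τ_close directly from QT (iterated, typically 2–3
  passes); Windkessel from pressure/flow curves; (E, σ₀) from global
  function.
* **Virtual cohort** — truncated-normal priors on all personalized
  parameters (e.g. c_Myo 413 ± 232 mm²/s, E 590 ± 135 kPa, σ₀ 295 ± 100
  kPa), covariates drawn through a one-factor Gaussian copula with
  configurable correlations to σ₀, observations from the forward models
  plus seeded noise; Pearson-with-p, Grubbs outlier test and cohort
  summaries on top.

See `vignettes/cardiotwin-methods.Rmd` for assumptions, units, numerical
choices and limitations.

## Worked example

```r
library(cardiotwin)

mesh   <- build_biventricular_mesh(anatomy_config(edge_length = 12))
fibers <- generate_fibers(mesh)
mesh
#> bv_mesh: 900 nodes, 4072 tets, 834 boundary facets
chamber_volume(mesh, "LV")   # end-diastolic-ish cavity volume, ml
#> [1] 128.3515

ep    <- ep_parameters()      # c_myo 413, c_lv 1600, c_rv 2200 mm^2/s
sol   <- simulate_ep(mesh, fibers, ep, sinus_protocol(mesh),
                     duration = 450, dt = 0.1)
torso <- build_torso(mesh)
extract_features(compute_ecg(sol, mesh, fibers, ep, torso))
#> QRSd: 211 ms  QTd: 441 ms  EA: 23.1 deg

beat <- simulate_beat(mesh, fibers, sol, mech_parameters(),
                      hemo_parameters(), early_stop = TRUE)
beat
#> beat_result: 1887 steps
#>   LV: EDV 128.7  ESV 79.7  SV 49.0 ml  EF 38.1%  EDP 8.0  ESP 85.3 mmHg
#>   RV: EDV 30.1  ESV 26.2  SV 3.9 ml  EF 12.9%
```

The QRS is wide and the ejection fraction reduced — the defaults describe
a dilated failing ventricle at the population-mean electrical and
mechanical parameters. Personalization inverts this direction: given
measured QRSd/EA/QT the EP loop recovers the conductivities
(`personalize_ep`), given pressure and flow curves the Windkessel constants
(`personalize_windkessel`), and given EF/SV/volumes/pressures the stiffness
and active force (`personalize_mechanics`). `sample_cohort()` draws whole
virtual populations and `run_pipeline()` orchestrates
mesh → fibers → EP → ECG → beat → cohort runs from a YAML config (see
`exec/cardiotwin` for the command-line entry points).

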