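---
title: "Photonic-force stimulation of hair bundles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photonic-force stimulation of hair bundles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`photonforce` models how a focused light beam exerts force on an inner-ear
hair bundle and how the resulting displacement traces are analysed. This
vignette records the models, their assumptions, the parameter choices, and
the numerical decisions, in the spirit of a methods section: everything a
user needs to judge what the package computes and what its validation does
and does not show.

## 1. Photon-momentum force at an interface

A photon beam of power `Pwr` travelling in a medium of refractive index `n`
carries momentum flux `n·Pwr/c`. A perfect reflector intercepting the beam
at angle θ from its surface normal therefore feels

F = 2 · Pwr · cos θ · n / c,

and a perfect absorber half of that, since the absorbed photon delivers
only its incoming momentum while the reflected one also recoils. The
time-averaged radiation pressure on an illuminated area A is
P = 2 (Pwr/A) cos²θ / (c/n) for reflection (one cos θ from the momentum
geometry, one from the beam's footprint). With 10 mW at θ = 20° in
physiological solution (n = 1.33) the reflector bound is 83.4 pN — quoted
as 80 pN at one significant figure. This is an upper limit: stereocilia
are weak reflectors, and the in-text worked example fixes θ at the
apparatus's 20° approach angle.

Two bookkeeping decisions matter here:

* **Medium momentum.** We use the medium-scaled (Minkowski) photon
  momentum `n·P/c` throughout, consistent with the "light speed is c/n"
  treatment of force estimates in water. All momentum-balance identities
  in the ray tracer are stated and tested in this convention.
* **Rounding.** Worked-example reports round to the printed precision
  (one significant figure for piconewton forces, two for refractive
  indices, nearest degree for angles) through `report_sigfig()`, never
  inside the physics.

## 2. Fresnel coefficients and the Gladstone–Dale index

`fresnel_amplitudes()` evaluates the amplitude coefficients for unit
incident amplitude in the standard form where, at the water→stereocilium
interface (1.33 → 1.4, θ = 20°), r∥ = +0.022, r⊥ = −0.029,
t∥ = t⊥ = 0.971. The perpendicular amplitude is genuinely negative for
this medium ordering; the signed value is preserved internally and
magnitudes appear in printed summaries. Energy conservation holds
analytically per polarization,

r² + t² · (n₂ cos θ_T)/(n₁ cos θ_I) = 1,

and is asserted to 10⁻¹² in the tests, along with the Brewster-angle zero
of r∥ and the normal-incidence symmetry |r| = (n₂−n₁)/(n₂+n₁).

In the total-internal-reflection regime no real transmission angle exists:
`snell_angle()` returns a distinguished TIR marker (`is_tir()`) rather than
a number, and `fresnel_amplitudes()` refuses with an error directing the
caller to the TIR branch. The critical angle for stereociliary cytoplasm
against water, arcsin(1.33/1.4) = 71.8°, rounds to 72°.

The stereociliary index itself comes from the Gladstone–Dale mixing rule
n = n₀ + α·ρ with solvent index n₀ = 1.33, protein refractive increment
α, and protein concentration ρ = 250 kg·m⁻³. The conventional protein
increment is 0.2 mL·g⁻¹ = 2.0×10⁻⁴ m³·kg⁻¹, which gives n = 1.38 ≈ 1.4;
a frequently reprinted variant of this constant carries dimensionally
inconsistent units (it would imply n ≈ 5×10⁴), so the package documents
and defaults to the consistent value.

One published-figure discrepancy is deliberately not reproduced: scaling
the 30-mW flat-interface estimate (0.05% reflected, 0.015 mW) by the
reflection formula gives ≈0.13 pN, not the 0.45 pN sometimes quoted; the
package computes the former and treats the latter as unrecoverable from
the stated constants.

## 3. Ray tracing on a cylinder cross-section

The flat-interface numbers above imply negligible force, yet bundles move;
the resolution is stereociliary curvature. `trace_ray()` works in the 2-D
cross-section plane of a dielectric cylinder (radius 0.25 μm, n = 1.4
inside, 1.33 outside; propagation +x, transverse +y, cylinder axis z). A
ray at impact parameter b strikes the front surface at local incidence
φ = arcsin(|b|/r) and splits by squared Fresnel coefficients — power, not
amplitude, is partitioned, so coherent interference between branches is
excluded (stereocilia in a bundle likely act as a grating with genuine
interference effects; that wave-optics regime is out of scope, as is the
fact that the 0.5-μm diameter is comparable to the wavelength, which makes
geometric optics qualitative here).

Chord geometry makes every internal wall hit occur at the entry refraction
angle θ_T. Since sin θ_T = (n₁/n₂)·sin φ ≤ n₁/n₂ = sin θ_c, an externally
incident ray reaches the critical angle only in the grazing limit
|b| → r: sustained total internal reflection of external light is a
limiting idealisation, and `regime_map()` reports zero `tir_chain`
fraction on any finite grid. The trapped-ray scenario is still available
through `inject_internal_ray()`, which starts a ray on the inner wall at a
chosen angle; at or beyond 72° it reflects indefinitely (terminating at
the bounce cap), each bounce depositing momentum.

Numerical decisions:

* **Branch tracking.** At each wall hit the transmitted share exits and is
  recorded; only the internally reflected branch continues. Defaults
  `max_internal_bounces = 10` and `power_cutoff_fraction = 10⁻⁴` cover the
  few successive reflections a trapped ray exhibits; near-grazing rays can
  be traced to the cutoff by raising the bounce cap.
* **Per-event momentum.** Each event transfers
  `(P/c)(n_in·d_in − n_out·d_out)`; summed over a path this telescopes to
  incident minus exiting momentum flux, which the tests verify as an
  independent oracle computed from the exit rays alone, to within the
  cutoff-truncation bound.
* **Quadrature.** `beam_force_on_cylinder()` integrates over impact
  parameters with the substitution b = r·sin ψ, ψ uniform. The Fresnel
  reflectance has a square-root cusp at grazing incidence that defeats a
  uniform-in-b midpoint rule; the graded grid restores second-order,
  monotone convergence (1001 vs 16001 rays agree to ~2×10⁻⁷ relative).
* **Polarization naming.** `"parallel"`/`"perpendicular"` refer to the
  plane of incidence, which here is the cross-section plane. An electric
  field along the cylinder's long axis — the preferred alignment for
  bundle stimulation, given stereociliary birefringence — is therefore
  the `"perpendicular"` case, and the tracer's default.

There are no published force-versus-impact-parameter values to compare
against, so the tracer is validated by conservation laws (power exactly;
momentum to the cutoff bound), symmetry (transverse antisymmetry in b;
zero force for matched indices), bounds (never exceeding the 2nP/c mirror
limit), and quadrature refinement — not by printed numbers.

## 4. Beam geometry

The lensed fiber tip is modelled as a straight cone: spot diameter
D(d) = D_tip + 2·d·tan(α/2). The ~11° divergence measured in water is
interpreted as the **full** cone angle (half-angle 5.5°) — the
measurement itself does not specify which, so both interpretations are
exposed via `half_angle =`. Irradiance treats the 95%-power disc as
uniformly illuminated (top-hat), because only a 95% spread diameter is
characterised, not a radial profile; no Gaussian-beam (M², waist)
propagation is attempted. `divergence_from_measurements()` inverts the
cone by least squares on diameter-versus-distance points, as produced by
withdrawing the fiber in 100-μm steps; on noiseless synthetic cones the
inversion is exact, and with 1-μm diameter noise the angle returns within
half a degree.

## 5. Hookean mechanics

All mechanics are static and linear, justified by the small pivoting
angles involved: probe force `F_p = k_p(Δprobe − Δtip)`, bundle stiffness
from the steady-state balance `k_HB = F_p/Δtip`, photonic force from
deflection `F = k·x` (1.8 mN·m⁻¹ × 20 nm = 36 pN, reported as
"approximately 40 pN"; both the raw product and the one-figure report are
returned). Dynamic probe loading, gating-spring nonlinearity, and
negative-stiffness regions are out of scope.

Equipartition stiffness is `k = k_B·T/⟨x²⟩` with
k_B = 1.380649×10⁻²³ J·K⁻¹. The variance is taken after removing the mean
or, optionally, a linear drift (`trace_variance(, "linear")`): slow drift
inflates apparent variance and biases the stiffness low, and detrending is
made explicit rather than silent.

## 6. Trace analysis

* **Averaging** (`average_repetitions()`) demands exactly identical time
  grids — no silent resampling — and tracks the repetition count; 25
  repetitions reduce uncorrelated noise five-fold.
* **Onset fits** (`fit_onset()`) fit
  x(t) = baseline + A·(1 − exp(−(t−t₀)/τ)) by Levenberg–Marquardt
  (analytic Jacobian, ftol = ptol = 10⁻¹⁵) on data from
  t₀ + 250 μs (default exclusion window) to the stimulus offset, with R²
  computed on the fitted window only. Starting values come from a
  log-linear regression of the decaying remainder, the 10–90% rise time,
  and a window fraction; the fit is run from each and the best
  sum-of-squares kept. This multistart matters because when the window is
  long compared with τ the amplitude and baseline directions become
  nearly collinear and a single poor start can collapse τ toward zero.
  Flat traces fail loudly rather than returning τ → ∞. On noiseless
  model data the fit is exact to optimizer tolerance across
  τ = 0.1–2 ms; at signal-to-noise 10 with 25-repetition averaging, τ
  returns within 5%.
* **Adaptation summaries** (`summarize_adaptation()`) use operational
  definitions: peak = extremum within 5τ of onset; plateau = mean of the
  last 20% of the stimulus window; sag = (peak − plateau)/peak clamped at
  zero (a rise not fully saturated by 5τ would otherwise read as a small
  negative sag); undershoot = post-offset extremum relative to baseline;
  twitch = largest dip below the plateau after the peak. The twitch
  definition is a stated convention — the phenomenon is described
  qualitatively in the literature — and its resolution is limited by the
  residual rise deficit at 5τ (~0.7% of the step) and, on noisy traces,
  by the extreme-value bias of a minimum statistic (up to ~4 noise
  standard deviations over ~10³ samples).
* **Power spectra** (`power_spectrum()`) are averaged periodograms
  (Welch): Hann-windowed, mean-detrended, 50%-overlapping segments,
  normalised so the one-sided PSD integrates to the signal variance
  (Parseval, verified to 1% on sinusoids over whole cycles and 5% on
  white noise). Per-segment periodograms are retained for bootstrap
  resampling.
* **Double-Lorentzian fits** (`fit_double_lorentzian()`) use the
  mirrored-peak form standard for spontaneous hair-bundle oscillations —
  a Lorentzian pair at ±f₀ plus a zero-centred Lorentzian and a flat
  noise floor — fitted in log power so each decade weighs equally.
  The functional form is a package choice (the source literature names
  the fit but not the formula); a single-Lorentzian fallback is
  selectable. The fit runs with analytic Jacobian and box constraints;
  a maxiter stop is accepted only if a restart from the terminal point
  confirms the objective is stationary (the noise-floor direction can be
  numerically flat). A peak-free spectrum degenerates to f₀ < w₁, which
  callers should read as "no distinct peak"; an f₀ pinned to the spectral
  edge is an error, not a result.
* **Pre/post comparison** (`compare_pre_post()`) fits both spectra,
  builds position histograms on common breaks, and reports frequency and
  RMS-amplitude changes with bootstrap confidence intervals (resampling
  spectrum segments for frequency, trace blocks for amplitude). On
  synthetic oscillators it detects a 1.5× frequency shift and a halved
  amplitude, and reports a CI containing zero for identical records.

## 7. Synthetic data: what it emulates, and what it does not

The generators produce traces with the statistical structure the analyses
assume, each reproducible bit-for-bit from its seed without touching the
session RNG:

* `generate_ou_trace()`: stationary Ornstein–Uhlenbeck motion of a
  spring-tethered object, by the **exact Gaussian transition kernel**
  (not Euler–Maruyama), so the stationary variance k_B·T/k and
  correlation time λ/k are unbiased at any step size.
* `generate_step_response()`: first-order rise (F/k)(1 − e^(−t/τ)) with
  τ = λ/k, multiplicative adaptation toward a plateau (1 − sag), an
  additive opposite-direction twitch (alpha-function time course,
  delayed 3τ so it is separable from the rise), an optional slow
  photothermal component (default τ = 2.1 ms, the timescale measured for
  light aimed at the cell body — an order slower than the photonic
  rise, and of either sign), mirrored decays after offset with a
  sag-proportional undershoot, plus OU thermal noise and white
  measurement noise. Adaptation and twitch are phenomenological
  exponentials, not mechanistic channel/motor models.
* `generate_oscillation()`: a stochastically driven damped harmonic
  oscillator (γ = ω₀/Q) whose displacement spectrum is the
  mirrored-peak double-Lorentzian with peak f₀ and width ~f₀/Q;
  integrated by semi-implicit Euler at 20× oversampling, drive scaled to
  the requested RMS.
* `generate_sweep_response()`: a linear chirp of force whose minimum
  stays at zero (laser power cannot go negative), passed through the
  first-order bundle filter by exact one-step propagation at 10×
  oversampling with midpoint force evaluation — phase-accurate to
  fs/10, verified pointwise against an independent `deSolve` integration
  to 2% on a 1–2 kHz sweep.

Default study conditions follow the experimental setting: fiber/bundle
constants k = 500 μN·m⁻¹ and λ = 150 nN·s·m⁻¹ (τ = 300 μs) for Brownian
fixtures; onset constants 335 μs, 459 μs, and the 0.64 ms mean as
programmed rises (one figure legend prints "335 s"; the millisecond-scale
axis makes microseconds the evident unit); 25 repetitions; spontaneous
oscillations near 2 Hz; sweeps between 10 Hz and 2 kHz; measurement noise
defaulting to 10 nm, i.e. signal-to-noise 10 on a 100-nm step (recorded
noise magnitudes are not published; this default is a stated convention).

**What passing tests show — and don't.** Parameter-recovery tests
demonstrate that the estimators are correct and calibrated on data obeying
their own assumptions: linear Hookean dynamics, Gaussian noise,
stationarity, exact exponential kinetics. Real recordings contain
nonlinear gating compliance, active bundle motility, non-Gaussian and
nonstationary noise, photodiode drift, and mechanical coupling between
stereocilia, none of which the generators emulate. Population-level
results (mean onset constants across cells, deflection ranges) depend on
raw recordings that are not packaged and are deliberately not asserted.

## 8. Problem sizes and runtime choices

Simulation-backed tests use sizes chosen so Monte-Carlo spreads sit well
inside the asserted tolerances: 8-s Brownian traces (≳26 000 correlation
times; variance-estimator spread under 1%, asserted 5%), 5.12-s traces at
20 kHz (~400 averaged segments) for the spectral-shape check, 60-s
oscillation records for 2-Hz peak fits across ten seeds, and 1001–16001
rays for quadrature refinement. The full suite runs in well under a
minute on one core.

## 9. Known limitations

* Geometric optics only: no Mie/grating scattering, no interference
  between branches, no dispersion or absorbing (complex) indices; the
  cited enhancement of cylinder reflectivity over an equal-volume sphere
  is an external wave-optics result the tracer does not reproduce.
* 2-D cross-section: out-of-plane skew rays and tilted-bundle geometry
  are not modelled; single cylinder only, with no shadowing by
  neighbouring stereocilia.
* The polarization-rotation response of a real bundle is not modelled:
  measured responses do not follow a simple cosine, reflecting varying
  stereociliary tilts and spacings beyond the parallel-cylinder
  idealisation.
* Mechanics are linear and static; the photothermal effect is represented
  only phenomenologically, and fiber fabrication, hardware control, and
  dye-uptake assays are out of scope.
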