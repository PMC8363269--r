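# photonforce

Optics, mechanics, and trace analysis for photonic-force stimulation of
inner-ear hair bundles.

Hair cells transduce sound through their hair bundles — upright clusters of
actin-filled stereocilia whose deflection gates mechanotransduction
channels. Conventional stimulation with a flexible glass fiber is low-pass
filtered by the fiber's own drag: a typical probe (stiffness
k = 500 μN·m⁻¹, drag λ = 150 nN·s·m⁻¹) has a time constant
τ = λ/k = 300 μs, a cutoff near 500 Hz, far below the frequency range of
mammalian hearing. Radiation pressure delivered by a tapered, lens-tipped
optical fiber removes that bottleneck: photons reflected, absorbed, or
refracted by the stereocilia transfer momentum directly to the bundle.

`photonforce` implements the quantitative framework needed to design and
interpret such experiments:

* **Interface optics.** Radiation pressure and force on a reflector or
  absorber, `F = 2·Pwr·cosθ / c_m` with `c_m = c/n` the light speed in the
  immersion medium; Snell refraction with total-internal-reflection
  detection; signed Fresnel amplitude coefficients; the Gladstone–Dale
  estimate `n = n₀ + αρ` of the stereociliary refractive index.
* **Cylinder ray tracing.** A stereocilium is modelled as a dielectric
  cylinder (n ≈ 1.4 in water, n = 1.33). Parallel rays are traced across
  the circular cross-section; each reflection, refraction, and internal
  reflection deposits momentum `(P/c)(n_in·d_in − n_out·d_out)` on the
  cylinder, and a beam is integrated as a deterministic quadrature over
  impact parameters. Conservation of power and momentum are enforced by
  construction and checked by oracle tests.
* **Beam geometry.** The lensed fiber tip emits a cone (≈11° full angle in
  water); spot diameter and irradiance at a working distance, and
  divergence recovered from spot-versus-distance measurements.
* **Bundle mechanics.** Probe-based force and stiffness estimation
  (`F_p = k_p(Δprobe − Δtip)`, `k_HB = F_p/Δtip`), photonic force from
  deflection (`F = k·x`), equipartition stiffness (`k = k_B·T/⟨x²⟩`), and
  first-order time constants.
* **Trace analysis.** Repetition averaging, exponential onset fits with a
  250-μs exclusion window, adaptation summaries (sag, twitch, undershoot),
  Welch power spectra, double-Lorentzian fits of spontaneous-oscillation
  spectra, and pre/post-irradiation comparison with bootstrap confidence
  intervals.
* **Synthetic data.** Seeded generators — exact-discretization
  Ornstein–Uhlenbeck Brownian motion, low-pass step responses with
  adaptation/twitch/photothermal components, stochastic oscillators, and
  frequency-sweep responses — so every analysis is validated against known
  ground truth.

## Worked example

```r
library(photonforce)

## Upper limit of the photonic force: 10 mW striking a perfect reflector
## at 20 degrees in physiological solution
beam <- beam_spec(power = 10e-3, incidence_deg = 20)
f <- reflection_force(beam, medium_index = 1.33)
#> 83.4 pN, reported as 80 pN at one significant figure

## Fresnel coefficients at the water/stereocilium interface
fresnel_amplitudes(1.33, 1.4, 20)
#> <fresnel_amplitudes> 1.33 -> 1.4 at 20 deg (theta_T = 18.96 deg)
#>   |r_par| = 0.022  |r_perp| = 0.029  t_par = 0.971  t_perp = 0.971
## only ~0.05% of the power reflects from a flat interface -- the curved
## stereociliary surface is what makes the bundle responsive:

cyl <- cylinder_section(radius = 0.25e-6, index_inside = 1.4,
                        index_outside = 1.33)
beam_force_on_cylinder(15e-3, cyl, n_rays = 1001)
#> <beam_cylinder_force> 15 mW uniform beam, 1001 rays
#>   total force (0.9699, 4.782e-17) pN

## Synthetic step responses analysed like recordings: 25 repetitions at
## signal-to-noise 10, averaged, then fitted past a 250-us exclusion window
spec <- step_stimulus_spec(force = 50e-12, stiffness = 500e-6,
                           drag = 167.5e-9)          # tau = 335 us
reps <- lapply(1:25, function(i) generate_step_response(
  spec, 2e-3, 28e-3,
  generator_config(seed = i, sampling_rate = 1e5, duration = 30e-3,
                   noise_sd = 10e-9)))
fit_onset(average_repetitions(reps))
#> <onset_fit> tau = 329.2 us, amplitude = 104.8 nm, R^2 = 0.7821
#>             (first 250 us excluded)
```

The first number is the textbook reflection bound; the cylinder trace shows
that a dielectric cylinder in water intercepts about 1 pN per 15 mW through
curved-surface reflection and refraction alone, and the onset fit recovers
the programmed 335-μs rise within 2% from noisy averaged data.

A command-line wrapper over the same functions ships in
`inst/cli/photonforce.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","photonforce.R",package="photonforce"))')" \
    optics --mode fresnel --n-in 1.33 --n-out 1.4 --theta-deg 20
```

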