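#' Configuration for the synthetic-trace generators
#'
#' Every generator is deterministic given a seed: identical configs produce
#' bit-identical traces, and the caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param sampling_rate sampling rate in hertz.
#' @param duration trace duration in seconds.
#' @param noise_sd additive white Gaussian measurement noise, metres
#'   (stand-in for photodiode noise).  The default 10e-9 gives a
#'   signal-to-noise ratio of 10 on a 100 nm step; set 0 for noise-free
#'   traces.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed, sampling_rate, duration,
                             noise_sd = 10e-9) {
  check_scalar(seed, "seed")
  check_scalar(sampling_rate, "sampling_rate", lower = 0,
               strict_lower = TRUE)
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", lower = 0)
  if (round(duration * sampling_rate) < 2)
    stop("duration times sampling rate must give at least 2 samples",
         call. = FALSE)
  structure(list(seed = as.integer(seed), sampling_rate = sampling_rate,
                 duration = duration, noise_sd = noise_sd),
            class = "generator_config")
}

.cfg_n <- function(cfg) as.integer(round(cfg$duration * cfg$sampling_rate))

.check_bandwidth <- function(cfg, tau) {
  ## a first-order process with time constant tau has its corner at
  ## 1/(2 pi tau); require ~20x that, i.e. fs * tau >= 20 / (2 pi)
  if (cfg$sampling_rate * tau < 20 / (2 * pi))
    warning(sprintf(
      "sampling rate %.3g Hz undersamples a %.3g-us time constant",
      cfg$sampling_rate, tau * 1e6), call. = FALSE)
}

## stationary exact-discretization OU sample path (noise-free), n samples
.ou_path <- function(n, dt, tau, stat_var) {
  if (stat_var == 0) return(numeric(n))
  rho <- exp(-dt / tau)
  z <- stats::rnorm(n)
  innov <- c(sqrt(stat_var) * z[1],
             sqrt(stat_var * (1 - rho^2)) * z[-1])
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

#' Synthetic Brownian motion of an elastically tethered object
#'
#' Stationary Ornstein--Uhlenbeck process with stiffness `k`, drag
#' `lambda` and temperature `T`: stationary variance `k_B T / k`
#' (equipartition) and correlation time `lambda / k`.  The discretization
#' uses the exact Gaussian transition kernel, so the sample variance is
#' unbiased at any step size.  Measurement noise from `cfg$noise_sd` is
#' added on top.
#'
#' @param k tether stiffness, N/m.
#' @param drag drag coefficient, N s/m.
#' @param temperature absolute temperature, K (0 gives an identically zero
#'   Brownian path).
#' @param cfg a [generator_config()].
#' @return A [displacement_trace()]; the generating parameters are attached
#'   as `attr(, "ground_truth")`.
#' @examples
#' cfg <- generator_config(seed = 7, sampling_rate = 2e4, duration = 2,
#'                         noise_sd = 0)
#' tr <- generate_ou_trace(1e-3, 150e-9, 298, cfg)
#' equipartition_stiffness(trace_variance(tr))   # ~1e-3 N/m
#' @export
generate_ou_trace <- function(k, drag, temperature = 298, cfg) {
  check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  check_scalar(drag, "drag", lower = 0, strict_lower = TRUE)
  check_scalar(temperature, "temperature", lower = 0)
  stopifnot(inherits(cfg, "generator_config"))
  tau <- drag / k
  .check_bandwidth(cfg, tau)
  n <- .cfg_n(cfg)
  dt <- 1 / cfg$sampling_rate
  x <- with_seed(cfg$seed, {
    path <- .ou_path(n, dt, tau, K_BOLTZMANN * temperature / k)
    if (cfg$noise_sd > 0) path <- path + stats::rnorm(n, 0, cfg$noise_sd)
    path
  })
  tr <- displacement_trace(x, sampling_rate = cfg$sampling_rate)
  attr(tr, "ground_truth") <- list(k = k, drag = drag,
                                   temperature = temperature, tau = tau,
                                   stationary_variance =
                                     K_BOLTZMANN * temperature / k)
  tr
}

#' Parameters of a synthetic step-force stimulus
#'
#' Phenomenological description of a light-step response: a first-order
#' rise `(F/k)(1 - exp(-t/tau))` with `tau = drag / k`, an optional slow
#' adaptive decline toward a plateau `(1 - sag_fraction)` of the peak, an
#' optional fast opposite-direction twitch, and an optional slow
#' photothermal component (time constant ~2 ms, an order slower than the
#' photonic rise) of either sign.
#'
#' @param force step force, N.
#' @param stiffness bundle stiffness, N/m.
#' @param drag bundle drag coefficient, N s/m.
#' @param sag_fraction fraction of the peak lost to adaptation, in `[0, 1)`.
#' @param adaptation_tau adaptation time constant, s.
#' @param twitch_amplitude depth of the fast opposite-direction rebound, m.
#' @param twitch_tau twitch time constant, s.
#' @param photothermal_amplitude amplitude of the slow photothermal
#'   component, m.
#' @param photothermal_tau photothermal time constant, s (default 2.1e-3).
#' @param photothermal_sign +1 with the light direction, -1 against it.
#' @return An object of class `step_stimulus_spec`.
#' @export
step_stimulus_spec <- function(force, stiffness, drag,
                               sag_fraction = 0, adaptation_tau = 10e-3,
                               twitch_amplitude = 0, twitch_tau = 1e-3,
                               photothermal_amplitude = 0,
                               photothermal_tau = 2.1e-3,
                               photothermal_sign = 1) {
  check_scalar(force, "force")
  check_scalar(stiffness, "stiffness", lower = 0, strict_lower = TRUE)
  check_scalar(drag, "drag", lower = 0, strict_lower = TRUE)
  check_scalar(sag_fraction, "sag_fraction", lower = 0)
  if (sag_fraction >= 1)
    stop("`sag_fraction` must be < 1", call. = FALSE)
  check_scalar(adaptation_tau, "adaptation_tau", lower = 0,
               strict_lower = TRUE)
  check_scalar(twitch_amplitude, "twitch_amplitude", lower = 0)
  check_scalar(twitch_tau, "twitch_tau", lower = 0, strict_lower = TRUE)
  check_scalar(photothermal_amplitude, "photothermal_amplitude", lower = 0)
  check_scalar(photothermal_tau, "photothermal_tau", lower = 0,
               strict_lower = TRUE)
  if (!photothermal_sign %in% c(-1, 1))
    stop("`photothermal_sign` must be +1 or -1", call. = FALSE)
  structure(list(force = force, stiffness = stiffness, drag = drag,
                 sag_fraction = sag_fraction,
                 adaptation_tau = adaptation_tau,
                 twitch_amplitude = twitch_amplitude,
                 twitch_tau = twitch_tau,
                 photothermal_amplitude = photothermal_amplitude,
                 photothermal_tau = photothermal_tau,
                 photothermal_sign = photothermal_sign),
            class = "step_stimulus_spec")
}

#' Synthetic displacement response to a step of photonic force
#'
#' Deterministic response per [step_stimulus_spec()] — first-order rise,
#' multiplicative adaptation toward the plateau, additive twitch and
#' photothermal components — plus stationary Ornstein--Uhlenbeck thermal
#' noise (at the spec's stiffness/drag and `temperature`) and additive
#' measurement noise.  After the stimulus offset the deterministic
#' components decay with their own time constants and adaptation produces
#' a proportional undershoot below baseline.
#'
#' @param spec a [step_stimulus_spec()].
#' @param onset,offset stimulus onset and offset times, s
#'   (`0 <= onset < offset <= duration`).
#' @param cfg a [generator_config()].
#' @param temperature temperature for the thermal-noise component, K; set 0
#'   to disable thermal noise.
#' @return A [displacement_trace()] with stimulus marks set and ground
#'   truth attached as `attr(, "ground_truth")`.
#' @examples
#' spec <- step_stimulus_spec(force = 50e-12, stiffness = 500e-6,
#'                            drag = 320e-9, sag_fraction = 0.3)
#' cfg <- generator_config(seed = 2, sampling_rate = 1e5, duration = 0.12)
#' tr <- generate_step_response(spec, onset = 0.01, offset = 0.1, cfg)
#' summarize_adaptation(tr)
#' @export
generate_step_response <- function(spec, onset, offset, cfg,
                                   temperature = 0) {
  stopifnot(inherits(spec, "step_stimulus_spec"),
            inherits(cfg, "generator_config"))
  check_scalar(onset, "onset", lower = 0)
  check_scalar(offset, "offset", lower = 0)
  if (!(onset < offset && offset <= cfg$duration))
    stop("need onset < offset <= duration", call. = FALSE)
  check_scalar(temperature, "temperature", lower = 0)
  tau <- spec$drag / spec$stiffness
  .check_bandwidth(cfg, tau)
  n <- .cfg_n(cfg)
  dt <- 1 / cfg$sampling_rate
  t <- (seq_len(n) - 1) * dt
  x_step <- spec$force / spec$stiffness

  rise_at <- function(tp) x_step * (1 - exp(-tp / tau)) *
    (1 - spec$sag_fraction * (1 - exp(-tp / spec$adaptation_tau)))
  twitch_at <- function(tp) {
    tpp <- pmax(0, tp - 3 * tau)
    -spec$twitch_amplitude * (tpp / spec$twitch_tau) *
      exp(1 - tpp / spec$twitch_tau)
  }
  pt_at <- function(tp) spec$photothermal_sign *
    spec$photothermal_amplitude * (1 - exp(-tp / spec$photothermal_tau))

  x <- numeric(n)
  during <- t >= onset & t <= offset
  after <- t > offset
  tp <- t[during] - onset
  x[during] <- rise_at(tp) + twitch_at(tp) + pt_at(tp)
  if (any(after)) {
    dur <- offset - onset
    ta <- t[after] - offset
    x[after] <- rise_at(dur) * exp(-ta / tau) -
      spec$sag_fraction * x_step * (1 - exp(-ta / tau)) *
        exp(-ta / spec$adaptation_tau) +
      twitch_at(dur) * exp(-ta / spec$twitch_tau) +
      pt_at(dur) * exp(-ta / spec$photothermal_tau)
  }
  x <- x + with_seed(cfg$seed, {
    noise <- .ou_path(n, dt, tau,
                      K_BOLTZMANN * temperature / spec$stiffness)
    if (cfg$noise_sd > 0) noise <- noise + stats::rnorm(n, 0, cfg$noise_sd)
    noise
  })
  tr <- displacement_trace(x, sampling_rate = cfg$sampling_rate,
                           stimulus_onset = onset,
                           stimulus_offset = offset)
  attr(tr, "ground_truth") <- list(
    spec = spec, tau = tau, step_amplitude = x_step,
    plateau = x_step * (1 - spec$sag_fraction), temperature = temperature)
  tr
}

#' Synthetic spontaneous hair-bundle oscillation
#'
#' Stochastically driven damped harmonic oscillator
#' `x'' + gamma x' + omega0^2 x = noise`, with `omega0 = 2 pi f0` and
#' `gamma = omega0 / quality`, whose displacement spectrum is the
#' mirrored-peak double-Lorentzian with peak `f0` and full width at half
#' maximum ~`f0 / quality`.  The drive amplitude is scaled so the
#' stationary RMS displacement equals `rms_amplitude`.  Integration uses
#' semi-implicit Euler at 20-fold oversampling, then decimates to the
#' configured rate.
#'
#' @param f0 oscillation peak frequency, Hz (must be below
#'   `sampling_rate / 10`).
#' @param rms_amplitude stationary root-mean-square displacement, m
#'   (0 gives pure measurement noise).
#' @param quality dimensionless quality factor (peak frequency over width).
#' @param cfg a [generator_config()].
#' @return A [displacement_trace()] with ground truth attached.
#' @export
generate_oscillation <- function(f0, rms_amplitude, quality, cfg) {
  check_scalar(f0, "f0", lower = 0, strict_lower = TRUE)
  check_scalar(rms_amplitude, "rms_amplitude", lower = 0)
  check_scalar(quality, "quality", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(cfg, "generator_config"))
  if (f0 >= cfg$sampling_rate / 10)
    stop("`f0` must be below sampling_rate / 10", call. = FALSE)
  n <- .cfg_n(cfg)
  over <- 20L
  dtf <- 1 / (cfg$sampling_rate * over)
  omega0 <- 2 * pi * f0
  gamma <- omega0 / quality
  sigma <- rms_amplitude * omega0 * sqrt(2 * gamma)   # drive for target rms
  x <- with_seed(cfg$seed, {
    if (rms_amplitude > 0) {
      nf <- n * over
      xi <- stats::rnorm(nf, 0, sigma * sqrt(dtf))
      xs <- numeric(nf)
      v <- stats::rnorm(1, 0, rms_amplitude * omega0)
      xp <- stats::rnorm(1, 0, rms_amplitude)
      for (i in seq_len(nf)) {
        v <- v + (-omega0^2 * xp - gamma * v) * dtf + xi[i]
        xp <- xp + v * dtf
        xs[i] <- xp
      }
      path <- xs[seq(1L, nf, by = over)]
    } else {
      path <- numeric(n)
    }
    if (cfg$noise_sd > 0) path <- path + stats::rnorm(n, 0, cfg$noise_sd)
    path
  })
  tr <- displacement_trace(x, sampling_rate = cfg$sampling_rate)
  attr(tr, "ground_truth") <- list(f0 = f0, rms_amplitude = rms_amplitude,
                                   quality = quality,
                                   fwhm = f0 / quality)
  tr
}

#' Synthetic response to a sinusoidal frequency sweep
#'
#' A linear-frequency chirp of photonic force,
#' `F(t) = peak_force (1 + sin(2 pi phi(t))) / 2` (so the force — like the
#' laser power driving it — never goes negative), filtered through the
#' bundle's first-order dynamics `tau = drag / k`.  Integration uses the
#' exact one-step propagator at 10-fold internal oversampling with the
#' force evaluated at interval midpoints, then decimates, so the sampled
#' response is phase-accurate up to `sampling_rate / 10`.  The response
#' amplitude rolls off with the analytic first-order magnitude
#' `1 / sqrt(1 + (2 pi f tau)^2)`.
#'
#' @param f_start,f_end sweep start and end frequencies, Hz
#'   (`f_end <= sampling_rate / 10`).
#' @param peak_force peak chirp force, N.
#' @param k bundle stiffness, N/m.
#' @param drag bundle drag coefficient, N s/m.
#' @param cfg a [generator_config()].
#' @return A [displacement_trace()] with ground truth attached (including
#'   the instantaneous frequency ramp).
#' @export
generate_sweep_response <- function(f_start, f_end, peak_force, k, drag,
                                    cfg) {
  check_scalar(f_start, "f_start", lower = 0, strict_lower = TRUE)
  check_scalar(f_end, "f_end", lower = 0, strict_lower = TRUE)
  check_scalar(peak_force, "peak_force", lower = 0)
  check_scalar(k, "k", lower = 0, strict_lower = TRUE)
  check_scalar(drag, "drag", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(cfg, "generator_config"))
  if (max(f_start, f_end) > cfg$sampling_rate / 10)
    stop("sweep frequencies must be <= sampling_rate / 10", call. = FALSE)
  tau <- drag / k
  n <- .cfg_n(cfg)
  dt <- 1 / cfg$sampling_rate
  t <- (seq_len(n) - 1) * dt
  chirp_force <- function(tt) {
    ph <- f_start * tt + (f_end - f_start) * tt^2 / (2 * cfg$duration)
    peak_force * (1 + sin(2 * pi * ph)) / 2
  }
  force <- chirp_force(t)
  over <- 10L
  dtf <- dt / over
  a <- exp(-dtf / tau)
  f_mid <- chirp_force(seq(0, by = dtf, length.out = (n - 1L) * over) +
                         dtf / 2)
  xf <- numeric((n - 1L) * over + 1L)
  xf[1] <- force[1] / k
  for (i in seq_len((n - 1L) * over))
    xf[i + 1L] <- xf[i] * a + (1 - a) * f_mid[i] / k
  x <- xf[seq(1L, length(xf), by = over)]
  x <- x + with_seed(cfg$seed, {
    if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
  })
  tr <- displacement_trace(x, sampling_rate = cfg$sampling_rate)
  attr(tr, "ground_truth") <- list(
    f_start = f_start, f_end = f_end, peak_force = peak_force,
    k = k, drag = drag, tau = tau, force = force,
    instantaneous_frequency = f_start + (f_end - f_start) * t /
      cfg$duration)
  tr
}
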