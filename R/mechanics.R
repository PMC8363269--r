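#' A Hookean mechanical element: hair bundle, glass rod, or probe fiber
#'
#' @param stiffness spring stiffness in N/m (> 0).
#' @param drag_coefficient viscous drag coefficient in N s/m (optional;
#'   required for [time_constant()] / [cutoff_frequency()]).
#' @param temperature absolute temperature in kelvin (default 298).
#' @return An object of class `mechanical_element`.
#' @examples
#' mechanical_element(500e-6, drag_coefficient = 150e-9)
#' @export
mechanical_element <- function(stiffness, drag_coefficient = NULL,
                               temperature = 298) {
  check_scalar(stiffness, "stiffness", lower = 0, strict_lower = TRUE)
  check_scalar(drag_coefficient, "drag_coefficient", lower = 0,
               allow_null = TRUE)
  check_scalar(temperature, "temperature", lower = 0)
  structure(list(stiffness = stiffness,
                 drag_coefficient = drag_coefficient,
                 temperature = temperature),
            class = "mechanical_element")
}

#' @export
print.mechanical_element <- function(x, ...) {
  cat(sprintf("<mechanical_element> k = %.4g uN/m", x$stiffness * 1e6))
  if (!is.null(x$drag_coefficient))
    cat(sprintf(", drag = %.4g nN s/m", x$drag_coefficient * 1e9))
  cat(sprintf(", T = %.4g K\n", x$temperature))
  invisible(x)
}

#' Displacements measured with a flexible probe against a hair bundle
#'
#' A calibrated glass probe of stiffness `k_p` is glued to the bundle's tip;
#' its base is driven by an actuator through `base_displacement`
#' (delta-probe) while the tip — and the bundle with it — moves by
#' `tip_displacement` (delta-tip).
#'
#' @param probe_stiffness probe stiffness in N/m.
#' @param base_displacement displacement imposed on the probe base, metres.
#' @param tip_displacement resulting displacement of the probe tip (equal to
#'   the bundle motion), metres; for a pushing stimulus it lies between 0
#'   and `base_displacement`.
#' @return An object of class `probe_measurement`.
#' @export
probe_measurement <- function(probe_stiffness, base_displacement,
                              tip_displacement) {
  check_scalar(probe_stiffness, "probe_stiffness", lower = 0,
               strict_lower = TRUE)
  check_scalar(base_displacement, "base_displacement")
  check_scalar(tip_displacement, "tip_displacement")
  if (base_displacement >= 0 &&
      (tip_displacement < 0 || tip_displacement > base_displacement))
    stop("for pushing stimulation, 0 <= tip_displacement <= ",
         "base_displacement", call. = FALSE)
  structure(list(probe_stiffness = probe_stiffness,
                 base_displacement = base_displacement,
                 tip_displacement = tip_displacement),
            class = "probe_measurement")
}

#' Force delivered by a flexed probe
#'
#' Hookean force of the probe fiber on the bundle:
#' `F_p = k_p (delta_probe - delta_tip)`.
#'
#' @param m a [probe_measurement()].
#' @return Force in newtons.
#' @examples
#' probe_force(probe_measurement(500e-6, 100e-9, 40e-9)) * 1e12  # 30 pN
#' @export
probe_force <- function(m) {
  stopifnot(inherits(m, "probe_measurement"))
  m$probe_stiffness * (m$base_displacement - m$tip_displacement)
}

#' Hair-bundle stiffness from a probe measurement
#'
#' At steady deflection the probe force balances the bundle's elastic
#' reaction `F_HB = k_HB delta_tip`, so
#' `k_HB = k_p (delta_probe - delta_tip) / delta_tip`.
#'
#' @param m a [probe_measurement()] with non-zero tip displacement.
#' @return Bundle stiffness in N/m.
#' @examples
#' bundle_stiffness_from_probe(probe_measurement(1e-3, 100e-9, 36e-9))
#' @export
bundle_stiffness_from_probe <- function(m) {
  stopifnot(inherits(m, "probe_measurement"))
  if (m$tip_displacement == 0)
    stop("tip displacement is zero: bundle stiffness is undefined",
         call. = FALSE)
  probe_force(m) / m$tip_displacement
}

#' Photonic force inferred from a bundle's deflection
#'
#' Given a bundle of known stiffness deflected by a light pulse, the
#' delivered force is `k x`.  A bundle of stiffness 1.8 mN/m deflected by
#' 20 nm experienced 36 pN, reported as approximately 40 pN at one
#' significant figure (see [report_sigfig()]).
#'
#' @param bundle_stiffness bundle stiffness in N/m (>= 0).
#' @param deflection observed deflection in metres (>= 0).
#' @return Force in newtons (unrounded).
#' @examples
#' f <- photonic_force_from_deflection(1.8e-3, 20e-9)
#' c(raw_pN = f * 1e12, reported_pN = report_sigfig(f * 1e12, 1))
#' @export
photonic_force_from_deflection <- function(bundle_stiffness, deflection) {
  check_scalar(bundle_stiffness, "bundle_stiffness", lower = 0)
  check_scalar(deflection, "deflection", lower = 0)
  bundle_stiffness * deflection
}

#' Stiffness from thermal position fluctuations (equipartition)
#'
#' For an elastically tethered object in thermal equilibrium the
#' equipartition theorem gives `k = k_B T / <x^2>`, with `<x^2>` the
#' variance of its Brownian position fluctuations.
#'
#' @param position_variance variance of the position trace in m^2 (> 0).
#' @param temperature absolute temperature in kelvin (default 298).
#' @return Stiffness in N/m.
#' @examples
#' equipartition_stiffness(4.11e-18)   # ~1 mN/m at 298 K
#' @seealso [trace_variance()] for detrended variance of a recorded trace;
#'   [generate_ou_trace()] for synthetic Brownian traces.
#' @export
equipartition_stiffness <- function(position_variance, temperature = 298) {
  check_scalar(position_variance, "position_variance", lower = 0,
               strict_lower = TRUE)
  check_scalar(temperature, "temperature", lower = 0, strict_lower = TRUE)
  K_BOLTZMANN * temperature / position_variance
}

#' Relaxation time constant of a spring-drag element
#'
#' First-order mechanics: an element of stiffness `k` and drag `lambda`
#' relaxes with `tau = lambda / k` and behaves as a low-pass filter with
#' cutoff `f_c = 1 / (2 pi tau)`.  A typical flexible stimulus fiber
#' (k = 500 uN/m, lambda = 150 nN s/m) has `tau` = 300 us and a cutoff
#' near 500 Hz — the bottleneck photonic stimulation removes.
#'
#' @param element a [mechanical_element()] with a drag coefficient.
#' @return `time_constant()`: seconds; `cutoff_frequency()`: hertz.
#' @examples
#' fiber <- mechanical_element(500e-6, drag_coefficient = 150e-9)
#' time_constant(fiber)       # 3e-4 s
#' cutoff_frequency(fiber)    # ~530 Hz
#' @export
time_constant <- function(element) {
  stopifnot(inherits(element, "mechanical_element"))
  if (is.null(element$drag_coefficient) || element$drag_coefficient <= 0)
    stop("a positive `drag_coefficient` is required for a time constant",
         call. = FALSE)
  element$drag_coefficient / element$stiffness
}

#' @rdname time_constant
#' @export
cutoff_frequency <- function(element) {
  1 / (2 * pi * time_constant(element))
}
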