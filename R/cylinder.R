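#' Circular cross-section of a stereocilium (or other dielectric cylinder)
#'
#' The ray tracer works in the plane perpendicular to the cylinder axis.
#' Light propagates along +x, the transverse direction is +y, and the
#' cylinder axis is z; forces are reported as `(F_x, F_y)`.
#'
#' @param radius cylinder radius in metres (a stereocilium is ~0.25e-6).
#' @param index_inside refractive index of the cylinder interior
#'   (stereociliary cytoplasm ~1.4).
#' @param index_outside refractive index of the surrounding medium
#'   (water 1.33).
#' @param perfect_mirror force unit reflectance at the front surface — the
#'   idealised perfect-reflector limit; no light enters the cylinder.
#' @return An object of class `cylinder_section`.
#' @examples
#' cylinder_section(0.25e-6, 1.4, 1.33)
#' @export
cylinder_section <- function(radius, index_inside = 1.4,
                             index_outside = 1.33,
                             perfect_mirror = FALSE) {
  check_scalar(radius, "radius", lower = 0, strict_lower = TRUE)
  check_scalar(index_inside, "index_inside", lower = 1)
  check_scalar(index_outside, "index_outside", lower = 1)
  structure(list(radius = radius, index_inside = index_inside,
                 index_outside = index_outside,
                 perfect_mirror = isTRUE(perfect_mirror)),
            class = "cylinder_section")
}

#' @export
print.cylinder_section <- function(x, ...) {
  cat(sprintf("<cylinder_section> radius %.4g um, n %.4g inside / %.4g outside\n",
              x$radius * 1e6, x$index_inside, x$index_outside))
  invisible(x)
}

#' A single parallel ray aimed at a cylinder cross-section
#'
#' @param impact_parameter signed distance (m) of the ray from the cylinder
#'   axis, measured in the cross-section plane; rays with
#'   `|impact_parameter|` larger than the radius miss.
#' @param power ray power in watts (the share of the beam carried by this
#'   ray).
#' @param polarization `"parallel"` or `"perpendicular"` to the plane of
#'   incidence (the cross-section plane).  An electric field aligned with
#'   the cylinder's long axis — the preferred alignment for hair-bundle
#'   stimulation — is the `"perpendicular"` case here.
#' @return An object of class `incident_ray`.
#' @export
incident_ray <- function(impact_parameter, power = 1,
                         polarization = c("perpendicular", "parallel")) {
  check_scalar(impact_parameter, "impact_parameter")
  check_scalar(power, "power", lower = 0)
  polarization <- match.arg(polarization)
  structure(list(impact_parameter = impact_parameter, power = power,
                 polarization = polarization),
            class = "incident_ray")
}

## ---- internal geometric/optical primitives (plain numerics, hot path) ----

## power reflectance at an interface, from cos(incidence); returns 1 for TIR
.reflectance <- function(n1, n2, cos_i, parallel) {
  sin_i <- sqrt(max(0, 1 - cos_i^2))
  sin_t <- n1 / n2 * sin_i
  if (sin_t >= 1) return(1)
  cos_t <- sqrt(1 - sin_t^2)
  r <- if (parallel) {
    (n2 * cos_i - n1 * cos_t) / (n2 * cos_i + n1 * cos_t)
  } else {
    (n1 * cos_i - n2 * cos_t) / (n1 * cos_i + n2 * cos_t)
  }
  r^2
}

.reflect_dir <- function(d, nhat) d - 2 * sum(d * nhat) * nhat

## refracted direction; nhat must oppose d (cos_i = -d.nhat > 0)
.refract_dir <- function(d, nhat, n1, n2) {
  cos_i <- -sum(d * nhat)
  eta <- n1 / n2
  sin2_t <- eta^2 * (1 - cos_i^2)
  if (sin2_t >= 1) return(NULL)       # TIR: no refracted ray
  cos_t <- sqrt(1 - sin2_t)
  eta * d + (eta * cos_i - cos_t) * nhat
}

## Trace the internal portion of a ray: from point `p` on the circle moving
## along unit vector `d` inside, with power `pw`.  Appends events/exits.
## Event rows: kind, px, py, din_x, din_y, dout_x, dout_y, power, mom_x, mom_y
.internal_loop <- function(p, d, pw, r, n1, n2, pol_parallel,
                           max_bounces, cutoff_abs, events, exits) {
  bounces <- 0L
  terminated <- NULL
  while (TRUE) {
    if (pw < cutoff_abs) { terminated <- "power_cutoff"; break }
    if (bounces >= max_bounces) { terminated <- "bounce_cap"; break }
    t_hit <- -2 * sum(p * d)
    if (t_hit <= r * 1e-12) { terminated <- "power_cutoff"; break } # grazing
    p <- p + t_hit * d
    nhat <- p / sqrt(sum(p^2))
    cos_th <- sum(d * nhat)                 # internal incidence cosine
    refl <- .reflectance(n2, n1, cos_th, pol_parallel)
    if (refl < 1) {                         # partial exit through the wall
      d_out <- .refract_dir(d, -nhat, n2, n1)
      p_exit <- pw * (1 - refl)
      events[[length(events) + 1L]] <- c(
        4, p, d, d_out, p_exit,
        (p_exit / C_VACUUM) * (n2 * d - n1 * d_out))
      exits[[length(exits) + 1L]] <- c(p_exit, d_out)
    }
    ## reflected branch continues inside (total reflection when refl == 1)
    d_ref <- .reflect_dir(d, nhat)
    p_ref <- pw * refl
    events[[length(events) + 1L]] <- c(
      3, p, d, d_ref, p_ref,
      (n2 * p_ref / C_VACUUM) * (d - d_ref))
    d <- d_ref
    pw <- p_ref
    bounces <- bounces + 1L
  }
  list(events = events, exits = exits, residual = pw,
       terminated = terminated, bounces = bounces)
}

## Full trace of one externally incident ray; returns plain lists.
.trace_core <- function(b, pw, pol_parallel, r, n1, n2,
                        max_bounces, cutoff_frac, mirror = FALSE) {
  events <- list()
  exits <- list()
  if (abs(b) > r || pw == 0) {
    if (pw > 0) exits[[1L]] <- c(pw, 1, 0)   # ray passes by untouched
    return(list(events = events, exits = exits, residual = 0,
                terminated = "exit", miss = TRUE, incident_power = pw))
  }
  p <- c(-sqrt(max(0, r^2 - b^2)), b)
  d <- c(1, 0)
  nhat <- p / r
  cos_i <- -sum(d * nhat)
  refl <- if (mirror) 1 else .reflectance(n1, n2, cos_i, pol_parallel)
  ## external reflection branch exits immediately
  if (refl > 0) {
    d_r <- .reflect_dir(d, nhat)
    p_r <- pw * refl
    events[[1L]] <- c(1, p, d, d_r, p_r, (n1 * p_r / C_VACUUM) * (d - d_r))
    exits[[1L]] <- c(p_r, d_r)
  }
  residual <- 0
  terminated <- "exit"
  bounces <- 0L
  if (refl < 1) {                            # refracted branch enters
    d_t <- .refract_dir(d, nhat, n1, n2)
    p_t <- pw * (1 - refl)
    events[[length(events) + 1L]] <- c(
      2, p, d, d_t, p_t, (p_t / C_VACUUM) * (n1 * d - n2 * d_t))
    loop <- .internal_loop(p, d_t, p_t, r, n1, n2, pol_parallel,
                           max_bounces, cutoff_frac * pw, events, exits)
    events <- loop$events
    exits <- loop$exits
    residual <- loop$residual
    terminated <- loop$terminated
    bounces <- loop$bounces
  }
  list(events = events, exits = exits, residual = residual,
       terminated = terminated, miss = FALSE, incident_power = pw,
       bounces = bounces)
}

.event_kinds <- c("external_reflection", "refraction_in",
                  "internal_reflection", "refraction_out")

## package the plain-list core result into a classed ray_path
.as_ray_path <- function(core, impact_parameter, cyl, polarization) {
  ev <- core$events
  if (length(ev)) {
    m <- do.call(rbind, ev)
    events <- data.frame(
      kind = .event_kinds[m[, 1]],
      point_x = m[, 2], point_y = m[, 3],
      in_x = m[, 4], in_y = m[, 5],
      out_x = m[, 6], out_y = m[, 7],
      event_power = m[, 8],
      momentum_x = m[, 9], momentum_y = m[, 10])
  } else {
    events <- data.frame(kind = character(), point_x = numeric(),
                         point_y = numeric(), in_x = numeric(),
                         in_y = numeric(), out_x = numeric(),
                         out_y = numeric(), event_power = numeric(),
                         momentum_x = numeric(), momentum_y = numeric())
  }
  ex <- core$exits
  exits <- if (length(ex)) {
    m <- do.call(rbind, ex)
    data.frame(power = m[, 1], dir_x = m[, 2], dir_y = m[, 3])
  } else {
    data.frame(power = numeric(), dir_x = numeric(), dir_y = numeric())
  }
  structure(list(
    events = events, exit_rays = exits,
    residual_power = core$residual,
    terminated_by = core$terminated,
    incident_power = core$incident_power,
    impact_parameter = impact_parameter,
    polarization = polarization,
    cylinder = cyl), class = "ray_path")
}

#' Trace one ray across a cylinder cross-section
#'
#' The ray first meets the front surface at local incidence angle
#' `phi = arcsin(|b| / r)` and splits by the Fresnel power coefficients into
#' an externally reflected ray (which exits) and a refracted ray that
#' travels along a chord.  By circle geometry every subsequent internal hit
#' occurs at the same angle — the refraction angle at entry — so the
#' internal ray either exits with a Fresnel split at each wall hit or, at or
#' beyond the critical angle, reflects totally.  Only the internally
#' reflected branch continues; the transmitted share is deposited as an
#' exiting ray.  Tracing stops when the tracked power falls below
#' `power_cutoff_fraction` of the incident power or after
#' `max_internal_bounces` wall reflections.
#'
#' Each surface interaction is recorded as one or two events whose momentum
#' transfer is `(P/c) (n_in d_in - n_out d_out)` with the refractive index
#' of the medium each direction travels in; summing the transfers over a
#' path gives the force the ray exerts on the cylinder.
#'
#' @param ray an [incident_ray()].
#' @param cyl a [cylinder_section()].
#' @param max_internal_bounces cap on internal wall reflections (default 10,
#'   ample for the few total internal reflections a trapped ray exhibits).
#' @param power_cutoff_fraction stop tracking when the remaining internal
#'   power falls below this fraction of the incident power (default 1e-4).
#' @return An object of class `ray_path` with fields `events` (data frame of
#'   surface events with momentum transfers in newtons), `exit_rays`,
#'   `residual_power`, `terminated_by` (`"exit"`, `"power_cutoff"` or
#'   `"bounce_cap"`), `incident_power` and `impact_parameter`.
#' @examples
#' cyl <- cylinder_section(0.25e-6, 1.4, 1.33)
#' path <- trace_ray(incident_ray(0.15e-6, power = 1e-3), cyl)
#' ray_force(path)
#' @seealso [ray_force()], [beam_force_on_cylinder()], [inject_internal_ray()]
#' @export
trace_ray <- function(ray, cyl, max_internal_bounces = 10,
                      power_cutoff_fraction = 1e-4) {
  stopifnot(inherits(ray, "incident_ray"), inherits(cyl, "cylinder_section"))
  check_scalar(max_internal_bounces, "max_internal_bounces", lower = 1)
  check_scalar(power_cutoff_fraction, "power_cutoff_fraction",
               lower = 0, strict_lower = TRUE)
  core <- .trace_core(ray$impact_parameter, ray$power,
                      ray$polarization == "parallel",
                      cyl$radius, cyl$index_outside, cyl$index_inside,
                      max_internal_bounces, power_cutoff_fraction,
                      mirror = cyl$perfect_mirror)
  .as_ray_path(core, ray$impact_parameter, cyl, ray$polarization)
}

#' @export
print.ray_path <- function(x, ...) {
  f <- ray_force(x)
  cat(sprintf(
    paste0("<ray_path> b = %.4g um, %d events, terminated by %s\n",
           "  incident %.4g mW, residual %.3g mW, force (%.3g, %.3g) N\n"),
    x$impact_parameter * 1e6, nrow(x$events), x$terminated_by,
    x$incident_power * 1e3, x$residual_power * 1e3, f[1], f[2]))
  invisible(x)
}

#' Start a ray inside the cylinder
#'
#' Entry point for studying trapped light: places a ray on the inner wall of
#' the cylinder and propagates it internally, so that sustained
#' total-internal-reflection chains — which external illumination of a
#' homogeneous circular section can only approach in the grazing limit —
#' can be produced and inspected directly.
#'
#' @param cyl a [cylinder_section()].
#' @param position_angle_deg angular position of the starting point on the
#'   circle, degrees counter-clockwise from +x.
#' @param direction_deg propagation direction, degrees counter-clockwise
#'   from +x; must point into the cylinder.
#' @param power ray power in watts.
#' @param polarization as in [incident_ray()].
#' @inheritParams trace_ray
#' @return A `ray_path` (the entry events are absent; the path starts with
#'   the first internal wall hit).
#' @examples
#' cyl <- cylinder_section(0.25e-6, 1.4, 1.33)
#' ## chord at 75 deg internal incidence: trapped, ends at the bounce cap
#' inject_internal_ray(cyl, 180, 75 - 0, power = 1e-3,
#'                     max_internal_bounces = 5)
#' @export
inject_internal_ray <- function(cyl, position_angle_deg, direction_deg,
                                power = 1, polarization = c("perpendicular",
                                                            "parallel"),
                                max_internal_bounces = 10,
                                power_cutoff_fraction = 1e-4) {
  stopifnot(inherits(cyl, "cylinder_section"))
  polarization <- match.arg(polarization)
  check_scalar(power, "power", lower = 0)
  a <- deg2rad(position_angle_deg)
  p <- cyl$radius * c(cos(a), sin(a))
  th <- deg2rad(direction_deg)
  d <- c(cos(th), sin(th))
  if (sum(d * p) >= 0)
    stop("`direction_deg` must point into the cylinder", call. = FALSE)
  loop <- .internal_loop(p, d, power, cyl$radius,
                         cyl$index_outside, cyl$index_inside,
                         polarization == "parallel",
                         max_internal_bounces,
                         power_cutoff_fraction * power,
                         list(), list())
  core <- list(events = loop$events, exits = loop$exits,
               residual = loop$residual, terminated = loop$terminated,
               miss = FALSE, incident_power = power)
  .as_ray_path(core, NA_real_, cyl, polarization)
}

#' Net force a traced ray exerts on the cylinder
#'
#' Vector sum of the per-event momentum transfers along a [trace_ray()]
#' path.  Equals, to within the tracker's power cutoff, the incident
#' momentum flux minus the total momentum flux of the exiting rays.
#'
#' @param path a `ray_path` from [trace_ray()] or [inject_internal_ray()].
#' @return Numeric length-2 vector `c(fx, fy)` in newtons: the propagation
#'   (+x) and transverse (+y) components.
#' @export
ray_force <- function(path) {
  stopifnot(inherits(path, "ray_path"))
  if (!nrow(path$events)) return(c(fx = 0, fy = 0))
  c(fx = sum(path$events$momentum_x), fy = sum(path$events$momentum_y))
}

#' Total photonic force of a flat beam on a cylinder cross-section
#'
#' Deterministic midpoint quadrature over impact parameters in `[-r, r]`:
#' the beam is decomposed into `n_rays` parallel rays, each carrying the
#' power of its quadrature cell under the chosen profile, traced with
#' [trace_ray()]'s machinery, and the per-ray forces are summed.
#'
#' @param beam_power total beam power in watts.
#' @param cyl a [cylinder_section()].
#' @param n_rays number of quadrature rays (>= 2).  The grid is graded as
#'   `b = r sin(psi)` with `psi` uniform, which removes the square-root
#'   cusp of the Fresnel coefficients at grazing incidence and makes the
#'   totals converge at second order in `1/n_rays`.
#' @param profile `"uniform"` (flat sheet across the cylinder) or
#'   `"gaussian"` (beam centred on the axis with standard deviation
#'   `sigma`; rays outside `[-r, r]` carry their power past the cylinder,
#'   so only the in-aperture fraction loads it).
#' @param sigma Gaussian profile standard deviation in metres (required for
#'   `profile = "gaussian"`).
#' @param polarization `"perpendicular"` (electric field along the cylinder
#'   axis, the default) or `"parallel"`.
#' @inheritParams trace_ray
#' @return An object of class `beam_cylinder_force`: `total_force`
#'   (`c(fx, fy)`, N), `per_ray` (data frame of impact parameter and force
#'   components), and `rays_traced`.
#' @examples
#' cyl <- cylinder_section(0.25e-6, 1.4, 1.33)
#' beam_force_on_cylinder(15e-3, cyl, n_rays = 201)
#' @export
beam_force_on_cylinder <- function(beam_power, cyl, n_rays = 1001,
                                   profile = c("uniform", "gaussian"),
                                   sigma = NULL,
                                   polarization = c("perpendicular",
                                                    "parallel"),
                                   max_internal_bounces = 10,
                                   power_cutoff_fraction = 1e-4) {
  stopifnot(inherits(cyl, "cylinder_section"))
  check_scalar(beam_power, "beam_power", lower = 0)
  check_scalar(n_rays, "n_rays", lower = 2)
  profile <- match.arg(profile)
  polarization <- match.arg(polarization)
  r <- cyl$radius
  ## graded grid b = r sin(psi): cell power is the profile density at b
  ## times the cell width r cos(psi) dpsi
  psi_edges <- seq(-pi / 2, pi / 2, length.out = n_rays + 1)
  psi <- (psi_edges[-1] + psi_edges[-length(psi_edges)]) / 2
  dpsi <- pi / n_rays
  b <- r * sin(psi)
  db <- r * cos(psi) * dpsi
  w <- if (profile == "uniform") {
    db / (2 * r)
  } else {
    check_scalar(sigma, "sigma", lower = 0, strict_lower = TRUE)
    stats::dnorm(b, mean = 0, sd = sigma) * db
  }
  pol_par <- polarization == "parallel"
  fx <- fy <- numeric(n_rays)
  for (i in seq_len(n_rays)) {
    pw <- beam_power * w[i]
    if (pw == 0) next
    core <- .trace_core(b[i], pw, pol_par, r,
                        cyl$index_outside, cyl$index_inside,
                        max_internal_bounces, power_cutoff_fraction,
                        mirror = cyl$perfect_mirror)
    for (ev in core$events) {
      fx[i] <- fx[i] + ev[9]
      fy[i] <- fy[i] + ev[10]
    }
  }
  structure(list(
    total_force = c(fx = sum(fx), fy = sum(fy)),
    per_ray = data.frame(impact_parameter = b, fx = fx, fy = fy),
    rays_traced = n_rays,
    beam_power = beam_power, profile = profile,
    polarization = polarization, cylinder = cyl),
    class = "beam_cylinder_force")
}

#' @export
print.beam_cylinder_force <- function(x, ...) {
  cat(sprintf(
    paste0("<beam_cylinder_force> %.4g mW %s beam, %d rays\n",
           "  total force (%.4g, %.4g) pN\n"),
    x$beam_power * 1e3, x$profile, x$rays_traced,
    x$total_force[1] * 1e12, x$total_force[2] * 1e12))
  invisible(x)
}

#' Classify ray fates across the beam aperture
#'
#' Samples impact parameters across (and slightly beyond) the cylinder and
#' labels each by the fate of its dominant transmitted ray: `"miss"`
#' (passes the cylinder), `"refract_through"` (enters and exits by
#' refraction), or `"tir_chain"` (the internal angle reaches the critical
#' angle, so the transmitted ray is trapped).  For a homogeneous circular
#' section illuminated externally the internal angle only reaches the
#' critical angle in the grazing limit `|b| -> r`, so the `tir_chain`
#' regime has measure zero on any finite grid.
#'
#' @param cyl a [cylinder_section()] with `index_inside > index_outside`.
#' @param n_samples number of impact parameters, spread over
#'   `[-1.2 r, 1.2 r]`.
#' @return Data frame with columns `impact_parameter` and `regime`.
#' @export
regime_map <- function(cyl, n_samples = 201) {
  stopifnot(inherits(cyl, "cylinder_section"))
  check_scalar(n_samples, "n_samples", lower = 1)
  if (cyl$index_inside <= cyl$index_outside)
    stop("regime classification assumes the cylinder is optically denser ",
         "than its surroundings", call. = FALSE)
  r <- cyl$radius
  b <- seq(-1.2 * r, 1.2 * r, length.out = n_samples)
  eta <- cyl$index_outside / cyl$index_inside
  sin_crit <- eta                          # sin of the internal critical angle
  regime <- vapply(b, function(bi) {
    if (abs(bi) > r) return("miss")
    sin_phi <- abs(bi) / r
    sin_int <- eta * sin_phi               # internal angle from Snell at entry
    if (sin_int >= sin_crit * (1 - 1e-12)) "tir_chain" else "refract_through"
  }, character(1))
  data.frame(impact_parameter = b, regime = regime)
}
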