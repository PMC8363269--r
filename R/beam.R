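#' Lensed fiber tip emitting a diverging light cone
#'
#' @param output_power power emitted at the tip, watts.
#' @param tip_spot_diameter light-spot diameter at the tip, metres.
#' @param divergence_full_angle full opening angle of the cone in the
#'   immersion medium, degrees (a hemispherical-lens tip in water diverges
#'   by about 11 degrees).
#' @return An object of class `fiber_tip`.
#' @examples
#' fiber_tip(15e-3, 5e-6, 11)
#' @export
fiber_tip <- function(output_power, tip_spot_diameter,
                      divergence_full_angle = 11) {
  check_scalar(output_power, "output_power", lower = 0, strict_lower = TRUE)
  check_scalar(tip_spot_diameter, "tip_spot_diameter",
               lower = 0, strict_lower = TRUE)
  check_scalar(divergence_full_angle, "divergence_full_angle",
               lower = 0, strict_lower = TRUE)
  if (divergence_full_angle >= 90)
    stop("`divergence_full_angle` must be < 90 degrees", call. = FALSE)
  structure(list(output_power = output_power,
                 tip_spot_diameter = tip_spot_diameter,
                 divergence_full_angle = divergence_full_angle),
            class = "fiber_tip")
}

#' @export
print.fiber_tip <- function(x, ...) {
  cat(sprintf("<fiber_tip> %.4g mW, %.4g um tip spot, %.4g deg full cone\n",
              x$output_power * 1e3, x$tip_spot_diameter * 1e6,
              x$divergence_full_angle))
  invisible(x)
}

#' Light-spot diameter at a distance from the fiber tip
#'
#' Straight-cone model: the 95%-power spot grows linearly with distance,
#' `D(d) = D_tip + 2 d tan(alpha / 2)` where `alpha` is the full divergence
#' angle.
#'
#' @param tip a [fiber_tip()].
#' @param distance axial distance(s) from the tip in metres (>= 0);
#'   vectorised.
#' @param half_angle set `TRUE` to interpret the stored divergence angle as
#'   the half angle instead of the full angle.
#' @return Spot diameter in metres.
#' @examples
#' tip <- fiber_tip(15e-3, 5e-6, 11)
#' spot_diameter(tip, 7e-6) * 1e6   # ~6.35 um at the 7-um working distance
#' @export
spot_diameter <- function(tip, distance, half_angle = FALSE) {
  stopifnot(inherits(tip, "fiber_tip"))
  if (!is.numeric(distance) || !length(distance) ||
      any(!is.finite(distance)) || any(distance < 0))
    stop("`distance` must be finite and >= 0", call. = FALSE)
  half <- if (half_angle) tip$divergence_full_angle
          else tip$divergence_full_angle / 2
  tip$tip_spot_diameter + 2 * distance * tan(deg2rad(half))
}

#' Recover cone divergence and tip diameter from spot measurements
#'
#' Least-squares line of spot diameter against distance, as measured by
#' withdrawing the fiber from a target in fixed steps and reading the
#' diameter containing 95% of the power at each separation.  The slope maps
#' to the full divergence angle via `alpha = 2 arctan(slope / 2)` and the
#' intercept is the tip spot diameter.
#'
#' @param points data frame with columns `distance` (m) and `diameter_95`
#'   (m); at least two distinct distances.
#' @return List with `full_angle` (degrees), `tip_diameter` (m),
#'   `fit_residual` (residual standard deviation, m; 0 for a 2-point fit),
#'   and the underlying `lm` fit.
#' @examples
#' tip <- fiber_tip(15e-3, 5e-6, 11)
#' d <- seq(0, 600e-6, by = 100e-6)
#' pts <- data.frame(distance = d, diameter_95 = spot_diameter(tip, d))
#' divergence_from_measurements(pts)$full_angle   # 11
#' @export
divergence_from_measurements <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("distance", "diameter_95") %in% names(points)))
    stop("`points` needs columns `distance` and `diameter_95`", call. = FALSE)
  if (length(unique(points$distance)) < 2)
    stop("need measurements at >= 2 distinct distances", call. = FALSE)
  fit <- stats::lm(diameter_95 ~ distance, data = points)
  slope <- unname(stats::coef(fit)[2])
  list(full_angle = rad2deg(2 * atan(slope / 2)),
       tip_diameter = unname(stats::coef(fit)[1]),
       fit_residual = stats::sigma(fit),
       fit = fit)
}

#' Irradiance at a distance from the fiber tip
#'
#' Power per unit area on the 95%-power disc, treating that disc as
#' uniformly illuminated: `I = 0.95 P / (pi (D/2)^2)` with `D` the spot
#' diameter at the given distance.
#'
#' @inheritParams spot_diameter
#' @return Irradiance in watts per square metre.
#' @examples
#' tip <- fiber_tip(15e-3, 5e-6, 11)
#' irradiance_at(tip, 7e-6)    # ~4.5e8 W/m^2
#' @export
irradiance_at <- function(tip, distance, half_angle = FALSE) {
  d95 <- spot_diameter(tip, distance, half_angle = half_angle)
  0.95 * tip$output_power / (pi * (d95 / 2)^2)
}
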