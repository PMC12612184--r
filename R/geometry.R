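# Spherical-cap geometry and keratometric conversion for inflated chip wells.
#
# A well of radius a holds a pressurised PDMS membrane that bulges into a
# spherical cap. Side-view imaging measures the chord angle phi between the
# horizontal baseline and the rim-to-apex chord; for a spherical cap the cap
# half-angle at the sphere centre is theta = 2*phi (tan phi = h/a =
# tan(theta/2)). All other descriptors follow from (phi, a).

#' Keratometric constant (diopter * mm)
#'
#' Optical power of a spherical refracting surface under the standard
#' keratometric index 1.3375: `D = 1000 * (1.3375 - 1) / R` with `R` in mm,
#' i.e. `D = 337.5 / R`.
#' @export
KERATOMETRIC_CONSTANT <- 337.5

#' Spherical-cap dome geometry from a measured chord angle
#'
#' Converts the side-view chord angle of an inflated well into the full
#' spherical-cap description: cap half-angle, radius of curvature,
#' keratometric power, apex height and cap volume.
#'
#' @param phi_deg chord angle between baseline and rim-to-apex chord, degrees.
#'   `0` is the flat control. Must satisfy `0 <= phi_deg < 45` (a cap at most
#'   a hemisphere).
#' @param well_radius_mm well (clamp) radius `a` in mm; default 4 mm, the
#'   8 mm-diameter chamber of the chip.
#' @return An object of class `dome_geometry`: a list with fields
#'   `well_radius_a` (mm), `chord_angle_phi` (deg), `half_angle_theta` (deg),
#'   `radius_R` (mm; `Inf` when flat), `apex_height_h` (mm), `power_D`
#'   (diopters) and `cap_volume` (uL).
#' @details The flat control (`phi_deg = 0`) is a valid degenerate geometry
#'   with infinite radius of curvature, zero power, zero height and zero
#'   volume. Power is `337.5 / R`; cap volume is `(pi h / 6) (3 a^2 + h^2)`
#'   with 1 mm^3 = 1 uL.
#' @examples
#' angle_to_geometry(15, 4)       # medium curvature: R = 8 mm, ~42.19 D
#' angle_to_geometry(11.79, 4)    # low curvature: ~33.75 D
#' @export
angle_to_geometry <- function(phi_deg, well_radius_mm = 4) {
  stopifnot(length(phi_deg) == 1L, length(well_radius_mm) == 1L)
  if (!is.finite(well_radius_mm) || well_radius_mm <= 0)
    stop("well_radius_mm must be a positive length (mm)")
  if (!is.finite(phi_deg) || phi_deg < 0)
    stop("phi_deg must be a finite angle >= 0")
  if (phi_deg >= 45)
    stop("phi_deg >= 45 deg: cap would exceed a hemisphere for this parameterization")
  a <- well_radius_mm
  theta <- 2 * phi_deg
  if (phi_deg == 0) {
    geom <- list(well_radius_a = a, chord_angle_phi = 0, half_angle_theta = 0,
                 radius_R = Inf, apex_height_h = 0, power_D = 0, cap_volume = 0)
    class(geom) <- "dome_geometry"
    return(geom)
  }
  th <- theta * pi / 180
  R <- a / sin(th)
  h <- R * (1 - cos(th))
  D <- KERATOMETRIC_CONSTANT / R
  V <- (pi * h / 6) * (3 * a^2 + h^2)
  geom <- list(well_radius_a = a, chord_angle_phi = phi_deg,
               half_angle_theta = theta, radius_R = R, apex_height_h = h,
               power_D = D, cap_volume = V)
  class(geom) <- "dome_geometry"
  geom
}

#' @export
print.dome_geometry <- function(x, ...) {
  cat("Spherical-cap dome geometry\n")
  cat(sprintf("  well radius a      : %.3f mm\n", x$well_radius_a))
  cat(sprintf("  chord angle phi    : %.2f deg\n", x$chord_angle_phi))
  cat(sprintf("  cap half-angle     : %.2f deg\n", x$half_angle_theta))
  cat(sprintf("  radius of curvature: %s mm\n",
              if (is.finite(x$radius_R)) sprintf("%.3f", x$radius_R) else "Inf (flat)"))
  cat(sprintf("  keratometric power : %.2f D\n", round(x$power_D, 2)))
  cat(sprintf("  apex height h      : %.3f mm\n", x$apex_height_h))
  cat(sprintf("  cap volume         : %.2f uL\n", x$cap_volume))
  invisible(x)
}

#' @export
as.data.frame.dome_geometry <- function(x, ...) {
  data.frame(phi_deg = x$chord_angle_phi, theta_deg = x$half_angle_theta,
             R_mm = x$radius_R, D = x$power_D, h_mm = x$apex_height_h,
             V_uL = x$cap_volume)
}

#' Radius of curvature to keratometric diopters
#'
#' @param radius_mm radius of curvature in mm (positive).
#' @return optical power in diopters, `337.5 / radius_mm`.
#' @examples
#' radius_to_diopters(7.8)  # ~43 D, a healthy cornea
#' @export
radius_to_diopters <- function(radius_mm) {
  if (any(!is.finite(radius_mm)) || any(radius_mm <= 0))
    stop("radius_mm must be positive and finite")
  KERATOMETRIC_CONSTANT / radius_mm
}

#' Keratometric diopters to chord angle
#'
#' Inverse of [angle_to_geometry()] for the power field: recovers the chord
#' angle that produces a given keratometric power at a given well radius.
#'
#' @param power_D optical power in diopters, `>= 0`.
#' @param well_radius_mm well radius `a` in mm.
#' @return chord angle phi in degrees.
#' @export
diopters_to_angle <- function(power_D, well_radius_mm = 4) {
  stopifnot(length(power_D) == 1L)
  if (!is.finite(power_D) || power_D < 0)
    stop("power_D must be finite and >= 0")
  if (!is.finite(well_radius_mm) || well_radius_mm <= 0)
    stop("well_radius_mm must be a positive length (mm)")
  if (power_D == 0) return(0)
  s <- well_radius_mm * power_D / KERATOMETRIC_CONSTANT  # sin(theta)
  if (s > 1)
    stop("power_D out of representable range: cap would exceed a hemisphere")
  asin(s) * 180 / pi / 2
}

#' Spherical-cap volume displaced by one well
#'
#' @inheritParams angle_to_geometry
#' @return cap volume in uL (1 mm^3 = 1 uL). Strictly increasing in
#'   `phi_deg` at fixed well radius. Note this is the geometric volume of one
#'   dome; injected syringe volumes additionally include manifold dead volume
#'   shared across wells and are treated as empirical calibration data.
#' @export
cap_volume <- function(phi_deg, well_radius_mm = 4) {
  angle_to_geometry(phi_deg, well_radius_mm)$cap_volume
}
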