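# Axisymmetric inflation of a clamped circular elastic membrane.
#
# The chip membrane is a flat PDMS disc of radius a and thickness t0 clamped
# at its rim and inflated by uniform pressure p. The deformed mid-surface is
# described in material coordinates r0 in [0, a] by the deformed radius
# rho(r0), height w(r0) and meridian slope angle psi(r0); stretches are
# lam1 = ds/dr0 (meridional) and lam2 = rho/r0 (hoop). Membrane equilibrium
# on the deformed surface reads
#
#   T_m * kappa_m + T_h * kappa_h = p          (normal, Laplace)
#   d(rho T_m)/dr0 = T_h d(rho)/dr0            (meridional, tangential)
#
# with kappa_m = dpsi/ds, kappa_h = sin(psi)/rho, and tensions T_i
# (force/length) from the constitutive law. The two-point boundary-value
# problem (regular apex, zero radial displacement at the clamp, rho(a) = a)
# is solved by shooting on the apex stretch.

#' Membrane specification for inflation analysis
#'
#' @param radius_a_mm clamped (well) radius in mm.
#' @param thickness_um undeformed membrane thickness in micrometres.
#' @param youngs_kpa Young's modulus in kPa (PDMS membrane: ~530 kPa).
#' @param poisson Poisson ratio; values above 0.4999 are clamped to 0.4999
#'   for numerical stability. Only used by the `"linear"` material; the
#'   default neo-Hookean model is incompressible.
#' @param pressure_kpa inflation pressure in kPa. Give exactly one of
#'   `pressure_kpa` or `target_apex_mm`.
#' @param target_apex_mm apex height to match (mm); the pressure is then
#'   found by [solve_for_apex_angle()].
#' @return object of class `membrane_spec`.
#' @export
membrane_spec <- function(radius_a_mm = 4, thickness_um = 100,
                          youngs_kpa = 530, poisson = 0.49,
                          pressure_kpa = NULL, target_apex_mm = NULL) {
  if (radius_a_mm <= 0 || thickness_um <= 0 || youngs_kpa <= 0)
    stop("radius, thickness and modulus must be positive")
  if (poisson < 0) stop("poisson must be >= 0")
  poisson <- min(poisson, 0.4999)
  if (is.null(pressure_kpa) == is.null(target_apex_mm))
    stop("give exactly one of pressure_kpa or target_apex_mm")
  if (!is.null(pressure_kpa) && pressure_kpa < 0)
    stop("pressure_kpa must be >= 0")
  if (!is.null(target_apex_mm) &&
      (target_apex_mm < 0 || target_apex_mm >= radius_a_mm))
    stop("target_apex_mm must lie in [0, radius_a_mm)")
  structure(list(radius_a_mm = radius_a_mm,
                 thickness_mm = thickness_um / 1000,
                 youngs_kpa = youngs_kpa, poisson = poisson,
                 pressure_kpa = pressure_kpa,
                 target_apex_mm = target_apex_mm),
            class = "membrane_spec")
}

# Tensions (kPa*mm) and their partial derivatives wrt the stretches.
# neo-Hookean: incompressible, shear modulus mu = E/3, plane stress through
# the thickness; linear: small-strain Hooke with Poisson ratio nu.
.tension_fun <- function(material, E, t0, nu) {
  if (material == "neo-hookean") {
    mu <- E / 3
    list(
      T = function(li, lj) mu * t0 * (li / lj - li^-3 * lj^-3),
      dT_dli = function(li, lj) mu * t0 * (1 / lj + 3 * li^-4 * lj^-3),
      dT_dlj = function(li, lj) mu * t0 * (-li / lj^2 + 3 * li^-3 * lj^-4)
    )
  } else {
    C <- E * t0 / (1 - nu^2)
    list(
      T = function(li, lj) C * ((li - 1) + nu * (lj - 1)),
      dT_dli = function(li, lj) C + 0 * li,
      dT_dlj = function(li, lj) C * nu + 0 * li
    )
  }
}

# Integrate the membrane ODE system for a trial apex stretch lam0.
# Returns the deSolve matrix or NULL on blow-up.
.integrate_membrane <- function(lam0, p, a, tf, r_out) {
  eps <- r_out[1]
  T0 <- tf$T(lam0, lam0)
  if (!is.finite(T0) || T0 <= 0) return(NULL)
  kappa0 <- p / (2 * T0)
  y0 <- c(psi = kappa0 * lam0 * eps, w = 0, lam1 = lam0, lam2 = lam0)
  rhs <- function(r0, y, parms) {
    psi <- min(y[1], 1.55); lam1 <- max(y[3], 1e-8); lam2 <- max(y[4], 1e-8)
    rho <- lam2 * r0
    T1 <- max(tf$T(lam1, lam2), 1e-12)
    T2 <- tf$T(lam2, lam1)
    lam2p <- (lam1 * cos(psi) - lam2) / r0
    psip <- lam1 * (p - T2 * sin(psi) / rho) / T1
    wp <- -lam1 * sin(psi)
    lam1p <- ((T2 - T1) * lam1 * cos(psi) / rho -
                tf$dT_dlj(lam1, lam2) * lam2p) / tf$dT_dli(lam1, lam2)
    list(c(psip, wp, lam1p, lam2p))
  }
  # terminate the trial when the meridian passes vertical or the state
  # degenerates: that apex stretch is rejected by the shooting residual
  rootfun <- function(r0, y, parms)
    c(1.5 - y[1], y[3] - 1e-6, y[4] - 1e-6, tf$T(max(y[3], 1e-8), max(y[4], 1e-8)) - 1e-10)
  out <- try(suppressWarnings(
    deSolve::lsodar(y0, r_out, rhs, parms = NULL, rootfunc = rootfun,
                    rtol = 1e-10, atol = 1e-12)), silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  if (nrow(out) < length(r_out) || anyNA(out[nrow(out), ])) return(NULL)
  out
}

#' Solve clamped-membrane inflation
#'
#' Computes deflection and the meridional/hoop Cauchy stress profiles of a
#' flat circular membrane clamped at its rim and inflated by uniform
#' pressure, by shooting on the apex stretch of the finite-deformation
#' axisymmetric membrane equations.
#'
#' @param spec a [membrane_spec()] with `pressure_kpa` set.
#' @param n_grid number of radial output points (>= 50).
#' @param material `"neo-hookean"` (incompressible, default; appropriate for
#'   PDMS) or `"linear"` (small-strain Hooke, mainly for cross-checks against
#'   small-deflection theory).
#' @return object of class `stress_profile`: a list with vectors `r_mm`
#'   (deformed radial position), `sigma_m_kpa`, `sigma_h_kpa` (Cauchy
#'   stresses), `w_mm` (height above the clamp plane), `psi_rad`, `s_mm`
#'   (deformed arc length from the apex), `lam1`, `lam2`, scalars
#'   `pressure_kpa`, `apex_height_mm`, `wrinkled` (TRUE if hoop stress
#'   becomes non-positive anywhere), and `region_means` from
#'   [region_partition()] with default center/slope/edge bounds a/3, 2a/3.
#' @export
solve_inflation <- function(spec, n_grid = 201, material = c("neo-hookean", "linear")) {
  stopifnot(inherits(spec, "membrane_spec"))
  material <- match.arg(material)
  if (is.null(spec$pressure_kpa))
    stop("spec must carry pressure_kpa (use solve_for_apex_angle for a height target)")
  if (n_grid < 50) stop("n_grid must be >= 50")
  a <- spec$radius_a_mm; t0 <- spec$thickness_mm; p <- spec$pressure_kpa
  if (p == 0) {
    z <- numeric(n_grid)
    prof <- structure(list(r_mm = seq(0, a, length.out = n_grid),
                           sigma_m_kpa = z, sigma_h_kpa = z, w_mm = z,
                           psi_rad = z, s_mm = seq(0, a, length.out = n_grid),
                           lam1 = z + 1, lam2 = z + 1,
                           pressure_kpa = 0, apex_height_mm = 0,
                           thickness_mm = t0, material = material,
                           spec = spec, wrinkled = FALSE),
                      class = "stress_profile")
    prof$region_means <- region_partition(prof, c(a / 3, 2 * a / 3))
    return(prof)
  }
  tf <- .tension_fun(material, spec$youngs_kpa, t0, spec$poisson)
  r_out <- c(a * 1e-7, seq(a / (n_grid - 1), a, length.out = n_grid - 1))
  shoot <- function(lam0) {
    out <- .integrate_membrane(lam0, p, a, tf, r_out)
    if (is.null(out)) return(-1)  # blow-up: membrane curled over, rim undershoots
    out[nrow(out), "lam2"] - 1
  }
  # bracket the apex stretch: small lam0 -> curled (f < 0), large -> overstretched
  lo <- NA; hi <- NA; lam <- 1 + 1e-6
  f_prev <- shoot(lam)
  for (i in 1:80) {
    lam_next <- 1 + (lam - 1) * 1.6
    f_next <- shoot(lam_next)
    if (f_prev < 0 && f_next >= 0) { lo <- lam; hi <- lam_next; break }
    if (f_prev >= 0 && f_next < 0) { lo <- lam_next; hi <- lam; break }
    lam <- lam_next; f_prev <- f_next
    if (lam - 1 > 50) break
  }
  if (is.na(lo))
    stop("inflation solver failed to bracket the apex stretch; ",
         "pressure may exceed the representable (sub-hemisphere) range")
  root <- stats::uniroot(shoot, c(lo, hi), tol = 1e-13)
  out <- .integrate_membrane(root$root, p, a, tf, r_out)
  if (is.null(out)) stop("inflation solver failed to converge")
  psi <- out[, "psi"]; w <- out[, "w"]
  lam1 <- out[, "lam1"]; lam2 <- out[, "lam2"]
  rho <- lam2 * r_out
  T1 <- tf$T(lam1, lam2); T2 <- tf$T(lam2, lam1)
  # Cauchy stress = tension / deformed thickness; incompressible thinning
  t_loc <- t0 / (lam1 * lam2)
  sig_m <- T1 / t_loc; sig_h <- T2 / t_loc
  # deformed arc length from the apex (trapezoid on ds = lam1 dr0)
  s <- cumsum(c(0, diff(r_out) * (lam1[-1] + lam1[-length(lam1)]) / 2))
  prof <- structure(list(r_mm = rho, sigma_m_kpa = sig_m, sigma_h_kpa = sig_h,
                         w_mm = w - w[length(w)], psi_rad = psi, s_mm = s,
                         lam1 = lam1, lam2 = lam2,
                         pressure_kpa = p,
                         apex_height_mm = w[1] - w[length(w)],
                         thickness_mm = t0, material = material, spec = spec,
                         wrinkled = any(sig_h <= 0)),
                    class = "stress_profile")
  prof$region_means <- region_partition(prof, c(a / 3, 2 * a / 3))
  prof
}

#' @export
print.stress_profile <- function(x, ...) {
  cat(sprintf("Inflated membrane profile (%s): p = %.4g kPa, apex height = %.4g mm\n",
              x$material, x$pressure_kpa, x$apex_height_mm))
  if (isTRUE(x$wrinkled))
    cat("  note: hoop stress reaches zero (wrinkling not modelled)\n")
  print(x$region_means)
  invisible(x)
}

#' @export
as.data.frame.stress_profile <- function(x, ...) {
  data.frame(r_mm = x$r_mm, sigma_m_kpa = x$sigma_m_kpa,
             sigma_h_kpa = x$sigma_h_kpa, w_mm = x$w_mm)
}

#' Area-weighted region summaries of a stress profile
#'
#' Partitions the membrane into center (A1), slope (A2) and edge (A3)
#' annuli and reports area-weighted mean meridional and hoop stresses plus
#' their ratio in percent per region.
#'
#' @param profile a `stress_profile`.
#' @param bounds two radii `(r1, r2)` in mm with `0 < r1 < r2 < a`, measured
#'   in the deformed radial coordinate; A1 = \[0, r1), A2 = \[r1, r2),
#'   A3 = \[r2, a\].
#' @return data.frame with one row per region: `region`, `r_lo`, `r_hi`,
#'   `sigma_m_kpa`, `sigma_h_kpa`, `ratio_pct` (100 * mean sigma_m / mean
#'   sigma_h; NA when the mean hoop stress is not positive).
#' @export
region_partition <- function(profile, bounds) {
  stopifnot(inherits(profile, "stress_profile"), length(bounds) == 2)
  a <- max(profile$r_mm)
  if (!(0 < bounds[1] && bounds[1] < bounds[2] && bounds[2] < a))
    stop("bounds must satisfy 0 < r1 < r2 < a")
  # area-weighted annulus mean by trapezoid integration of sigma * r dr,
  # with the annulus boundaries inserted as exact interpolation nodes
  edges <- c(0, bounds, a)
  trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  res <- lapply(1:3, function(i) {
    rg <- sort(unique(c(edges[i], edges[i + 1],
                        profile$r_mm[profile$r_mm > edges[i] &
                                       profile$r_mm < edges[i + 1]])))
    sm <- stats::approx(profile$r_mm, profile$sigma_m_kpa, rg, rule = 2)$y
    sh <- stats::approx(profile$r_mm, profile$sigma_h_kpa, rg, rule = 2)$y
    denom <- trapz(rg, rg)
    m_m <- trapz(rg, sm * rg) / denom
    m_h <- trapz(rg, sh * rg) / denom
    data.frame(region = c("A1", "A2", "A3")[i],
               r_lo = edges[i], r_hi = edges[i + 1],
               sigma_m_kpa = m_m, sigma_h_kpa = m_h,
               ratio_pct = if (m_h > 0) 100 * m_m / m_h else NA_real_)
  })
  do.call(rbind, res)
}

#' Pointwise Laplace-equilibrium residual of a solved profile
#'
#' Recomputes the normal-equilibrium balance `sigma_m * kappa_m + sigma_h *
#' kappa_h = p / t` from the returned fields (meridional curvature by spline
#' differentiation of the slope angle along the deformed arc length, local
#' thickness from the stretches) and returns the relative residual at
#' interior grid points.
#'
#' @param profile a converged `stress_profile` with positive pressure.
#' @return numeric vector of `|lhs - p/t| / (p/t)` at interior points.
#' @export
equilibrium_residual <- function(profile) {
  stopifnot(inherits(profile, "stress_profile"))
  p <- profile$pressure_kpa
  if (p <= 0) stop("residual is defined for a pressurised profile")
  idx <- 2:(length(profile$s_mm) - 1)
  psi_s <- stats::splinefun(profile$s_mm, profile$psi_rad)
  kap_m <- psi_s(profile$s_mm[idx], deriv = 1)
  kap_h <- sin(profile$psi_rad[idx]) / profile$r_mm[idx]
  t_loc <- profile$thickness_mm / (profile$lam1[idx] * profile$lam2[idx])
  rhs <- p / t_loc
  abs(profile$sigma_m_kpa[idx] * kap_m + profile$sigma_h_kpa[idx] * kap_h - rhs) / rhs
}

#' Find the pressure that inflates the membrane to a target apex height
#'
#' Root-finds on pressure so that the solved profile's apex height matches
#' `spec$target_apex_mm`, typically taken from [angle_to_geometry()] so the
#' mechanical state corresponds to a measured dome angle.
#'
#' @param spec a [membrane_spec()] with `target_apex_mm` set.
#' @param n_grid,material passed to [solve_inflation()].
#' @param tol_mm absolute tolerance on the apex height (default 1e-4 * a).
#' @return list with `pressure_kpa` and the matched `profile`.
#' @export
solve_for_apex_angle <- function(spec, n_grid = 201,
                                 material = c("neo-hookean", "linear"),
                                 tol_mm = NULL) {
  stopifnot(inherits(spec, "membrane_spec"))
  material <- match.arg(material)
  if (is.null(spec$target_apex_mm))
    stop("spec must carry target_apex_mm")
  h_tgt <- spec$target_apex_mm
  a <- spec$radius_a_mm
  if (is.null(tol_mm)) tol_mm <- 1e-4 * a
  if (h_tgt == 0) {
    sp0 <- spec; sp0$target_apex_mm <- NULL; sp0$pressure_kpa <- 0
    return(list(pressure_kpa = 0, profile = solve_inflation(sp0, n_grid, material)))
  }
  solve_at <- function(p) {
    sp <- spec; sp$target_apex_mm <- NULL; sp$pressure_kpa <- p
    solve_inflation(sp, n_grid, material)
  }
  # initial scale from the small-deflection cube law h ~ 0.65 a (p a / E t)^(1/3)
  p_guess <- spec$youngs_kpa * spec$thickness_mm / a * (h_tgt / (0.65 * a))^3
  p_lo <- p_guess; p_hi <- p_guess
  h_lo <- solve_at(p_lo)$apex_height_mm
  for (i in 1:60) { if (h_lo < h_tgt) break; p_lo <- p_lo / 2
                    h_lo <- solve_at(p_lo)$apex_height_mm }
  h_hi <- solve_at(p_hi)$apex_height_mm
  ok <- FALSE
  for (i in 1:60) {
    if (h_hi > h_tgt) { ok <- TRUE; break }
    p_hi <- p_hi * 2
    h_hi <- try(solve_at(p_hi)$apex_height_mm, silent = TRUE)
    if (inherits(h_hi, "try-error")) break
  }
  if (!ok) stop("target apex height unattainable below the hemisphere limit")
  root <- stats::uniroot(function(p) solve_at(p)$apex_height_mm - h_tgt,
                         c(p_lo, p_hi), tol = p_guess * 1e-9)
  prof <- solve_at(root$root)
  if (abs(prof$apex_height_mm - h_tgt) > tol_mm)
    stop("apex-height matching did not reach tolerance")
  list(pressure_kpa = root$root, profile = prof)
}

#' Plot meridional and hoop stress profiles
#'
#' @param x a `stress_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.stress_profile <- function(x, ...) {
  graphics::plot(x$r_mm, x$sigma_h_kpa, type = "l", lty = 2,
                 xlab = "radius (mm)", ylab = "Cauchy stress (kPa)",
                 ylim = range(c(x$sigma_m_kpa, x$sigma_h_kpa)), ...)
  graphics::lines(x$r_mm, x$sigma_m_kpa, lty = 1)
  graphics::legend("bottomleft", legend = c("meridional", "hoop"), lty = 1:2,
                   bty = "n")
  graphics::abline(v = x$region_means$r_hi[1:2], col = "grey70")
  invisible(x)
}
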