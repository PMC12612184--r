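# Fixtures and independent oracles shared across the suite.

# Sinusoidal stripe pattern whose fiber axis lies at th_deg (math
# convention: x right, y up, degrees CCW from +x). Intensity varies along
# the stripe normal.
stripes <- function(th_deg, n = 256, period = 12) {
  th <- th_deg * pi / 180
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(rev(seq_len(n)), n, n)
  u <- -x * sin(th) + y * cos(th)
  0.5 + 0.5 * cos(2 * pi * u / period)
}

# Independent small-slope membrane oracle: the Foeppl (Hencky-type) problem
#   r^2 sigma'' + 3 r sigma' + E p^2 r^2 / (8 t^2 sigma^2) = 0
#   sigma'(0) = 0;  a sigma'(a) + (1 - nu) sigma(a) = 0   (clamped rim)
#   w' = -p r / (2 t sigma),  apex deflection w0 = integral of -w'
# solved by fixed-step RK4 shooting on the apex radial stress. Completely
# separate equations and integrator from the package solver.
fvk_apex_deflection <- function(p, a, t, E, nu, n_steps = 4000) {
  deriv <- function(r, y) {
    c(y[2], -(3 / r) * y[2] - E * p^2 / (8 * t^2 * y[1]^2))
  }
  integrate_rk4 <- function(s0) {
    eps <- a * 1e-6
    c2 <- -E * p^2 / (64 * t^2 * s0^2)
    y <- c(s0 + c2 * eps^2, 2 * c2 * eps)
    h <- (a - eps) / n_steps
    r <- eps
    sig <- numeric(n_steps + 1); rr <- numeric(n_steps + 1)
    sig[1] <- y[1]; rr[1] <- r
    for (i in seq_len(n_steps)) {
      k1 <- deriv(r, y)
      k2 <- deriv(r + h / 2, y + h / 2 * k1)
      k3 <- deriv(r + h / 2, y + h / 2 * k2)
      k4 <- deriv(r + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      r <- r + h
      sig[i + 1] <- y[1]; rr[i + 1] <- r
    }
    list(bc = a * y[2] + (1 - nu) * y[1], sigma = sig, r = rr)
  }
  s_scale <- (E * p^2 * a^2 / t^2)^(1 / 3)
  bc_of <- function(s0) {
    v <- integrate_rk4(s0)$bc
    if (!is.finite(v)) -1e6 else v
  }
  root <- stats::uniroot(bc_of, c(0.05 * s_scale, 5 * s_scale), tol = 1e-12)$root
  sol <- integrate_rk4(root)
  integrand <- p * sol$r / (2 * t * sol$sigma)
  sum(diff(sol$r) * (integrand[-1] + integrand[-length(integrand)]) / 2)
}

# Axial von Mises window mass, written out from the density
# f(theta) = exp(kappa cos 2 theta) / (pi I0(kappa)) per radian on
# (-pi/2, pi/2]; independent of the package's density function.
vm_mass_in_window <- function(kappa, half_width_deg = 10) {
  f <- function(th) exp(kappa * cos(2 * th)) / (pi * besselI(kappa, 0))
  w <- half_width_deg * pi / 180
  stats::integrate(f, -w, w)$value
}

# Paint a filled rotated ellipse with the given label into a matrix
# (semi-axes in px, th_deg CCW from +x with y up).
paint_ellipse <- function(lab, cx, cy, a_semi, b_semi, th_deg, id) {
  n <- nrow(lab)
  th <- th_deg * pi / 180
  half <- max(a_semi, b_semi) + 2
  rows <- max(1, floor(n - (cy + half) + 1)):min(n, ceiling(n - (cy - half) + 1))
  cols <- max(1, floor(cx - half)):min(ncol(lab), ceiling(cx + half))
  x <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
  y <- matrix(n - rows + 1, length(rows), length(cols)) - cy
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  inside <- (u / a_semi)^2 + (v / b_semi)^2 <= 1
  block <- lab[rows, cols]
  block[inside] <- id
  lab[rows, cols] <- block
  lab
}

# disc mask helper (pixel grid, center at image center)
disc_mask <- function(n_px, radius_px) {
  ctr <- (n_px + 1) / 2
  outer(seq_len(n_px) - ctr, seq_len(n_px) - ctr,
        function(dr, dc) sqrt(dr^2 + dc^2)) <= radius_px
}
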