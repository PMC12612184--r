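# Clamped-membrane inflation: equilibrium, oracles, region summaries.

test_that("unpressurised membrane is flat and stress-free", {
  pr <- solve_inflation(membrane_spec(pressure_kpa = 0))
  expect_equal(max(abs(pr$w_mm)), 0)
  expect_equal(max(abs(pr$sigma_m_kpa)), 0)
  expect_equal(max(abs(pr$sigma_h_kpa)), 0)
  expect_equal(pr$apex_height_mm, 0)
})

test_that("converged solutions satisfy apex isotropy and Laplace equilibrium", {
  pr <- solve_inflation(membrane_spec(pressure_kpa = 2))
  expect_lt(abs(pr$sigma_m_kpa[1] / pr$sigma_h_kpa[1] - 1), 1e-6)
  expect_lt(max(equilibrium_residual(pr)), 1e-3)
  # clamped rim: zero radial displacement
  expect_equal(pr$r_mm[length(pr$r_mm)], 4, tolerance = 1e-9)
  # meridional-to-hoop ratio grows monotonically from center to edge
  ratio <- pr$sigma_m_kpa / pr$sigma_h_kpa
  expect_true(all(diff(ratio) > -1e-9))
  expect_false(pr$wrinkled)
})

test_that("grid refinement and p,E rescaling leave the solution invariant", {
  p1 <- solve_inflation(membrane_spec(pressure_kpa = 1), n_grid = 101)
  p2 <- solve_inflation(membrane_spec(pressure_kpa = 1), n_grid = 201)
  expect_lt(abs(p2$apex_height_mm / p1$apex_height_mm - 1), 1e-3)
  # geometry depends only on p/E; stresses scale with the common factor
  p3 <- solve_inflation(membrane_spec(pressure_kpa = 3, youngs_kpa = 3 * 530))
  p1b <- solve_inflation(membrane_spec(pressure_kpa = 1, youngs_kpa = 530))
  expect_equal(p3$apex_height_mm, p1b$apex_height_mm, tolerance = 1e-8)
  expect_equal(p3$sigma_m_kpa, 3 * p1b$sigma_m_kpa, tolerance = 1e-7)
})

test_that("small-pressure apex deflection matches independent small-slope theory", {
  p <- 0.003  # apex deflection ~ 0.036 a: small-slope regime
  w_oracle <- fvk_apex_deflection(p, a = 4, t = 0.1, E = 530, nu = 0.5)
  pr <- solve_inflation(membrane_spec(pressure_kpa = p))
  expect_lt(abs(pr$apex_height_mm / w_oracle - 1), 0.01)
  prl <- solve_inflation(membrane_spec(pressure_kpa = p, poisson = 0.5),
                         material = "linear")
  expect_lt(abs(prl$apex_height_mm / w_oracle - 1), 0.01)
})

test_that("region partition reproduces analytic annulus averages", {
  # hand-built profiles on a uniform radius grid
  fake <- function(sig_m, sig_h, r) {
    structure(list(r_mm = r, sigma_m_kpa = sig_m, sigma_h_kpa = sig_h),
              class = "stress_profile")
  }
  r <- seq(0, 4, length.out = 8001)
  u <- fake(rep(7, length(r)), rep(7, length(r)), r)
  rm <- region_partition(u, c(4 / 3, 8 / 3))
  expect_equal(rm$ratio_pct, rep(100, 3), tolerance = 1e-12)
  expect_equal(rm$sigma_m_kpa, rep(7, 3), tolerance = 1e-12)
  # linear ramp sigma_m = c1 * r: annulus mean = 2 c1 (r2^3 - r1^3) / (3 (r2^2 - r1^2))
  c1 <- 2.5
  lin <- fake(c1 * r, rep(4, length(r)), r)
  rm <- region_partition(lin, c(1, 3))
  analytic <- function(r1, r2) 2 * c1 * (r2^3 - r1^3) / (3 * (r2^2 - r1^2))
  expect_equal(rm$sigma_m_kpa, c(analytic(0, 1), analytic(1, 3), analytic(3, 4)),
               tolerance = 1e-6)
  expect_equal(rm$ratio_pct, 100 * rm$sigma_m_kpa / 4, tolerance = 1e-9)
  expect_error(region_partition(u, c(3, 1)), "bounds")
})

test_that("pressure matching recovers the dome apex height of a measured angle", {
  h_tgt <- angle_to_geometry(15, 4)$apex_height_h  # 8 (1 - cos 30 deg)
  m <- solve_for_apex_angle(membrane_spec(target_apex_mm = h_tgt), n_grid = 121)
  expect_lt(abs(m$profile$apex_height_mm - h_tgt), 1e-4 * 4)
  expect_gt(m$pressure_kpa, 0)
  # a taller dome needs more pressure
  m2 <- solve_for_apex_angle(
    membrane_spec(target_apex_mm = angle_to_geometry(20.91, 4)$apex_height_h),
    n_grid = 121)
  expect_gt(m2$pressure_kpa, m$pressure_kpa)
  # zero target is the flat state
  m0 <- solve_for_apex_angle(membrane_spec(target_apex_mm = 0))
  expect_equal(m0$pressure_kpa, 0)
})

test_that("membrane specification is validated", {
  expect_error(membrane_spec(pressure_kpa = 1, target_apex_mm = 1), "exactly one")
  expect_error(membrane_spec(), "exactly one")
  expect_error(membrane_spec(radius_a_mm = -1, pressure_kpa = 1), "positive")
  expect_error(membrane_spec(target_apex_mm = 5), "lie in")
  expect_error(solve_inflation(membrane_spec(pressure_kpa = 1), n_grid = 10),
               "n_grid")
})
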