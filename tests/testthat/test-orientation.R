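# Structure-tensor orientation: equivariance, histograms, crossing angles.

test_that("stripe fixtures recover programmed fiber angles equivariantly", {
  base <- 10
  for (delta in c(0, 15, 30, 45)) {
    h <- build_histogram(orientation_field(stripes(base + delta)))
    d <- abs(h$peaks$angle[1] - (base + delta)) %% 180
    expect_lte(min(d, 180 - d), 1)  # within one 1-degree bin
  }
  # angles wrap axially at the -90/+90 seam
  h <- build_histogram(orientation_field(stripes(-88)))
  d <- abs(h$peaks$angle[1] - (-88)) %% 180
  expect_lte(min(d, 180 - d), 1)
})

test_that("histogram peak normalisation and degenerate inputs behave", {
  h <- build_histogram(orientation_field(stripes(30)))
  expect_equal(max(h$bins$normalized), 1)
  expect_false(h$empty)
  # constant image: zero energy everywhere, flagged empty, no error
  f0 <- orientation_field(matrix(5, 128, 128))
  expect_equal(max(f0$energy), 0)
  h0 <- build_histogram(f0)
  expect_true(h0$empty)
  expect_error(alignment_efficiency(h0, 0), "zero total weight")
  # isotropic band-limited noise: no prominent mode (white pixel noise is
  # below the resolution scale and carries a lattice bias; isotropic texture
  # means smoothed noise)
  set.seed(4)
  iso <- EBImage::imageData(EBImage::gblur(matrix(runif(1024^2), 1024, 1024), 3))
  hn <- build_histogram(orientation_field(iso))
  expect_lt(max(hn$peaks$prominence), 0.2)
})

test_that("crossing angle of two fiber families is recovered within 2 degrees", {
  for (alpha in c(60, 75, 90)) {
    im <- make_image(image_recipe(
      size_px = 512, n_nuclei = 0, n_fibers = 400, noise_sd = 0.005,
      orientation = list(model = "two_family", mu_deg = -20,
                         alpha_deg = alpha, kappa = 60),
      seed = 40 + alpha))
    h <- build_histogram(orientation_field(im$image[, , "green"]))
    expect_lt(abs(h$theta_cross_deg - alpha), 2)
  }
})

test_that("alignment efficiency is exact for uniform and point distributions", {
  hu <- histogram_from_angles(seq(-89.5, 89.5, by = 1))
  expect_equal(alignment_efficiency(hu, 0), 1 / 9, tolerance = 1e-12)
  expect_equal(alignment_efficiency(hu, 37.25), 1 / 9, tolerance = 1e-12)
  expect_equal(alignment_efficiency(hu, 0, window_deg = 90), 1)
  hp <- histogram_from_angles(rep(20, 100))
  expect_equal(alignment_efficiency(hp, 20), 1)
  expect_equal(alignment_efficiency(hp, 200), 1)  # axial wrap: 200 = 20 mod 180
  expect_equal(alignment_efficiency(hp, -70), 0)
})

test_that("sampled von Mises orientations reproduce their programmed window mass", {
  # concentration chosen so the +-10 degree mass is 0.484 (window-mass oracle)
  kstar <- uniroot(function(k) vm_mass_in_window(k) - 0.484, c(0.5, 20))$root
  set.seed(5)
  h <- histogram_from_angles(rvonmises_axial(1e5, 0, kstar))
  expect_equal(alignment_efficiency(h, 0), 0.484, tolerance = 0.02)
  # circular mean of a kappa = 4 histogram is close to the generator mean
  set.seed(6)
  ang <- rvonmises_axial(2e4, 25, 4)
  hh <- histogram_from_angles(ang)
  wm <- axial_mean(rep(hh$bins$angle, times = round(hh$bins$frequency)))
  expect_lt(abs(wm - 25), 2)
})

test_that("cell elongation axes come from second moments in the axial convention", {
  lab <- matrix(0L, 160, 160)
  lab <- paint_ellipse(lab, 80, 80, 30, 10, 40, 1L)
  ax <- cell_axes(lab)
  expect_equal(nrow(ax), 1)
  expect_lt(abs(ax$angle_deg - 40), 0.5)
  expect_gt(ax$aspect_ratio, 2.5)
  # a circle has no defined axis
  lab2 <- paint_ellipse(matrix(0L, 64, 64), 32, 32, 10, 10, 0, 1L)
  ax2 <- cell_axes(lab2)
  expect_true(is.na(ax2$angle_deg))
  expect_lt(ax2$aspect_ratio, 1.05)
  # a population of ellipses drawn from von Mises(mu = 0, kappa = 8)
  set.seed(7)
  angs <- rvonmises_axial(100, 0, 8)
  lab3 <- matrix(0L, 700, 700)
  centers <- expand.grid(row = seq(35, 665, by = 70), col = seq(35, 665, by = 70))
  for (i in 1:100)
    lab3 <- paint_ellipse(lab3, centers$col[i], 700 - centers$row[i] + 1,
                          24, 8, angs[i], as.integer(i))
  ax3 <- cell_axes(lab3)
  expect_equal(nrow(ax3), 100)
  expect_lt(abs(axial_mean(ax3$angle_deg)), 2)
})
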