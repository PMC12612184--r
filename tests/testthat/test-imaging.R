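# Tiling, background subtraction, CTCF and nucleus counting.

test_that("tiling drops partial tiles and labels regions by tile center", {
  expect_length(split_tiles(matrix(0, 2048, 2048), pixel_size_um = 2,
                            channels = c(green = 1))$tiles, 4)
  expect_length(split_tiles(matrix(0, 3000, 3000), pixel_size_um = 2,
                            channels = c(green = 1))$tiles, 4)
  expect_length(split_tiles(matrix(0, 1024, 3000), pixel_size_um = 2,
                            channels = c(green = 1))$tiles, 2)
  # 4x4 grid of 64-px tiles; well center at the corner, bounds chosen so the
  # grid spans all three regions
  ts <- split_tiles(matrix(0, 256, 256), pixel_size_um = 10, tile_size = 64,
                    region_bounds_mm = c(0.7, 1.8), channels = c(green = 1))
  expect_length(ts$tiles, 16)
  regs <- vapply(ts$tiles, `[[`, "", "region")
  rmm <- vapply(ts$tiles, `[[`, 0, "center_r_mm")
  expect_equal(regs, ifelse(rmm < 0.7, "A1", ifelse(rmm < 1.8, "A2", "A3")))
  expect_setequal(unique(regs), c("A1", "A2", "A3"))
  # first tile center: (32.5, 32.5) px = 0.46 mm from the corner
  expect_equal(rmm[1], sqrt(2) * 32.5 * 10 / 1000, tolerance = 1e-12)
  expect_error(split_tiles(matrix(0, 2048, 2048)), "pixel_size")
  expect_error(split_tiles(matrix(0, 100, 100), pixel_size_um = 1), "smaller")
})

test_that("rolling-ball subtraction removes offsets and keeps small features", {
  expect_equal(max(abs(rolling_ball(matrix(50, 128, 128), 15))), 0)
  set.seed(1)
  img <- matrix(runif(128 * 128), 128, 128)
  expect_equal(rolling_ball(img + 3, 15), rolling_ball(img, 15),
               tolerance = 1e-12)
  expect_equal(preprocess_tile(img + 3), preprocess_tile(img), tolerance = 1e-10)
  # output never exceeds the input
  expect_true(all(rolling_ball(img, 15) <= img + 1e-12))
  # isolated bright spot of diameter << radius on flat background survives
  spot <- matrix(10, 96, 96)
  ctr <- 48
  for (i in -3:3) for (j in -3:3)
    if (i^2 + j^2 <= 9) spot[ctr + i, ctr + j] <- spot[ctr + i, ctr + j] + 20
  out <- preprocess_tile(spot, gaussian_sigma = 0, rolling_ball_radius = 15)
  expect_gt(max(out), 0.95 * 20)
  expect_error(rolling_ball(img, 0), "positive")
})

test_that("CTCF follows its defining identity and offset invariance", {
  # uniform tile: integrated density is exactly area * mean background
  u <- matrix(4.2, 64, 64)
  m <- matrix(FALSE, 64, 64); m[10:20, 10:20] <- TRUE
  expect_equal(compute_ctcf(u, m)$ctcf, 0)
  # 100 px at value 10 on zero background
  img <- matrix(0, 64, 64); msk <- matrix(FALSE, 64, 64)
  msk[1:10, 1:10] <- TRUE; img[msk] <- 10
  q <- compute_ctcf(img, msk)
  expect_equal(q$integrated_density, 1000)
  expect_equal(q$area_px, 100)
  expect_equal(q$mean_background, 0)
  expect_equal(q$ctcf, 1000)
  # constant offset cancels exactly
  set.seed(2)
  img <- matrix(rexp(64 * 64), 64, 64)
  msk <- img > 1
  expect_equal(compute_ctcf(img + 11.3, msk)$ctcf, compute_ctcf(img, msk)$ctcf,
               tolerance = 1e-10)
  expect_error(compute_ctcf(img, matrix(TRUE, 64, 64)), "background")
  expect_error(compute_ctcf(img, matrix(TRUE, 32, 32)), "shape")
})

test_that("nucleus counting recovers generator ground truth", {
  expect_equal(count_nuclei(matrix(0, 128, 128)), 0)
  expect_equal(count_nuclei(matrix(3, 128, 128)), 0)
  # well-separated nuclei are counted exactly
  im <- make_image(image_recipe(size_px = 640, n_nuclei = 50, n_fibers = 0,
                                min_spacing_px = 24, nucleus_radius_px = 5,
                                noise_sd = 0.02, seed = 21))
  expect_equal(count_nuclei(im$image[, , "nuclei"]), 50)
  # dense field with overlapping pairs: recall at least 0.9
  im2 <- make_image(image_recipe(size_px = 512, n_nuclei = 60, n_fibers = 0,
                                 min_spacing_px = 0, nucleus_radius_px = 5,
                                 noise_sd = 0.02, seed = 22))
  cnt <- count_nuclei(im2$image[, , "nuclei"])
  expect_gte(cnt / 60, 0.9)
  expect_lte(cnt / 60, 1.1)
})

test_that("per-region aggregates recompute exactly from per-tile values", {
  im <- make_image(image_recipe(size_px = 384, n_nuclei = 40, n_fibers = 60,
                                fiber_length_px = 40, noise_sd = 0.01,
                                min_spacing_px = 12, seed = 31))
  ts <- split_tiles(im$image, pixel_size_um = 10, tile_size = 128,
                    region_bounds_mm = c(1.5, 3))
  qr <- quantify_tiles(ts, marker = "green", rolling_ball_radius = 10,
                       nuclei_min_area = 10)
  expect_equal(nrow(qr$per_tile), 9)
  # invariant ctcf = int_den - area * mean_bg holds row-wise by construction
  expect_equal(qr$per_tile$ctcf,
               qr$per_tile$integrated_density -
                 qr$per_tile$area_px * qr$per_tile$mean_background)
  for (reg in unique(qr$per_tile$region)) {
    sub <- qr$per_tile[qr$per_tile$region == reg, ]
    agg <- qr$aggregates[qr$aggregates$region == reg, ]
    expect_identical(agg$ctcf_mean, mean(sub$ctcf))
    expect_identical(agg$ctcf_sd, sd(sub$ctcf))
  }
  glob <- qr$aggregates[qr$aggregates$region == "global", ]
  expect_identical(glob$ctcf_mean, mean(qr$per_tile$ctcf))
})
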