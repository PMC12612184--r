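# Synthetic-data generators with known ground truth.
#
# Every generator takes a recipe with a mandatory RNG seed and emits, next
# to the rendered data, a machine-readable truth table so the analysis
# modules can be validated in closed loop: nuclei positions for counting,
# fiber angles for orientation recovery, analytic areas for coverage rates,
# programmed fold changes for ddCt recovery. Identical recipe + seed give
# identical output. Images are rendered on the projected plane in the same
# axial-angle convention as the orientation module (x right, y up, angles
# in [-90, 90) from +x).

# run code under a recipe seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed) || !is.finite(seed)) stop("recipe must carry a finite seed")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Sample axial angles from a von Mises orientation model
#'
#' Axial (180-degree periodic) von Mises sampling: doubled angles are drawn
#' from a circular von Mises distribution with concentration `kappa` (Best &
#' Fisher rejection sampler) and halved. `kappa = 0` gives the uniform
#' axial distribution.
#'
#' @param n number of samples.
#' @param mu_deg mean axis, degrees in \[-90, 90).
#' @param kappa concentration (>= 0).
#' @return angles in degrees in \[-90, 90).
#' @export
rvonmises_axial <- function(n, mu_deg = 0, kappa = 4) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
  } else {
    # Best & Fisher (1979) wrapped-Cauchy envelope rejection
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n); got <- 0
    while (got < n) {
      m <- n - got
      u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      c_ <- kappa * (r - f)
      ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
      v <- sign(u3[ok] - 0.5) * acos(f[ok])
      take <- min(length(v), n - got)
      if (take > 0) th[got + seq_len(take)] <- v[seq_len(take)]
      got <- got + take
    }
  }
  (((th * 90 / pi) + mu_deg + 90) %% 180) - 90
}

#' Density of the axial von Mises distribution
#'
#' @param theta_deg axial angles in degrees.
#' @param mu_deg mean axis in degrees.
#' @param kappa concentration.
#' @return density per degree on \[-90, 90).
#' @export
dvonmises_axial <- function(theta_deg, mu_deg = 0, kappa = 4) {
  d <- (theta_deg - mu_deg) * pi / 90  # doubled angle, radians
  # exponentially scaled Bessel avoids overflow at large kappa
  exp(kappa * (cos(d) - 1)) / (180 * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Recipe for a synthetic multichannel fluorescence image
#'
#' @param size_px image side in pixels.
#' @param pixel_size_um pixel size (um/px).
#' @param n_nuclei number of nuclei (Gaussian blobs in the nuclei channel).
#' @param nucleus_radius_px mean nucleus Gaussian sigma in pixels (10
#'   percent s.d. jitter).
#' @param nuclei_layout `"full"` (uniform over the frame), `"disc"` or
#'   `"annulus"` placement.
#' @param layout_radii_frac for disc/annulus layouts, radii as fractions of
#'   the half-size.
#' @param min_spacing_px minimum center-to-center nucleus spacing (0 =
#'   unconstrained).
#' @param n_fibers number of fibrous structures (F-actin-like ribbons).
#' @param fiber_length_px,fiber_width_px mean fiber length and Gaussian
#'   half-width in pixels.
#' @param orientation orientation model for fibers: list with `model` one of
#'   `"uniform"`, `"vonmises"` (fields `mu_deg`, `kappa`) or `"two_family"`
#'   (fields `mu_deg`, `alpha_deg` between families, `kappa` within-family,
#'   `weights`).
#' @param marker_intensity named amplitudes of the fiber signal per marker
#'   channel, e.g. `c(green = 1, red = 0.3)` for condition-dependent levels.
#' @param nucleus_intensity amplitude of nuclear blobs.
#' @param background constant background level added to every channel.
#' @param gradient_amplitude peak-to-peak linear background gradient across
#'   x (uneven illumination).
#' @param noise_sd Gaussian (read) noise s.d.
#' @param poisson if TRUE, apply Poisson (shot) noise with `poisson_scale`
#'   expected counts per intensity unit.
#' @param poisson_scale counts per intensity unit for shot noise.
#' @param seed RNG seed (mandatory).
#' @return object of class `image_recipe`.
#' @export
image_recipe <- function(size_px = 512, pixel_size_um = 1,
                         n_nuclei = 50, nucleus_radius_px = 5,
                         nuclei_layout = c("full", "disc", "annulus"),
                         layout_radii_frac = c(0.3, 0.9),
                         min_spacing_px = 0,
                         n_fibers = 150, fiber_length_px = 80,
                         fiber_width_px = 2.5,
                         orientation = list(model = "uniform"),
                         marker_intensity = c(green = 1, red = 0.3),
                         nucleus_intensity = 1,
                         background = 0.05, gradient_amplitude = 0.02,
                         noise_sd = 0.01, poisson = FALSE,
                         poisson_scale = 100, seed) {
  if (missing(seed)) stop("seed is mandatory")
  nuclei_layout <- match.arg(nuclei_layout)
  stopifnot(size_px >= 32, pixel_size_um > 0, n_nuclei >= 0, n_fibers >= 0)
  structure(as.list(environment()), class = "image_recipe")
}

# draw fiber angles according to the recipe orientation model
.draw_fiber_angles <- function(orient, n) {
  model <- orient$model
  if (model == "uniform") return(stats::runif(n, -90, 90))
  if (model == "vonmises")
    return(rvonmises_axial(n, orient$mu_deg, orient$kappa))
  if (model == "two_family") {
    w <- if (is.null(orient$weights)) c(0.5, 0.5) else orient$weights
    fam <- sample(1:2, n, replace = TRUE, prob = w)
    mu <- c(orient$mu_deg, orient$mu_deg + orient$alpha_deg)
    kap <- if (is.null(orient$kappa)) 30 else orient$kappa
    ang <- rvonmises_axial(n, 0, kap) + mu[fam]
    return(((ang + 90) %% 180) - 90)
  }
  stop("unknown orientation model: ", model)
}

# additively render an anisotropic Gaussian ribbon into img (y up)
.render_fiber <- function(img, cx, cy, angle_deg, len, wdt, amp) {
  n <- nrow(img)
  th <- angle_deg * pi / 180
  half <- len / 2 + 3.5 * wdt
  rows <- max(1, floor(n - (cy + half) + 1)):min(n, ceiling(n - (cy - half) + 1))
  cols <- max(1, floor(cx - half)):min(ncol(img), ceiling(cx + half))
  if (!length(rows) || !length(cols)) return(img)
  x <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
  y <- matrix(n - rows + 1, length(rows), length(cols)) - cy
  d_par <- x * cos(th) + y * sin(th)
  d_perp <- -x * sin(th) + y * cos(th)
  over <- pmax(0, abs(d_par) - len / 2)
  img[rows, cols] <- img[rows, cols] +
    amp * exp(-(d_perp^2 + over^2) / (2 * wdt^2))
  img
}

# additively render an isotropic Gaussian blob (y up)
.render_blob <- function(img, cx, cy, sig, amp) {
  n <- nrow(img)
  half <- 4 * sig
  rows <- max(1, floor(n - (cy + half) + 1)):min(n, ceiling(n - (cy - half) + 1))
  cols <- max(1, floor(cx - half)):min(ncol(img), ceiling(cx + half))
  if (!length(rows) || !length(cols)) return(img)
  x <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
  y <- matrix(n - rows + 1, length(rows), length(cols)) - cy
  img[rows, cols] <- img[rows, cols] + amp * exp(-(x^2 + y^2) / (2 * sig^2))
  img
}

# rejection placement of points in the recipe layout with optional spacing
.place_points <- function(rec, n) {
  sz <- rec$size_px; ctr <- (sz + 1) / 2
  draw <- function(m) {
    if (rec$nuclei_layout == "full") {
      cbind(stats::runif(m, 1, sz), stats::runif(m, 1, sz))
    } else {
      r_out <- rec$layout_radii_frac[2] * (sz - 1) / 2
      r_in <- if (rec$nuclei_layout == "annulus")
        rec$layout_radii_frac[1] * (sz - 1) / 2 else 0
      rr <- sqrt(stats::runif(m, (r_in / r_out)^2, 1)) * r_out
      aa <- stats::runif(m, 0, 2 * pi)
      cbind(ctr + rr * cos(aa), ctr + rr * sin(aa))
    }
  }
  if (rec$min_spacing_px <= 0) return(draw(n))
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(pts) < n && tries < 200) {
    cand <- draw(n)
    for (i in seq_len(nrow(cand))) {
      if (nrow(pts) == n) break
      if (nrow(pts) == 0 ||
          min(sqrt((pts[, 1] - cand[i, 1])^2 + (pts[, 2] - cand[i, 2])^2)) >=
            rec$min_spacing_px)
        pts <- rbind(pts, cand[i, ])
    }
    tries <- tries + 1
  }
  if (nrow(pts) < n) stop("could not place nuclei at the requested spacing")
  pts
}

#' Render a synthetic multichannel image with ground truth
#'
#' @param recipe an [image_recipe()].
#' @return list with `image` (array `[size, size, 3]`, channels nuclei /
#'   green / red), and `truth`: `nuclei` data.frame (x, y in pixel
#'   coordinates with y up, sigma_px), `fibers` data.frame (x, y, angle_deg,
#'   length_px, width_px). A warning is raised if more than 95 percent of
#'   pixels saturate the 99.5th-percentile intensity.
#' @export
make_image <- function(recipe) {
  stopifnot(inherits(recipe, "image_recipe"))
  .with_seed(recipe$seed, {
    sz <- recipe$size_px
    base <- matrix(0, sz, sz)
    # nuclei
    nuc_img <- base
    nuclei <- data.frame(x = numeric(0), y = numeric(0), sigma_px = numeric(0))
    if (recipe$n_nuclei > 0) {
      pts <- .place_points(recipe, recipe$n_nuclei)
      sig <- recipe$nucleus_radius_px * (1 + 0.1 * stats::rnorm(recipe$n_nuclei))
      sig <- pmax(sig, 0.5)
      nuclei <- data.frame(x = pts[, 1], y = pts[, 2], sigma_px = sig)
      for (i in seq_len(nrow(nuclei)))
        nuc_img <- .render_blob(nuc_img, nuclei$x[i], nuclei$y[i], sig[i],
                                recipe$nucleus_intensity)
    }
    # fibers
    fib_img <- base
    fibers <- data.frame(x = numeric(0), y = numeric(0), angle_deg = numeric(0),
                         length_px = numeric(0), width_px = numeric(0))
    if (recipe$n_fibers > 0) {
      ang <- .draw_fiber_angles(recipe$orientation, recipe$n_fibers)
      fx <- stats::runif(recipe$n_fibers, 1, sz)
      fy <- stats::runif(recipe$n_fibers, 1, sz)
      ln <- recipe$fiber_length_px * (1 + 0.15 * stats::rnorm(recipe$n_fibers))
      ln <- pmax(ln, 4)
      fibers <- data.frame(x = fx, y = fy, angle_deg = ang, length_px = ln,
                           width_px = recipe$fiber_width_px)
      for (i in seq_len(recipe$n_fibers))
        fib_img <- .render_fiber(fib_img, fx[i], fy[i], ang[i], ln[i],
                                 recipe$fiber_width_px, 1)
    }
    # background with a linear illumination gradient across x
    grad <- matrix(seq(-0.5, 0.5, length.out = sz), sz, sz, byrow = TRUE)
    bg <- recipe$background + recipe$gradient_amplitude * grad
    img <- array(0, dim = c(sz, sz, 3),
                 dimnames = list(NULL, NULL, c("nuclei", "green", "red")))
    img[, , "nuclei"] <- nuc_img + bg
    img[, , "green"] <- recipe$marker_intensity[["green"]] * fib_img + bg
    img[, , "red"] <- recipe$marker_intensity[["red"]] * fib_img + bg
    if (recipe$poisson)
      img[] <- stats::rpois(length(img), pmax(img, 0) * recipe$poisson_scale) /
        recipe$poisson_scale
    if (recipe$noise_sd > 0)
      img[] <- img + stats::rnorm(length(img), sd = recipe$noise_sd)
    sat <- stats::quantile(img, 0.995)
    if (mean(img >= sat) > 0.95)
      warning("object density saturates the image")
    list(image = img, truth = list(nuclei = nuclei, fibers = fibers))
  })
}

#' Recipe for a radially expanding colony time series
#'
#' @param initial_radius_mm colony radius at day 0.
#' @param speed_mm_day radial expansion speed (mm/day).
#' @param days timepoints sampled (days).
#' @param pixel_size_um raster pixel size; the frame spans the full 2a well.
#' @param well_radius_mm well radius a (colonies are clipped at the rim,
#'   mirroring near-complete coverage late in culture).
#' @param density_cells_mm2 nucleus density when rendering nuclei images.
#' @param nucleus_radius_px nucleus blob sigma for rendered nuclei.
#' @param seed RNG seed (mandatory).
#' @return object of class `growth_recipe`.
#' @export
growth_recipe <- function(initial_radius_mm = 0.75, speed_mm_day = 0.35,
                          days = c(0, 3, 6, 9), pixel_size_um = 20,
                          well_radius_mm = 4, density_cells_mm2 = 150,
                          nucleus_radius_px = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(initial_radius_mm >= 0, speed_mm_day >= 0, length(days) >= 1)
  structure(as.list(environment()), class = "growth_recipe")
}

#' Generate a colony growth series with analytic truth areas
#'
#' Colony radius grows linearly, `r(t) = r0 + v t`, clipped at the well
#' radius; the truth area is `pi * min(r(t), a)^2`.
#'
#' @param recipe a [growth_recipe()].
#' @param render_nuclei also render per-day nuclei images (Gaussian blobs at
#'   the recipe density inside the colony disc).
#' @return list with `days`, `radius_mm` (clipped), `truth_area_mm2`,
#'   `masks` (list of logical matrices over the `2a x 2a` frame) and, when
#'   requested, `nuclei_images`.
#' @export
make_growth_series <- function(recipe, render_nuclei = FALSE) {
  stopifnot(inherits(recipe, "growth_recipe"))
  .with_seed(recipe$seed, {
    a <- recipe$well_radius_mm
    px_mm <- 1000 / recipe$pixel_size_um
    n <- round(2 * a * px_mm)
    ctr <- (n + 1) / 2
    rr_px <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
                   function(dr, dc) sqrt(dr^2 + dc^2))
    r_raw <- recipe$initial_radius_mm + recipe$speed_mm_day * recipe$days
    clipped <- r_raw > a
    if (any(clipped))
      message("colony radius clipped at the well rim on day(s) ",
              paste(recipe$days[clipped], collapse = ", "))
    r_mm <- pmin(r_raw, a)
    masks <- lapply(r_mm, function(r) rr_px <= r * px_mm)
    out <- list(days = recipe$days, radius_mm = r_mm,
                truth_area_mm2 = pi * r_mm^2, masks = masks,
                pixel_size_um = recipe$pixel_size_um)
    if (render_nuclei) {
      out$nuclei_images <- lapply(r_mm, function(r) {
        img <- matrix(0, n, n)
        n_cells <- stats::rpois(1, recipe$density_cells_mm2 * pi * r^2)
        if (n_cells > 0) {
          rho <- sqrt(stats::runif(n_cells)) * r * px_mm
          th <- stats::runif(n_cells, 0, 2 * pi)
          cx <- ctr + rho * cos(th); cy <- ctr + rho * sin(th)
          for (i in seq_len(n_cells))
            img <- .render_blob(img, cx[i], cy[i], recipe$nucleus_radius_px, 1)
        }
        img
      })
    }
    out
  })
}

#' Recipe for a synthetic Ct table
#'
#' @param strata data.frame with columns `cell_type`, `gene`, `condition`,
#'   `fold`: the programmed fold change of each stratum relative to the
#'   reference condition (reference rows should carry fold 1).
#' @param baseline_ct target-gene Ct at fold 1.
#' @param housekeeping_ct housekeeping-gene Ct.
#' @param housekeeping housekeeping gene name.
#' @param noise_sd Gaussian Ct noise s.d. (cycles).
#' @param n_replicates biological replicates per stratum.
#' @param seed RNG seed (mandatory).
#' @return object of class `ct_recipe`.
#' @export
ct_recipe <- function(strata, baseline_ct = 24, housekeeping_ct = 18,
                      housekeeping = "GAPDH", noise_sd = 0.2,
                      n_replicates = 3, seed) {
  if (missing(seed)) stop("seed is mandatory")
  need <- c("cell_type", "gene", "condition", "fold")
  if (!all(need %in% names(strata)))
    stop("strata needs columns ", paste(need, collapse = ", "))
  if (any(strata$fold <= 0)) stop("fold changes must be positive")
  structure(list(strata = strata, baseline_ct = baseline_ct,
                 housekeeping_ct = housekeeping_ct,
                 housekeeping = housekeeping, noise_sd = noise_sd,
                 n_replicates = n_replicates, seed = seed),
            class = "ct_recipe")
}

#' Generate a Ct table with programmed fold changes
#'
#' Target Ct values are `baseline - log2(fold) + N(0, sd)`; housekeeping Ct
#' values are `housekeeping_ct + N(0, sd)`, one per sample.
#'
#' @param recipe a [ct_recipe()].
#' @return list with `ct_table` (columns sample_id, cell_type, condition,
#'   gene, ct; includes housekeeping rows) and `truth` (the recipe strata).
#' @export
make_ct_table <- function(recipe) {
  stopifnot(inherits(recipe, "ct_recipe"))
  .with_seed(recipe$seed, {
    st <- recipe$strata
    rows <- list()
    combos <- unique(st[, c("cell_type", "condition")])
    for (i in seq_len(nrow(combos))) {
      ctype <- combos$cell_type[i]; cond <- combos$condition[i]
      for (rep_i in seq_len(recipe$n_replicates)) {
        sid <- sprintf("%s_%s_r%d", ctype, cond, rep_i)
        sub <- st[st$cell_type == ctype & st$condition == cond, ]
        for (j in seq_len(nrow(sub))) {
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sid, cell_type = ctype, condition = cond,
            gene = sub$gene[j],
            ct = recipe$baseline_ct - log2(sub$fold[j]) +
              stats::rnorm(1, sd = recipe$noise_sd))
        }
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sid, cell_type = ctype, condition = cond,
          gene = recipe$housekeeping,
          ct = recipe$housekeeping_ct + stats::rnorm(1, sd = recipe$noise_sd))
      }
    }
    list(ct_table = do.call(rbind, rows), truth = st)
  })
}
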