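# Region-resolved fluorescence quantification of tiled chip images.
#
# Stitched quarter-well images are split into fixed-size tiles, each tile is
# smoothed, background-subtracted (rolling-ball-style morphological opening)
# and quantified: integrated density over a foreground mask, mean background,
# corrected total cell fluorescence CTCF = IntDen - Area * MeanBackground,
# and nucleus counts for per-cell normalisation. Tiles carry a region label
# (A1 center / A2 slope / A3 edge) from their distance to the well center.

# channel data of a tile or image as a plain numeric matrix
.as_channel <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (!is.matrix(x) || !is.numeric(x)) stop("expected a single-channel numeric image")
  x
}

#' Split a stitched image into labelled analysis tiles
#'
#' Cuts a (multi-channel) image into non-overlapping square tiles on a grid
#' anchored at the image origin, dropping partial tiles at the edges, and
#' labels every tile with the curvature region (A1/A2/A3) containing its
#' center.
#'
#' @param image numeric matrix (single channel) or 3-D array
#'   `[rows, cols, channels]`.
#' @param pixel_size_um pixel size in micrometres per pixel (required).
#' @param tile_size tile side in pixels (default 1024).
#' @param region_bounds_mm radii `(r1, r2)` in mm separating A1/A2/A3,
#'   measured from the well center; typically the displacement-region bounds
#'   used by [region_partition()].
#' @param well_center_px `(row, col)` pixel coordinates of the well center.
#'   The default `c(0, 0)` places it at the image corner, matching
#'   quarter-well acquisitions.
#' @param channels named integer vector mapping channel names to slices of
#'   the third array dimension, e.g. `c(nuclei = 1, green = 2, red = 3)`.
#' @return object of class `tile_set`: list with `tiles` (each a list with
#'   `data`, `origin` (row, col of the tile's first pixel), `center_r_mm`,
#'   `region`), plus `pixel_size_um`, `tile_size` and `channels`.
#' @export
split_tiles <- function(image, pixel_size_um, tile_size = 1024,
                        region_bounds_mm = c(4 / 3, 8 / 3),
                        well_center_px = c(0, 0),
                        channels = c(nuclei = 1, green = 2, red = 3)) {
  if (missing(pixel_size_um) || is.null(pixel_size_um) || !is.finite(pixel_size_um) ||
      pixel_size_um <= 0)
    stop("pixel_size_um metadata is required and must be positive")
  dims <- dim(image)
  if (length(dims) == 2) { nch <- 1L } else if (length(dims) == 3) {
    nch <- dims[3]
  } else stop("image must be a matrix or a [rows, cols, channels] array")
  if (dims[1] < tile_size || dims[2] < tile_size)
    stop("image is smaller than one tile")
  if (!(length(region_bounds_mm) == 2 && region_bounds_mm[1] < region_bounds_mm[2]))
    stop("region_bounds_mm must be two increasing radii")
  n_r <- dims[1] %/% tile_size
  n_c <- dims[2] %/% tile_size
  tiles <- list()
  for (i in seq_len(n_r)) for (j in seq_len(n_c)) {
    r0 <- (i - 1) * tile_size; c0 <- (j - 1) * tile_size
    dat <- if (nch == 1) image[r0 + 1:tile_size, c0 + 1:tile_size]
           else image[r0 + 1:tile_size, c0 + 1:tile_size, , drop = FALSE]
    ctr <- c(r0 + (tile_size + 1) / 2, c0 + (tile_size + 1) / 2)
    r_mm <- sqrt(sum((ctr - well_center_px)^2)) * pixel_size_um / 1000
    region <- if (r_mm < region_bounds_mm[1]) "A1"
              else if (r_mm < region_bounds_mm[2]) "A2" else "A3"
    tiles[[length(tiles) + 1]] <-
      list(data = dat, origin = c(row = r0 + 1, col = c0 + 1),
           center_r_mm = r_mm, region = region)
  }
  structure(list(tiles = tiles, pixel_size_um = pixel_size_um,
                 tile_size = tile_size, channels = channels),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  regs <- vapply(x$tiles, `[[`, "", "region")
  cat(sprintf("tile_set: %d tiles of %d px (%.3g um/px); regions: %s\n",
              length(x$tiles), x$tile_size, x$pixel_size_um,
              paste(sprintf("%s=%d", names(table(regs)), table(regs)), collapse = " ")))
  invisible(x)
}

#' Rolling-ball-style background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the image with a disc structuring element of the given radius and
#' subtracts it. Like the classical rolling-ball filter this removes any
#' constant offset exactly, maps uniform images to zero and preserves bright
#' features smaller than the element.
#'
#' @param x single-channel image (matrix).
#' @param radius element radius in pixels (the classical choice is 10-20 px).
#' @return background-subtracted matrix (non-negative where `x` is).
#' @export
rolling_ball <- function(x, radius = 15) {
  x <- .as_channel(x)
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  rng <- range(x)
  if (diff(rng) == 0) return(x * 0)
  brush <- EBImage::makeBrush(2 * floor(radius) + 1, shape = "disc")
  # EBImage grayscale morphology operates on [0, 1] intensities; min/max
  # filters commute with the affine rescaling, so this is exact
  xn <- (x - rng[1]) / diff(rng)
  bg <- EBImage::imageData(EBImage::opening(xn, brush)) * diff(rng) + rng[1]
  x - bg
}

#' Smooth and background-subtract one tile
#'
#' Gaussian smoothing followed by [rolling_ball()] background subtraction,
#' the standard preparation before thresholding and CTCF quantification.
#'
#' @param tile single-channel image (matrix).
#' @param gaussian_sigma Gaussian sigma in pixels; `0` skips smoothing.
#' @param rolling_ball_radius background element radius in pixels.
#' @return preprocessed matrix.
#' @export
preprocess_tile <- function(tile, gaussian_sigma = 2, rolling_ball_radius = 15) {
  tile <- .as_channel(tile)
  if (gaussian_sigma < 0) stop("gaussian_sigma must be >= 0")
  if (gaussian_sigma > 0)
    tile <- EBImage::imageData(EBImage::gblur(tile, sigma = gaussian_sigma))
  rolling_ball(tile, rolling_ball_radius)
}

#' Otsu foreground mask
#'
#' Threshold a (preprocessed) channel with Otsu's method on the rescaled
#' intensity range.
#'
#' @param tile single-channel image (matrix).
#' @return logical matrix; all `FALSE` for a constant tile.
#' @export
foreground_mask <- function(tile) {
  tile <- .as_channel(tile)
  rng <- range(tile)
  if (diff(rng) == 0) return(matrix(FALSE, nrow(tile), ncol(tile)))
  xn <- (tile - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  xn > thr
}

#' Corrected total cell fluorescence of one tile
#'
#' `CTCF = IntegratedDensity - Area * MeanBackground`, with the integrated
#' density summed over the foreground mask and the mean background taken
#' over its complement.
#'
#' @param tile single-channel image (matrix).
#' @param mask logical matrix of the same shape; foreground pixels `TRUE`.
#' @return list with `integrated_density`, `area_px`, `mean_background`,
#'   `ctcf`.
#' @export
compute_ctcf <- function(tile, mask) {
  tile <- .as_channel(tile)
  if (!identical(dim(tile), dim(mask))) stop("mask and tile shapes differ")
  mask <- as.logical(mask)
  if (all(mask)) stop("mask covers the whole tile: background undefined")
  int_den <- sum(tile[mask])
  area <- sum(mask)
  mean_bg <- mean(tile[!mask])
  list(integrated_density = int_den, area_px = area,
       mean_background = mean_bg, ctcf = int_den - area * mean_bg)
}

#' Label nuclei in a nuclei-channel image
#'
#' Gaussian blur, Otsu threshold, then watershed splitting on the distance
#' transform to separate touching nuclei; objects below `min_area` are
#' discarded.
#'
#' @param img nuclei-channel image (matrix).
#' @param sigma blur sigma in pixels.
#' @param min_area minimum object area in pixels.
#' @param tolerance watershed intensity tolerance on the distance map.
#' @return integer label matrix (0 = background), relabelled consecutively.
#' @export
label_nuclei <- function(img, sigma = 2, min_area = 20, tolerance = 1) {
  img <- .as_channel(img)
  rng <- range(img)
  if (diff(rng) == 0) return(matrix(0L, nrow(img), ncol(img)))
  sm <- if (sigma > 0) EBImage::imageData(EBImage::gblur(img, sigma)) else img
  rng <- range(sm)
  xn <- (sm - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(xn), range = c(0, 1))
  mask <- xn > thr
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance, ext = 1))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(img), ncol(img))
  if (length(keep)) {
    newid <- integer(length(sizes)); newid[keep] <- seq_along(keep)
    pos <- lab > 0
    out[pos] <- newid[lab[pos]]
  }
  out
}

#' Count nuclei in a nuclei-channel image
#'
#' @inheritParams label_nuclei
#' @return integer nucleus count (0 for a blank image).
#' @export
count_nuclei <- function(img, sigma = 2, min_area = 20, tolerance = 1) {
  max(label_nuclei(img, sigma = sigma, min_area = min_area,
                   tolerance = tolerance))
}

#' Quantify CTCF and nuclei across a tile set
#'
#' Runs the per-tile pipeline (preprocess marker channel, Otsu foreground,
#' CTCF, nucleus count) over all tiles and aggregates by region.
#'
#' @param tileset a [split_tiles()] result with a multi-channel image.
#' @param marker channel name to quantify (`"green"` or `"red"`).
#' @param gaussian_sigma,rolling_ball_radius passed to [preprocess_tile()].
#' @param nuclei_sigma,nuclei_min_area passed to [count_nuclei()].
#' @return object of class `quant_result`: `per_tile` data.frame (tile_id,
#'   region, integrated_density, area_px, mean_background, ctcf,
#'   nucleus_count, ctcf_per_nucleus) and `aggregates` data.frame of mean and
#'   s.d. of CTCF and CTCF per nucleus, per region and global.
#' @export
quantify_tiles <- function(tileset, marker = "green", gaussian_sigma = 2,
                           rolling_ball_radius = 15, nuclei_sigma = 2,
                           nuclei_min_area = 20) {
  stopifnot(inherits(tileset, "tile_set"))
  ch <- tileset$channels
  if (!marker %in% names(ch)) stop("unknown marker channel: ", marker)
  rows <- lapply(seq_along(tileset$tiles), function(i) {
    tl <- tileset$tiles[[i]]
    dat <- tl$data
    mk <- dat[, , ch[[marker]]]
    nuc <- dat[, , ch[["nuclei"]]]
    pp <- preprocess_tile(mk, gaussian_sigma, rolling_ball_radius)
    msk <- foreground_mask(pp)
    q <- if (any(msk) && !all(msk)) compute_ctcf(pp, msk)
         else list(integrated_density = 0, area_px = sum(msk),
                   mean_background = mean(pp), ctcf = 0)
    nn <- count_nuclei(nuc, sigma = nuclei_sigma, min_area = nuclei_min_area)
    data.frame(tile_id = i, region = tl$region,
               integrated_density = q$integrated_density, area_px = q$area_px,
               mean_background = q$mean_background, ctcf = q$ctcf,
               nucleus_count = nn,
               ctcf_per_nucleus = if (nn > 0) q$ctcf / nn else NA_real_)
  })
  per_tile <- do.call(rbind, rows)
  agg_one <- function(d, label) data.frame(
    region = label, n_tiles = nrow(d),
    ctcf_mean = mean(d$ctcf), ctcf_sd = stats::sd(d$ctcf),
    ctcf_per_nucleus_mean = mean(d$ctcf_per_nucleus, na.rm = TRUE),
    ctcf_per_nucleus_sd = stats::sd(d$ctcf_per_nucleus, na.rm = TRUE))
  aggregates <- do.call(rbind, c(
    lapply(split(per_tile, per_tile$region), function(d) agg_one(d, d$region[1])),
    list(agg_one(per_tile, "global"))))
  rownames(aggregates) <- NULL
  structure(list(per_tile = per_tile, aggregates = aggregates,
                 marker = marker), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("CTCF quantification (%s channel), %d tiles\n",
              x$marker, nrow(x$per_tile)))
  print(x$aggregates)
  invisible(x)
}
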