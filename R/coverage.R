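# Colony coverage over time: areas, rates (mm^2/day) and fold changes.
#
# Cells are droplet-seeded at the well center and expand radially; coverage
# is measured on binary colony masks (or derived from nuclei images) on the
# projected plane, clipped to the well disc.

#' Colony area from a binary mask
#'
#' @param mask logical or 0/1 matrix of colony coverage.
#' @param pixel_size_um pixel size in micrometres per pixel (required).
#' @param well_radius_mm well radius; pixels outside this disc are clipped
#'   when `clip = TRUE`.
#' @param well_center_px `(row, col)` of the well center in pixels; default
#'   is the image center.
#' @param clip clip the mask to the well disc (default TRUE).
#' @return area in mm^2.
#' @export
coverage_area <- function(mask, pixel_size_um, well_radius_mm = 4,
                          well_center_px = NULL, clip = TRUE) {
  if (missing(pixel_size_um) || is.null(pixel_size_um) ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um metadata is required and must be positive")
  if (inherits(mask, "Image")) mask <- EBImage::imageData(mask)
  m <- mask > 0
  if (clip) {
    if (is.null(well_center_px))
      well_center_px <- c((nrow(m) + 1) / 2, (ncol(m) + 1) / 2)
    rr <- outer(seq_len(nrow(m)) - well_center_px[1],
                seq_len(ncol(m)) - well_center_px[2],
                function(dr, dc) sqrt(dr^2 + dc^2)) * pixel_size_um / 1000
    m <- m & rr <= well_radius_mm
  }
  sum(m) * (pixel_size_um / 1000)^2
}

#' Colony mask from a nuclei image
#'
#' Detected nuclei are dilated by a fixed physical radius and the largest
#' connected component is taken as the colony footprint.
#'
#' @param nuclei_img nuclei-channel image (matrix).
#' @param pixel_size_um pixel size (um/px).
#' @param dilate_um dilation radius in micrometres (default 30, about one
#'   cell body).
#' @param sigma,min_area passed to [label_nuclei()].
#' @return logical colony mask.
#' @export
colony_mask <- function(nuclei_img, pixel_size_um, dilate_um = 30,
                        sigma = 2, min_area = 20) {
  lab <- label_nuclei(nuclei_img, sigma = sigma, min_area = min_area)
  if (max(lab) == 0) return(matrix(FALSE, nrow(lab), ncol(lab)))
  r_px <- max(1, round(dilate_um / pixel_size_um))
  brush <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate((lab > 0) * 1, brush)) > 0
  cc <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(dil * 1)))
  sizes <- tabulate(cc[cc > 0])
  cc == which.max(sizes)
}

#' Coverage time series
#'
#' @param days numeric vector of timepoints (days).
#' @param areas_mm2 areas at those timepoints (mm^2), each within
#'   `[0, pi * well_radius_mm^2]`.
#' @param well_radius_mm well radius used for the bound check.
#' @return object of class `coverage_series` (data.frame day, area_mm2).
#' @export
coverage_series <- function(days, areas_mm2, well_radius_mm = 4) {
  if (length(days) != length(areas_mm2)) stop("days and areas differ in length")
  if (anyDuplicated(days)) stop("duplicate timepoints")
  if (any(areas_mm2 < 0)) stop("areas must be nonnegative")
  # allow 1 percent discretisation excess over the exact disc area
  a_max <- pi * well_radius_mm^2
  if (any(areas_mm2 > a_max * 1.01))
    stop(sprintf("areas exceed the well area %.2f mm^2", a_max))
  o <- order(days)
  structure(data.frame(day = days[o], area_mm2 = areas_mm2[o]),
            class = c("coverage_series", "data.frame"))
}

#' Coverage rate between two timepoints
#'
#' `(area(t_end) - area(t_start)) / (t_end - t_start)` in mm^2/day; the
#' standard window is day 3 to day 6, the expansion period after curvature
#' is applied.
#'
#' @param series a [coverage_series()].
#' @param t_start,t_end timepoints present in the series.
#' @return rate in mm^2/day; negative rates are returned with a warning.
#' @export
coverage_rate <- function(series, t_start = 3, t_end = 6) {
  stopifnot(inherits(series, "coverage_series"))
  if (t_start == t_end) stop("t_start and t_end must differ")
  i0 <- match(t_start, series$day); i1 <- match(t_end, series$day)
  if (is.na(i0) || is.na(i1))
    stop("both timepoints must be present in the series")
  rate <- (series$area_mm2[i1] - series$area_mm2[i0]) / (t_end - t_start)
  if (rate < 0) warning("negative coverage rate (colony shrank)")
  rate
}

#' Fold change of a coverage rate versus a reference
#'
#' @param rate coverage rate (mm^2/day).
#' @param reference_rate reference (e.g. flat-control) rate; must be
#'   positive. Flat-control rates can be near zero (quiescent keratocytes);
#'   references below `floor_eps` are replaced by `floor_eps` with a
#'   warning so fold changes stay finite.
#' @param floor_eps positive floor for the reference rate (mm^2/day).
#' @return `rate / max(reference_rate, floor_eps)`.
#' @export
fold_change <- function(rate, reference_rate, floor_eps = 0.1) {
  if (!is.finite(reference_rate) || reference_rate <= 0)
    stop("reference_rate must be positive; for near-zero flat rates use the ",
         "floor_eps argument to bound the denominator")
  if (floor_eps <= 0) stop("floor_eps must be positive")
  if (reference_rate < floor_eps) {
    warning(sprintf("reference rate %.3g below floor %.3g; floored", reference_rate, floor_eps))
    reference_rate <- floor_eps
  }
  rate / reference_rate
}

#' Boundary contours of a colony mask
#'
#' Equally spaced boundary points of the colony footprint, for Fig.-style
#' contour overlays of growth over days.
#'
#' @param mask logical colony mask.
#' @param pixel_size_um pixel size (um/px).
#' @param n_points number of boundary points returned.
#' @param well_center_px `(row, col)` of the well center; default image
#'   center.
#' @return data.frame `x_mm`, `y_mm` of boundary points (well-centred
#'   coordinates, y up), ordered by polar angle.
#' @export
coverage_contour <- function(mask, pixel_size_um, n_points = 180,
                             well_center_px = NULL) {
  if (inherits(mask, "Image")) mask <- EBImage::imageData(mask)
  m <- mask > 0
  if (!any(m)) return(data.frame(x_mm = numeric(), y_mm = numeric()))
  if (is.null(well_center_px))
    well_center_px <- c((nrow(m) + 1) / 2, (ncol(m) + 1) / 2)
  # boundary = mask minus its erosion
  er <- EBImage::imageData(EBImage::erode(m * 1, EBImage::makeBrush(3, "box"))) > 0
  bd <- which(m & !er, arr.ind = TRUE)
  x <- (bd[, 2] - well_center_px[2]) * pixel_size_um / 1000
  y <- -(bd[, 1] - well_center_px[1]) * pixel_size_um / 1000
  ang <- atan2(y, x)
  tgt <- seq(-pi, pi, length.out = n_points + 1)[-(n_points + 1)]
  idx <- vapply(tgt, function(a) {
    d <- abs(((ang - a + pi) %% (2 * pi)) - pi)
    which.min(d)
  }, integer(1))
  data.frame(x_mm = x[idx], y_mm = y[idx])
}
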