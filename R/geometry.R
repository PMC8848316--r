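# Binary-mask morphometry: bounding dimensions, outer-boundary perimeter,
# convex hull, Feret diameters by rotating calipers, and the
# moment-equivalent ellipse. All lengths are returned in mm via the mask's
# calibration; pixel centres are the point set throughout.

# Foreground pixel coordinates as (x = column, y = row).
mask_coords <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}

as_mask_matrix <- function(mask) {
  if (inherits(mask, "gradphen_mask")) mask$mask else mask
}

mask_cal <- function(mask, mm_per_px = NULL) {
  if (!is.null(mm_per_px)) return(mm_per_px)
  if (inherits(mask, "gradphen_mask") && is.finite(mask$mm_per_px)) {
    return(mask$mm_per_px)
  }
  stopf("mask carries no calibration; pass mm_per_px")
}

#' Bounding dimensions and area of a mask
#'
#' Height and width are the bounding-box extents of the foreground (in
#' pixels, converted to mm); area is the foreground pixel count times the
#' squared calibration. An empty mask yields zeros with `empty = TRUE`.
#'
#' @param mask A [plant_mask()] or logical matrix.
#' @param mm_per_px Calibration override (required for a bare matrix).
#' @return List with `height_mm`, `width_mm`, `area_mm2`, `empty`.
#' @export
measure_dimensions <- function(mask, mm_per_px = NULL) {
  m <- as_mask_matrix(mask)
  if (!any(m)) {
    return(list(height_mm = 0, width_mm = 0, area_mm2 = 0, empty = TRUE))
  }
  cal <- mask_cal(mask, mm_per_px)
  co <- mask_coords(m)
  list(
    height_mm = (max(co[, "y"]) - min(co[, "y"]) + 1) * cal,
    width_mm = (max(co[, "x"]) - min(co[, "x"]) + 1) * cal,
    area_mm2 = nrow(co) * cal^2,
    empty = FALSE
  )
}

#' Moment-equivalent ellipse of a mask
#'
#' The ellipse with the same second central moments as the foreground pixel
#' set: axes are `4 * sqrt(eigenvalue)` of the covariance matrix, so a
#' digitized disk of radius r yields axes close to 2r.
#'
#' @inheritParams measure_dimensions
#' @return List with `major_mm`, `minor_mm`, `angle` (radians, major axis
#'   vs x) and `degenerate` (TRUE for collinear regions).
#' @export
fit_ellipse <- function(mask, mm_per_px = NULL) {
  m <- as_mask_matrix(mask)
  co <- mask_coords(m)
  if (nrow(co) < 2) stopf("fit_ellipse needs at least 2 foreground pixels")
  cal <- mask_cal(mask, mm_per_px)
  x <- co[, "x"]; y <- co[, "y"]
  n <- length(x)
  mu20 <- sum((x - mean(x))^2) / n
  mu02 <- sum((y - mean(y))^2) / n
  mu11 <- sum((x - mean(x)) * (y - mean(y))) / n
  common <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (mu20 + mu02 + common) / 2
  l2 <- (mu20 + mu02 - common) / 2
  l2 <- max(l2, 0)
  angle <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  list(major_mm = 4 * sqrt(l1) * cal, minor_mm = 4 * sqrt(l2) * cal,
       angle = angle, degenerate = l2 < 1e-12)
}

# Outer 8-connected boundary chains of every component, 1-based (x, y).
boundary_chains <- function(m) {
  img <- EBImage::Image(t(m))
  lab <- EBImage::bwlabel(img)
  oc <- EBImage::ocontour(lab)
  lapply(oc, function(ct) ct + 1)
}

# Vossepoel-Smeulders perimeter of one closed chain (px units).
chain_perimeter <- function(ct) {
  if (nrow(ct) == 1) return(4)        # single pixel: unit-square convention
  d <- diff(rbind(ct, ct[1, , drop = FALSE]))
  steps <- sqrt(rowSums(d^2))
  ne <- sum(steps < 1.2)
  no <- sum(steps >= 1.2)
  dirs <- atan2(d[, 2], d[, 1])
  nc <- sum(abs(diff(c(dirs, dirs[1]))) > 1e-9)
  0.980 * ne + 1.406 * no - 0.091 * nc
}

# Each foreground pixel contributes its four unit-square corners, so the
# hull bounds the full pixel footprint: hull area >= pixel-count area and
# Feret extents match bounding extents on axis-aligned shapes.
pixel_corners <- function(m) {
  co <- mask_coords(m)
  x <- co[, "x"]; y <- co[, "y"]
  cbind(x = c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
        y = c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
}

# Convex hull vertices (closed, counter-clockwise in (x, y)) of a point set.
hull_vertices <- function(pts) {
  if (nrow(pts) == 1) return(pts)
  h <- grDevices::chull(pts[, 1], pts[, 2])
  pts[h, , drop = FALSE]
}

polygon_area <- function(v) {
  n <- nrow(v)
  if (n < 3) return(0)
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygon_perimeter <- function(v) {
  n <- nrow(v)
  if (n < 2) return(0)
  d <- diff(rbind(v, v[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# Rotating calipers over hull vertices: max Feret is the hull diameter;
# min Feret the smallest width over hull-edge directions.
feret_extremes <- function(hull) {
  n <- nrow(hull)
  if (n == 1) return(list(max = 0, min = 0))
  dmax <- 0
  for (i in seq_len(n - 1)) {
    d2 <- (hull[(i + 1):n, 1] - hull[i, 1])^2 +
      (hull[(i + 1):n, 2] - hull[i, 2])^2
    dmax <- max(dmax, d2)
  }
  dmax <- sqrt(dmax)
  if (n == 2) return(list(max = dmax, min = 0))
  wmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    # distance of every vertex from the line through edge i-j
    d <- abs((hull[, 1] - hull[i, 1]) * e[2] -
               (hull[, 2] - hull[i, 2]) * e[1]) / len
    wmin <- min(wmin, max(d))
  }
  list(max = dmax, min = wmin)
}

#' Perimeter, convex hull and Feret diameters of a mask
#'
#' The perimeter uses a weighted chain-code estimate on the 8-connected
#' outer boundary (0.980 per axial step, 1.406 per diagonal step, -0.091
#' per corner), summed over all retained components; interior holes are not
#' traced. The convex hull is taken over the unit-square corners of all
#' foreground pixels (so hull area always bounds the pixel-count area); max
#' and min Feret diameters come from rotating calipers over the hull, and
#' the mean Feret is the mean of the two extremes.
#'
#' @inheritParams measure_dimensions
#' @return List with `perimeter_mm`, `hull_area_mm2`, `hull_perimeter_mm`,
#'   `feret_max_mm`, `feret_min_mm`, `feret_mean_mm`, `degenerate`.
#' @export
hull_and_perimeter <- function(mask, mm_per_px = NULL) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stopf("hull_and_perimeter needs a non-empty mask")
  cal <- mask_cal(mask, mm_per_px)
  chains <- boundary_chains(m)
  per_px <- sum(vapply(chains, chain_perimeter, numeric(1)))
  hull <- hull_vertices(pixel_corners(m))
  fer <- feret_extremes(hull)
  degenerate <- nrow(hull) < 3
  list(
    perimeter_mm = per_px * cal,
    hull_area_mm2 = polygon_area(hull) * cal^2,
    hull_perimeter_mm = polygon_perimeter(hull) * cal,
    feret_max_mm = fer$max * cal,
    feret_min_mm = fer$min * cal,
    feret_mean_mm = (fer$max + fer$min) / 2 * cal,
    degenerate = degenerate
  )
}
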