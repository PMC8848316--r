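# Procedural rendering of plant scenes: a 2.5-D plant (stem + leaves as
# parametric ellipses with 3-D azimuth/elevation) projected into 6 side
# views over a 180° rotation and 1 top view, with the exact ground-truth
# mask retained per view. Side views show a dark plant on a bright back-lit
# background; the top view a bright plant on dark cloth.

#' Scene/rendering configuration
#'
#' @param width_px,height_px Frame size in pixels.
#' @param mm_per_px Spatial calibration applied to all scenes.
#' @param margin_px Free border the plant must not enter; a plant that would
#'   clip outside `frame - margin` raises an error rather than truncating.
#' @param side_background,top_background Background grey levels (0-255).
#' @param background_noise_sd Gaussian noise SD on background pixels.
#' @param chart If `TRUE`, a neutral reference patch is embedded in the
#'   top-left corner of every frame (drives white-balance and spatial
#'   calibration).
#' @param chart_rgb Nominal RGB of the patch.
#' @param chart_size_mm Physical edge length of the square patch (mm).
#' @param cast Length-3 per-channel gains applied to the finished frame
#'   (simulates an uncalibrated camera colour cast); `c(1, 1, 1)` is
#'   neutral.
#' @return A list of class `gradphen_scene_config`.
#' @export
scene_config <- function(width_px = 256L, height_px = 256L, mm_per_px = 1.0,
                         margin_px = 8L,
                         side_background = 245, top_background = 12,
                         background_noise_sd = 0,
                         chart = FALSE, chart_rgb = c(200, 200, 200),
                         chart_size_mm = 24,
                         cast = c(1, 1, 1)) {
  stopifnot(width_px > 32, height_px > 32, mm_per_px > 0, margin_px >= 0,
            length(cast) == 3, all(cast > 0), length(chart_rgb) == 3)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         mm_per_px = mm_per_px, margin_px = as.integer(margin_px),
         side_background = side_background, top_background = top_background,
         background_noise_sd = background_noise_sd,
         chart = chart, chart_rgb = as.numeric(chart_rgb),
         chart_size_mm = chart_size_mm, cast = as.numeric(cast)),
    class = "gradphen_scene_config"
  )
}

#' Construct an image record
#'
#' @param pixels H x W x 3 numeric array, values 0-255.
#' @param pot_uid Pot identifier.
#' @param view `"side"` or `"top"`.
#' @param frame Frame index (0-5 for side views, 0 for top).
#' @param day Acquisition day.
#' @param mm_per_px Spatial calibration, or `NA` until calibrated.
#' @return A list of class `gradphen_image`.
#' @export
image_record <- function(pixels, pot_uid, view = c("side", "top"),
                         frame = 0L, day = 0L, mm_per_px = NA_real_) {
  view <- match.arg(view)
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            min(pixels) >= 0, max(pixels) <= 255)
  if (view == "side" && frame > 5L) stopf("side frame index must be 0-5")
  if (view == "top" && frame != 0L) stopf("top view has a single frame 0")
  structure(
    list(pixels = pixels, pot_uid = pot_uid, view = view,
         frame = as.integer(frame), day = as.integer(day),
         mm_per_px = mm_per_px),
    class = "gradphen_image"
  )
}

# -- geometry -----------------------------------------------------------

# Draw a filled rotated ellipse into a logical mask (in place semantics via
# return). (cx, cy) in pixel coordinates: x = column, y = row from top.
draw_ellipse <- function(mask, cx, cy, a, b, angle) {
  H <- nrow(mask); W <- ncol(mask)
  ext <- max(a, b)
  x0 <- max(1L, floor(cx - ext)); x1 <- min(W, ceiling(cx + ext))
  y0 <- max(1L, floor(cy - ext)); y1 <- min(H, ceiling(cy + ext))
  if (x0 > x1 || y0 > y1) return(mask)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - cx)
  dy <- outer(ys - cy, rep(1, length(xs)))
  u <- (dx * cos(angle) + dy * sin(angle)) / a
  v <- (-dx * sin(angle) + dy * cos(angle)) / max(b, 0.5)
  hit <- (u * u + v * v) <= 1
  mask[ys, xs] <- mask[ys, xs] | hit
  mask
}

draw_rect <- function(mask, x0, x1, y0, y1) {
  H <- nrow(mask); W <- ncol(mask)
  xs <- max(1L, round(x0)):min(W, round(x1))
  ys <- max(1L, round(y0)):min(H, round(y1))
  if (length(xs) && length(ys)) mask[ys, xs] <- TRUE
  mask
}

# The stochastic "individual": fixed leaf azimuths, attachment fractions,
# length fractions and sub-plant offsets drawn once per pot so that views
# and days are mutually consistent.
plant_geometry <- function(m, seed) {
  with_seed(seed, {
    n <- m$n_leaves
    golden <- 2.39996
    geo <- list(
      phi = (seq_len(n) * golden + stats::runif(1, 0, 2 * pi) +
               stats::rnorm(n, 0, 0.15)) %% (2 * pi),
      attach = switch(m$habit,
        caulescent = 0.25 + 0.73 * (seq_len(n) - 1) / max(1, n - 1),
        bush = 0.3 + 0.6 * stats::runif(n),
        stats::runif(n, 0, 0.05)),            # rosette/grass: basal
      len_frac = stats::runif(n, 0.65, 1),
      elev_jit = stats::rnorm(n, 0, 3) * pi / 180,
      subplants = if (m$habit == "bush") {
        k <- max(1L, as.integer(m$n_plants))
        list(off = stats::runif(k, -0.33, 0.33), scale = stats::runif(k, 0.55, 0.85))
      } else {
        list(off = 0, scale = 1)
      }
    )
    geo
  })
}

# Leaf set in 3-D for a plant of given height/width (mm). Each leaf:
# attachment z (mm above soil), azimuth, elevation, length, width (mm).
leaf_set <- function(m, geo, height_mm, width_mm, area_mult) {
  n <- m$n_leaves
  e0 <- m$leaf_angle_deg * pi / 180
  elev <- pmin(pmax(e0 + geo$elev_jit, 0.03), pi / 2 - 0.03)
  lw_scale <- sqrt(area_mult)
  if (m$habit == "rosette") {
    len <- (width_mm / 2) * geo$len_frac * lw_scale
    elev <- rep(asin(min(1, height_mm / max(len))), n)
    z <- rep(0, n)
  } else if (m$habit == "grass") {
    len <- (height_mm / sin(max(elev))) * geo$len_frac * lw_scale
    len <- pmin(len, height_mm / sin(elev))  # no leaf overtops the plant
    z <- rep(0, n)
  } else { # caulescent / bush sub-plant
    len <- (width_mm / 2) / cos(min(elev)) * geo$len_frac * lw_scale
    z <- geo$attach * height_mm
  }
  wid <- pmax(len * m$leaf_aspect * lw_scale, 1.5)
  list(phi = geo$phi, elev = elev, z = z, len = len, wid = wid)
}

# Rasterize one plant into side-view (theta) or top-view mask.
draw_plant <- function(mask, m, leaves, height_mm, base_x_mm, cal, view,
                       theta = 0, base_row = NULL) {
  px <- function(mm) mm / cal
  H <- nrow(mask); W <- ncol(mask)
  if (view == "side") {
    bx <- W / 2 + px(base_x_mm)
    by <- base_row
    if (m$habit %in% c("caulescent", "bush")) {
      stem_h <- px(height_mm * 0.95)
      mask <- draw_rect(mask, bx - max(1, px(2)), bx + max(1, px(2)),
                        by - stem_h, by)
      # growing tip closes the gap to the nominal height
      mask <- draw_ellipse(mask, bx, by - px(height_mm) + px(3), px(3.2),
                           px(3.2), 0)
    }
    for (i in seq_along(leaves$phi)) {
      dxp <- cos(leaves$elev[i]) * cos(leaves$phi[i] - theta) * leaves$len[i]
      dz <- sin(leaves$elev[i]) * leaves$len[i]
      plen <- sqrt(dxp^2 + dz^2)
      cx <- bx + px(dxp / 2)
      cy <- by - px(leaves$z[i]) - px(dz / 2)
      ang <- atan2(-dz, dxp)  # image y runs downward
      mask <- draw_ellipse(mask, cx, cy, max(px(plen / 2), 1),
                           max(px(leaves$wid[i] / 2), 1), ang)
    }
  } else { # top
    bx <- W / 2 + px(base_x_mm)
    by <- H / 2
    mask <- draw_ellipse(mask, bx, by, max(px(4), 2), max(px(4), 2), 0)
    for (i in seq_along(leaves$phi)) {
      lxy <- cos(leaves$elev[i]) * leaves$len[i]
      cx <- bx + px(cos(leaves$phi[i]) * lxy / 2)
      cy <- by - px(sin(leaves$phi[i]) * lxy / 2)
      mask <- draw_ellipse(mask, cx, cy, max(px(lxy / 2), 1),
                           max(px(leaves$wid[i] / 2), 1), -leaves$phi[i])
    }
  }
  mask
}

# Mask-derived truth for one view (same conventions as the descriptor
# contracts: bounding-box extents, pixel-count area).
mask_truth <- function(mask, cal) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(list(height_mm = 0, width_mm = 0, area_mm2 = 0))
  }
  list(
    height_mm = (max(idx[, 1]) - min(idx[, 1]) + 1) * cal,
    width_mm = (max(idx[, 2]) - min(idx[, 2]) + 1) * cal,
    area_mm2 = nrow(idx) * cal^2
  )
}

# -- scene rendering ----------------------------------------------------

#' Render a full scene (6 side views + 1 top view) for one pot and day
#'
#' The plant's dimensions follow the morphotype's saturating growth curve;
#' its per-trait multipliers `1 + slope(day) * ln(ratio)` implement the
#' light-quality response; multiplicative log-normal noise (truncated at
#' 2.5 SD) perturbs dimensions and Gaussian noise the colours, unless
#' `noise = FALSE`.
#'
#' @param m A [morphotype()].
#' @param light One row of a [build_light_map()] table (needs `ratio`), or
#'   a list with a `ratio` element.
#' @param day Day since treatment start (>= 0).
#' @param seed Integer seed; the plant individual is derived from it
#'   independently of `day`, so the same seed yields a consistent plant
#'   across the time course.
#' @param config A [scene_config()].
#' @param pot_uid Identifier stored in the image records.
#' @param noise Disable all stochastic perturbation with `FALSE`
#'   (noiseless scenes render identically for any seed).
#' @return A list of class `gradphen_scene` with elements `images` (named
#'   list of 7 [image_record()]s), `masks` (matching logical matrices),
#'   `truth_views` (per-view tibble) and `truth` (one-row aggregate tibble
#'   with `true_`-prefixed columns).
#' @export
render_scene <- function(m, light, day, seed = 1L, config = scene_config(),
                         pot_uid = "R1-r01-c01", noise = TRUE) {
  stopifnot(inherits(m, "gradphen_morphotype"), day >= 0)
  ratio <- light$ratio
  stopifnot(is.numeric(ratio), ratio > 0)
  cal <- config$mm_per_px

  geo <- plant_geometry(m, derive_seed(seed, "geom"))
  g <- growth_fraction(m, day)
  nz <- if (noise && m$dim_noise_cv > 0) {
    with_seed(derive_seed(seed, "dimnoise", day), {
      z <- pmin(pmax(stats::rnorm(3), -2.5), 2.5)
      exp(m$dim_noise_cv * z)
    })
  } else {
    c(1, 1, 1)
  }
  height_mm <- m$height_mm * g * trait_multiplier(m, "height", day, ratio) * nz[1]
  width_mm <- m$width_mm * g * trait_multiplier(m, "width", day, ratio) * nz[2]
  area_mult <- trait_multiplier(m, "area", day, ratio) * nz[3]
  green_mult <- trait_multiplier(m, "greenness", day, ratio)

  # clip check before drawing
  max_h <- (config$height_px - 2 * config$margin_px) * cal
  max_w <- (config$width_px - 2 * config$margin_px) * cal
  if (height_mm > max_h || width_mm > max_w) {
    stopf(paste0("plant (%.0f x %.0f mm) exceeds frame (%.0f x %.0f mm); ",
                 "enlarge the frame or coarsen mm_per_px"),
          height_mm, width_mm, max_h, max_w)
  }

  sub <- geo$subplants
  views <- c(sprintf("side_%d", 0:5), "top_0")
  masks <- list()
  for (v in views) {
    mk <- matrix(FALSE, config$height_px, config$width_px)
    is_top <- v == "top_0"
    theta <- if (is_top) 0 else (as.integer(sub("side_", "", v))) * pi / 6
    base_row <- config$height_px - config$margin_px
    for (k in seq_along(sub$off)) {
      sc <- sub$scale[k]
      lv <- leaf_set(m, geo, height_mm * sc, width_mm * sc, area_mult)
      off_mm <- sub$off[k] * width_mm
      off_eff <- if (is_top) off_mm else off_mm * cos(theta)
      mk <- draw_plant(mk, m, lv, height_mm * sc, off_eff, cal,
                       if (is_top) "top" else "side", theta, base_row)
    }
    masks[[v]] <- mk
  }

  # colour the frames
  base_col <- m$color
  base_col[2] <- clip255(base_col[2] * green_mult)
  images <- list()
  for (v in views) {
    is_top <- v == "top_0"
    bg <- if (is_top) config$top_background else config$side_background
    plant_col <- if (is_top) base_col else base_col * 0.75  # back-lit, darker
    mk <- masks[[v]]
    npx <- length(mk)
    img <- array(0, dim = c(nrow(mk), ncol(mk), 3))
    cseed <- derive_seed(seed, "color", day, v)
    chans <- with_seed(cseed, {
      lapply(1:3, function(ch) {
        plane <- matrix(bg, nrow(mk), ncol(mk))
        if (noise && config$background_noise_sd > 0) {
          plane <- plane + matrix(stats::rnorm(npx, 0, config$background_noise_sd),
                                  nrow(mk))
        }
        vals <- rep(plant_col[ch], sum(mk))
        if (noise && m$color_noise_sd > 0) {
          vals <- vals + stats::rnorm(length(vals), 0, m$color_noise_sd)
        }
        plane[mk] <- vals
        clip255(plane)
      })
    })
    for (ch in 1:3) img[, , ch] <- chans[[ch]]
    if (config$chart) {
      side_px <- round(config$chart_size_mm / cal)
      rows <- (config$margin_px + 1):(config$margin_px + side_px)
      cols <- rows
      for (ch in 1:3) img[rows, cols, ch] <- config$chart_rgb[ch]
    }
    if (any(config$cast != 1)) {
      for (ch in 1:3) img[, , ch] <- clip255(img[, , ch] * config$cast[ch])
    }
    frame <- if (is_top) 0L else as.integer(sub("side_", "", v))
    images[[v]] <- image_record(img, pot_uid,
                                if (is_top) "top" else "side",
                                frame, day, cal)
  }

  tv <- dplyr::bind_rows(lapply(views, function(v) {
    t <- mask_truth(masks[[v]], cal)
    mk <- masks[[v]]
    is_top <- v == "top_0"
    pc <- if (is_top) base_col else base_col * 0.75
    tibble::tibble(
      view = if (is_top) "top" else "side",
      frame = if (is_top) 0L else as.integer(sub("side_", "", v)),
      height_mm = t$height_mm, width_mm = t$width_mm,
      area_mm2 = t$area_mm2,
      red_mean = pc[1], green_mean = pc[2], blue_mean = pc[3]
    )
  }))
  side <- tv[tv$view == "side", ]
  top <- tv[tv$view == "top", ]
  truth <- tibble::tibble(
    pot_uid = pot_uid, day = as.integer(day), ratio = ratio,
    true_HeightMax = max(side$height_mm),
    true_WidthMax = max(side$width_mm),
    true_AreaMean = mean(side$area_mm2),
    true_Area = top$area_mm2,
    true_Voxel = sqrt(max(side$area_mm2) * min(side$area_mm2) * top$area_mm2),
    true_side_RedMean = mean(side$red_mean),
    true_side_GreenMean = mean(side$green_mean),
    true_side_BlueMean = mean(side$blue_mean),
    true_top_RedMean = top$red_mean,
    true_top_GreenMean = top$green_mean,
    true_top_BlueMean = top$blue_mean
  )
  structure(list(images = images, masks = masks, truth_views = tv,
                 truth = truth, morphotype = m$name),
            class = "gradphen_scene")
}
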