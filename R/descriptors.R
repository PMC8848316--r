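# Descriptor computation: the full measured parameter set per view
# (dimensions, fitted-ellipse and convex-hull shape factors, RGB/HSB colour
# statistics and vegetation indices), and the aggregation of 6 side views
# plus 1 top view into one record per pot and day.

#' Shape factors from region measurements
#'
#' Unitless silhouette descriptors:
#' roundness = minor/major ellipse axis; solidity = area / hull area;
#' convexity = hull perimeter / perimeter; circularity = 4 pi area /
#' perimeter^2; compactness = sqrt(4 area / pi) / major axis. A zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param area,perimeter Region area and perimeter (consistent units).
#' @param hull_area,hull_perimeter Convex-hull area and perimeter.
#' @param major_axis,minor_axis Fitted-ellipse axes.
#' @return Tibble with `Roundness`, `Solidity`, `Convexity`, `Circularity`,
#'   `Compactness`.
#' @export
shape_factors <- function(area, perimeter, hull_area, hull_perimeter,
                          major_axis, minor_axis) {
  safe_div <- function(num, den) ifelse(is.na(den) | den <= 0, NA_real_,
                                        num / den)
  tibble::tibble(
    Roundness = safe_div(minor_axis, major_axis),
    Solidity = safe_div(area, hull_area),
    Convexity = safe_div(hull_perimeter, perimeter),
    Circularity = safe_div(4 * pi * area, perimeter^2),
    Compactness = safe_div(sqrt(4 * area / pi), major_axis)
  )
}

#' Colour statistics over the plant pixels
#'
#' RGB and HSB channel means on the 0-255 scale (HSB via the standard
#' RGB-to-HSV transform), the hue coefficient of variation
#' `100 * sd(hue) / mean(hue)` (linear statistics on the 0-255 hue
#' channel; a `hue_wrap` flag marks foregrounds whose hue values straddle
#' the 0/255 discontinuity), and the integrated density
#' `foreground pixel count * mean grey value` with grey = (R + G + B) / 3.
#'
#' @param image An [image_record()].
#' @param mask A [plant_mask()] aligned with the image.
#' @return One-row tibble: `RedMean`, `GreenMean`, `BlueMean`, `HueMean`,
#'   `HueCv`, `SaturationMean`, `BrightnessMean`, `Density`, `hue_wrap`.
#'   All statistics are `NA` for an empty mask.
#' @export
color_statistics <- function(image, mask) {
  stopifnot(inherits(image, "gradphen_image"))
  m <- as_mask_matrix(mask)
  stopifnot(all(dim(m) == dim(image$pixels)[1:2]))
  if (!any(m)) {
    return(tibble::tibble(RedMean = NA_real_, GreenMean = NA_real_,
                          BlueMean = NA_real_, HueMean = NA_real_,
                          HueCv = NA_real_, SaturationMean = NA_real_,
                          BrightnessMean = NA_real_, Density = NA_real_,
                          hue_wrap = FALSE))
  }
  r <- image$pixels[, , 1][m]
  g <- image$pixels[, , 2][m]
  b <- image$pixels[, , 3][m]
  hsv <- grDevices::rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  hue <- hsv[1, ] * 255
  sat <- hsv[2, ] * 255
  bri <- hsv[3, ] * 255
  grey <- (r + g + b) / 3
  hue_wrap <- (max(hue) - min(hue)) > 200
  tibble::tibble(
    RedMean = mean(r), GreenMean = mean(g), BlueMean = mean(b),
    HueMean = mean(hue),
    HueCv = if (mean(hue) > 0) 100 * stats::sd(hue) / mean(hue) else NA_real_,
    SaturationMean = mean(sat), BrightnessMean = mean(bri),
    Density = length(grey) * mean(grey),
    hue_wrap = hue_wrap
  )
}

#' RGB vegetation indices and predicted chlorophyll content
#'
#' Evaluates, from mean channel values on the 0-255 scale:
#' the green leaf index `GLI = (2G - R - B) / (2G + R + B)`, the
#' triangular greenness index
#' `TGI = ((670 - 480)(R - G) - (670 - 550)(R - B)) / -200`, and the
#' RGB-regression chlorophyll estimate
#' `Chl = 440 + 7.266 B + 10.873 R - 15.545 G` (µmol m^-2).
#'
#' @param red,green,blue Mean channel values in [0, 255]; vectorized.
#' @return Tibble with `GLI`, `TGI`, `Chl_predicted`. `GLI` is `NA` when
#'   its denominator is 0 (all-black input).
#' @export
color_indices <- function(red, green, blue) {
  stopifnot(all(red >= 0 & red <= 255, na.rm = TRUE),
            all(green >= 0 & green <= 255, na.rm = TRUE),
            all(blue >= 0 & blue <= 255, na.rm = TRUE))
  den <- 2 * green + red + blue
  tibble::tibble(
    GLI = ifelse(den == 0, NA_real_, (2 * green - red - blue) / den),
    TGI = ((670 - 480) * (red - green) - (670 - 550) * (red - blue)) / -200,
    Chl_predicted = 440 + blue * 7.266 + red * 10.873 + green * -15.545
  )
}

#' Measure every per-view descriptor for one image + mask
#'
#' @param image An [image_record()].
#' @param mask The matching [plant_mask()].
#' @return One-row tibble with dimensions (mm), hull/Feret/ellipse
#'   measurements, shape factors and colour statistics; `empty = TRUE`
#'   rows carry zeros/`NA`s.
#' @export
measure_view <- function(image, mask) {
  dims <- measure_dimensions(mask)
  base <- tibble::tibble(
    pot_uid = mask$pot_uid, day = mask$day, view = mask$view,
    frame = image$frame,
    Height = dims$height_mm, Width = dims$width_mm, Area = dims$area_mm2,
    empty = dims$empty
  )
  if (dims$empty) {
    geom <- tibble::tibble(
      Perimeter = NA_real_, HullArea = NA_real_, HullPerimeter = NA_real_,
      FeretMax = NA_real_, FeretMin = NA_real_, MeanFeret = NA_real_,
      MajorAxis = NA_real_, MinorAxis = NA_real_
    )
    sf <- shape_factors(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                        NA_real_)
    col <- color_statistics(image, mask)
    return(dplyr::bind_cols(base, geom, sf, col))
  }
  hp <- hull_and_perimeter(mask)
  el <- if (sum(mask$mask) >= 2) {
    fit_ellipse(mask)
  } else {
    list(major_mm = NA_real_, minor_mm = NA_real_)
  }
  geom <- tibble::tibble(
    Perimeter = hp$perimeter_mm, HullArea = hp$hull_area_mm2,
    HullPerimeter = hp$hull_perimeter_mm,
    FeretMax = hp$feret_max_mm, FeretMin = hp$feret_min_mm,
    MeanFeret = hp$feret_mean_mm,
    MajorAxis = el$major_mm, MinorAxis = el$minor_mm
  )
  sf <- shape_factors(dims$area_mm2, hp$perimeter_mm, hp$hull_area_mm2,
                      hp$hull_perimeter_mm, el$major_mm, el$minor_mm)
  col <- color_statistics(image, mask)
  dplyr::bind_cols(base, geom, sf, col)
}

side_agg_cols <- c("Roundness", "Solidity", "Convexity", "Circularity",
                   "Compactness", "HueMean", "HueCv", "SaturationMean",
                   "BrightnessMean", "RedMean", "GreenMean", "BlueMean",
                   "Density")

#' Aggregate per-view measurements into one descriptor record
#'
#' Side views contribute `HeightMax`/`WidthMax` (maximum over views),
#' `AreaMean` (mean) and view-mean shape/colour factors; the top view
#' contributes its area, mean Feret, shape/colour factors and the colour
#' indices (GLI, TGI, predicted chlorophyll, computed from the top-view
#' mean channel values). The volume proxy is
#' `Voxel = sqrt(max side area * min side area * top area)` (mm^3).
#'
#' @param views Tibble of [measure_view()] rows for one pot and day:
#'   normally 6 side rows and 1 top row. Fewer side views are accepted and
#'   flagged; without a top view all top descriptors and Voxel are `NA`.
#' @return One-row tibble keyed by `pot_uid` and `day` with `side_`- and
#'   `top_`-prefixed descriptor columns plus `Voxel` and quality flags.
#' @export
aggregate_views <- function(views) {
  stopifnot(is.data.frame(views), all(c("view", "Area") %in% names(views)))
  side <- views[views$view == "side" & !views$empty, ]
  top <- views[views$view == "top" & !views$empty, ]
  if (nrow(views[views$view == "top", ]) > 1) {
    stopf("expected a single top view, got %d", nrow(top))
  }
  out <- tibble::tibble(
    pot_uid = views$pot_uid[1], day = views$day[1],
    n_side_views = nrow(side),
    incomplete = nrow(side) < 6 || nrow(top) < 1
  )
  if (nrow(side) > 0) {
    out$side_HeightMax <- max(side$Height)
    out$side_WidthMax <- max(side$Width)
    out$side_AreaMean <- mean(side$Area)
    for (cn in side_agg_cols) out[[paste0("side_", cn)]] <- mean(side[[cn]])
  } else {
    out$side_HeightMax <- NA_real_
    out$side_WidthMax <- NA_real_
    out$side_AreaMean <- NA_real_
    for (cn in side_agg_cols) out[[paste0("side_", cn)]] <- NA_real_
  }
  if (nrow(top) == 1) {
    out$top_Area <- top$Area
    out$top_MeanFeret <- top$MeanFeret
    for (cn in side_agg_cols) out[[paste0("top_", cn)]] <- top[[cn]]
    idx <- color_indices(top$RedMean, top$GreenMean, top$BlueMean)
    out$top_GLI <- idx$GLI
    out$top_TGI <- idx$TGI
    out$top_Chl_predicted <- idx$Chl_predicted
  } else {
    out$top_Area <- NA_real_
    out$top_MeanFeret <- NA_real_
    for (cn in side_agg_cols) out[[paste0("top_", cn)]] <- NA_real_
    out$top_GLI <- NA_real_
    out$top_TGI <- NA_real_
    out$top_Chl_predicted <- NA_real_
  }
  out$Voxel <- if (nrow(side) > 0 && nrow(top) == 1) {
    sqrt(max(side$Area) * min(side$Area) * top$Area)
  } else {
    NA_real_
  }
  out
}

#' Descriptor column schema
#'
#' The canonical descriptor column names produced by [aggregate_views()],
#' in output order.
#'
#' @return Character vector of column names.
#' @export
descriptor_schema <- function() {
  c("pot_uid", "day", "n_side_views", "incomplete",
    "side_HeightMax", "side_WidthMax", "side_AreaMean",
    paste0("side_", side_agg_cols),
    "top_Area", "top_MeanFeret", paste0("top_", side_agg_cols),
    "top_GLI", "top_TGI", "top_Chl_predicted", "Voxel")
}
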