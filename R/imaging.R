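# Imaging: white balance against a neutral reference patch, spatial
# calibration from the patch's known physical size, and plant/background
# segmentation. Side views hold a dark plant on a bright back-lit
# background (segmented on inverted brightness); top views a bright plant
# on dark cloth (segmented on excess green, 2G - R - B).

#' Reference colour chart description
#'
#' @param x0,y0 Top-left pixel (column, row) of the neutral patch.
#' @param width_px,height_px Patch extent in pixels.
#' @param nominal_rgb Nominal patch colour (a neutral grey).
#' @param size_mm Physical edge length of the patch (mm); with the known
#'   pixel extent this yields the spatial calibration.
#' @return A list of class `gradphen_color_reference`.
#' @export
color_reference <- function(x0, y0, width_px, height_px,
                            nominal_rgb = c(200, 200, 200), size_mm = 24) {
  stopifnot(width_px > 0, height_px > 0, size_mm > 0,
            length(nominal_rgb) == 3)
  structure(
    list(x0 = as.integer(x0), y0 = as.integer(y0),
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         nominal_rgb = as.numeric(nominal_rgb), size_mm = size_mm),
    class = "gradphen_color_reference"
  )
}

chart_pixels <- function(image, ref) {
  d <- dim(image$pixels)
  if (ref$y0 + ref$height_px - 1 > d[1] || ref$x0 + ref$width_px - 1 > d[2] ||
      ref$x0 < 1 || ref$y0 < 1) {
    stopf("reference patch (%d:%d, %d:%d) lies outside the %dx%d frame",
          ref$y0, ref$y0 + ref$height_px - 1, ref$x0,
          ref$x0 + ref$width_px - 1, d[1], d[2])
  }
  rows <- ref$y0:(ref$y0 + ref$height_px - 1)
  cols <- ref$x0:(ref$x0 + ref$width_px - 1)
  image$pixels[rows, cols, , drop = FALSE]
}

#' White-balance an image against its neutral patch
#'
#' Applies per-channel linear gains chosen so that the neutral patch's
#' channel means all equal their common mean; output is clipped to
#' [0, 255]. Applying the correction twice changes nothing beyond rounding.
#'
#' @param image An [image_record()].
#' @param ref A [color_reference()] locating the neutral patch.
#' @return The corrected [image_record()].
#' @export
white_balance <- function(image, ref) {
  stopifnot(inherits(image, "gradphen_image"),
            inherits(ref, "gradphen_color_reference"))
  patch <- chart_pixels(image, ref)
  ch_means <- apply(patch, 3, mean)
  if (any(ch_means <= 1)) {
    stopf("neutral patch unreadable (channel means %s); chart occluded?",
          paste(round(ch_means, 1), collapse = "/"))
  }
  gains <- mean(ch_means) / ch_means
  out <- image
  for (ch in 1:3) out$pixels[, , ch] <- clip255(image$pixels[, , ch] * gains[ch])
  out
}

#' Spatial calibration from the detected patch size
#'
#' @param ref A [color_reference()] (provides the physical size).
#' @param detected_px Detected patch edge length in pixels; defaults to the
#'   reference's nominal pixel width.
#' @return mm-per-pixel calibration factor.
#' @export
spatial_calibration <- function(ref, detected_px = ref$width_px) {
  stopifnot(inherits(ref, "gradphen_color_reference"))
  if (detected_px <= 0) stopf("detected patch size must be positive")
  ref$size_mm / detected_px
}

#' Construct a plant mask object
#'
#' @param mask Logical matrix (TRUE = plant).
#' @param mm_per_px Calibration carried from the image.
#' @param view,pot_uid,day Propagated metadata.
#' @param empty Flag set when segmentation found no plant.
#' @return A list of class `gradphen_mask`.
#' @export
plant_mask <- function(mask, mm_per_px, view = "side", pot_uid = NA_character_,
                       day = NA_integer_, empty = !any(mask)) {
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(
    list(mask = mask, mm_per_px = mm_per_px, view = view,
         pot_uid = pot_uid, day = as.integer(day), empty = empty),
    class = "gradphen_mask"
  )
}

# Otsu threshold on a [0,1]-scaled matrix.
otsu_threshold <- function(x01) {
  EBImage::otsu(EBImage::Image(t(x01)), range = c(0, 1))
}

#' Segment the plant from the background
#'
#' `method = "grey"` thresholds inverted brightness (side views: plant
#' darker than the back-lit background); `method = "color"` thresholds the
#' excess-green index 2G - R - B (top views: green plant on dark cloth).
#' The threshold is chosen automatically (Otsu) unless given. Connected
#' components smaller than `min_area_px` are dropped; all remaining
#' components together form the mask (multi-plant pots are one specimen).
#' An empty mask is returned flagged, not raised as an error.
#'
#' @param image An [image_record()] (calibration should be set).
#' @param method `"grey"` or `"color"`; default picked from the view.
#' @param threshold Fixed threshold on the segmentation channel (0-1
#'   scale), or `NULL` for automatic selection.
#' @param min_area_px Minimum component area kept.
#' @param exclude Optional list `(x0, y0, width_px, height_px)` (or a
#'   [color_reference()]) masked out before segmentation, e.g. the chart.
#' @return A [plant_mask()].
#' @export
segment <- function(image, method = NULL, threshold = NULL,
                    min_area_px = 25L, exclude = NULL) {
  stopifnot(inherits(image, "gradphen_image"))
  method <- method %||% if (image$view == "top") "color" else "grey"
  method <- match.arg(method, c("grey", "color"))
  px <- image$pixels / 255
  score <- if (method == "grey") {
    1 - (px[, , 1] + px[, , 2] + px[, , 3]) / 3   # darker = higher
  } else {
    clip01((2 * px[, , 2] - px[, , 1] - px[, , 3] + 2) / 4)  # ExG to [0,1]
  }
  if (!is.null(exclude)) {
    rows <- exclude$y0:(exclude$y0 + exclude$height_px - 1)
    cols <- exclude$x0:(exclude$x0 + exclude$width_px - 1)
    score[rows, cols] <- 0
  }
  thr <- threshold %||% otsu_threshold(score)
  fg <- score > thr
  if (any(fg)) {
    lab <- EBImage::bwlabel(EBImage::Image(t(fg)))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_area_px)
    fg <- t(matrix(as.integer(lab) %in% keep, nrow = nrow(lab)))
  }
  plant_mask(fg, image$mm_per_px, image$view, image$pot_uid, image$day)
}

#' Read an image file into an image record
#'
#' @param path PNG or TIFF file.
#' @param pot_uid,view,frame,day Metadata; parsed from a
#'   `<potUID>_<day>_<view>_<frame>` file name when omitted.
#' @param mm_per_px Calibration to attach.
#' @return An [image_record()].
#' @export
read_image <- function(path, pot_uid = NULL, view = NULL, frame = NULL,
                       day = NULL, mm_per_px = NA_real_) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  base <- tools::file_path_sans_ext(basename(path))
  parts <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(parts) >= 4) {
    pot_uid <- pot_uid %||% parts[1]
    day <- day %||% as.integer(parts[2])
    view <- view %||% parts[3]
    frame <- frame %||% as.integer(parts[4])
  }
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    a <- EBImage::readImage(path)
    d <- dim(a)
    aperm(a, c(2, 1, 3))
  } else {
    png::readPNG(path)
  }
  if (length(dim(arr)) == 2) arr <- array(rep(arr, 3), c(dim(arr), 3))
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  image_record(arr * 255, pot_uid %||% base, view %||% "side",
               frame %||% 0L, day %||% 0L, mm_per_px)
}

#' Write a plant mask as a 1-bit style PNG
#'
#' @param mask A [plant_mask()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "gradphen_mask"))
  png::writePNG(matrix(as.numeric(mask$mask), nrow(mask$mask)), path)
  invisible(path)
}
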