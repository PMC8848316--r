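# Whole-experiment generation: scenes for every pot and scheduled day,
# written as PNG files with metadata and ground-truth tables, plus a fast
# rendering-free path that simulates descriptor tables directly from the
# parametric model.

#' Twice-weekly imaging schedule
#'
#' @param treatment_days Length of the gradient treatment (days).
#' @param sessions_per_week Imaging sessions per week.
#' @param post_days Days of follow-up after the treatment ends (imaged on
#'   the same cadence).
#' @return Sorted integer vector of imaging days, starting at day 0.
#' @export
imaging_schedule <- function(treatment_days = 30, sessions_per_week = 2,
                             post_days = 0) {
  stopifnot(treatment_days > 0, sessions_per_week >= 1)
  step <- 7 / sessions_per_week
  days <- unique(as.integer(round(seq(0, treatment_days + post_days,
                                      by = step))))
  days[days <= treatment_days + post_days]
}

#' Generate a complete synthetic experiment on disk
#'
#' Renders one scene (6 side + 1 top view) per pot per scheduled day and
#' writes 8-bit RGB PNGs named `<potUID>_<day>_<view>_<frame>.png`, a
#' metadata table `metadata.csv` (pot_uid, species, room, row, column,
#' ratio, ppfd, day, mm_per_px) and a ground-truth table `truth.csv`
#' (`true_`-prefixed descriptor columns).
#'
#' @param layout A [build_layout()] result.
#' @param light_map Matching [build_light_map()] result.
#' @param morphotypes Named list of [morphotype()]s covering every species
#'   in the layout.
#' @param schedule Integer vector of imaging days (see
#'   [imaging_schedule()]).
#' @param seed Integer master seed; per-pot streams are derived from it.
#' @param dir Output directory (created; must be empty unless
#'   `overwrite = TRUE`).
#' @param config A [scene_config()].
#' @param noise Passed to [render_scene()].
#' @param treatment_days Stored in the metadata so post-treatment sessions
#'   can be flagged downstream.
#' @param overwrite Allow writing into a non-empty directory.
#' @return Invisibly, a list with `dir`, `metadata`, `truth`.
#' @export
generate_experiment <- function(layout, light_map,
                                morphotypes = default_morphotypes(),
                                schedule = imaging_schedule(),
                                seed = 1L, dir,
                                config = scene_config(),
                                noise = TRUE,
                                treatment_days = 30,
                                overwrite = FALSE) {
  stopifnot(inherits(layout, "gradphen_layout"), length(schedule) >= 1,
            !is.unsorted(schedule))
  if (!all(layout$species %in% names(morphotypes))) {
    stopf("missing morphotypes for: %s",
          paste(setdiff(layout$species, names(morphotypes)), collapse = ", "))
  }
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stopf("output directory '%s' is not empty (use overwrite = TRUE)", dir)
  }
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)

  lm_idx <- match(layout$pot_uid, light_map$pot_uid)
  if (anyNA(lm_idx)) stopf("light map does not cover every pot in the layout")

  meta <- list(); truth <- list(); k <- 0L
  for (i in seq_len(nrow(layout))) {
    pot <- layout[i, ]
    light <- light_map[lm_idx[i], ]
    m <- morphotypes[[pot$species]]
    pot_seed <- derive_seed(seed, pot$pot_uid)
    for (day in schedule) {
      sc <- tryCatch(
        render_scene(m, light, day, seed = pot_seed, config = config,
                     pot_uid = pot$pot_uid, noise = noise),
        error = function(e) stopf("pot %s day %d: %s", pot$pot_uid, day,
                                  conditionMessage(e))
      )
      for (v in names(sc$images)) {
        rec <- sc$images[[v]]
        fn <- sprintf("%s_%d_%s_%d.png", pot$pot_uid, day, rec$view,
                      rec$frame)
        ok <- tryCatch({
          png::writePNG(aperm(rec$pixels, c(1, 2, 3)) / 255,
                        file.path(img_dir, fn))
          TRUE
        }, error = function(e) {
          stopf("pot %s day %d view %s: image write failed (%s)",
                pot$pot_uid, day, v, conditionMessage(e))
        })
      }
      k <- k + 1L
      meta[[k]] <- tibble::tibble(
        pot_uid = pot$pot_uid, species = pot$species, room = pot$room,
        row = pot$row, column = pot$column, ratio = light$ratio,
        ppfd = light$ppfd, day = as.integer(day),
        mm_per_px = config$mm_per_px,
        post_treatment = day > treatment_days
      )
      truth[[k]] <- dplyr::bind_cols(
        sc$truth[, c("pot_uid", "day")],
        tibble::tibble(species = pot$species, ratio = light$ratio),
        sc$truth[, !(names(sc$truth) %in% c("pot_uid", "day", "ratio"))]
      )
    }
  }
  metadata <- dplyr::bind_rows(meta)
  truth_tab <- dplyr::bind_rows(truth)
  utils::write.csv(metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(truth_tab, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(list(dir = dir, metadata = metadata, truth = truth_tab))
}

# Habit-specific silhouette bases of the parametric descriptor model:
# nominal solidity/circularity per view for each plant architecture.
habit_shape_base <- function(habit) {
  switch(habit,
    rosette = c(side_sol = 0.80, side_circ = 0.55, top_sol = 0.75,
                top_circ = 0.45, top_round = 0.88),
    caulescent = c(side_sol = 0.55, side_circ = 0.18, top_sol = 0.60,
                   top_circ = 0.30, top_round = 0.80),
    grass = c(side_sol = 0.35, side_circ = 0.08, top_sol = 0.40,
              top_circ = 0.12, top_round = 0.62),
    bush = c(side_sol = 0.60, side_circ = 0.30, top_sol = 0.65,
             top_circ = 0.35, top_round = 0.85)
  )
}

#' Simulate a descriptor table directly from the parametric model
#'
#' Bypasses rendering: evaluates the morphotype growth, effect and noise
#' model for every pot and day and returns a full ground-truth descriptor
#' table in the [descriptor_schema()] layout. Dimensions follow the same
#' growth/effect/noise path as [render_scene()]; shape factors are smooth
#' habit-specific functions of the morphotype geometry parameters; colour
#' statistics derive from the (effect-shifted) base colour. This is the
#' fast path for studying the gradient and multivariate statistics
#' themselves.
#'
#' @inheritParams generate_experiment
#' @return Tibble with one row per pot x day: keys (`pot_uid`, `species`,
#'   `day`, `ratio`, `post_treatment`) plus every [descriptor_schema()]
#'   descriptor column.
#' @export
simulate_descriptor_truth <- function(layout, light_map,
                                      morphotypes = default_morphotypes(),
                                      schedule = imaging_schedule(),
                                      seed = 1L, noise = TRUE,
                                      treatment_days = 30) {
  stopifnot(inherits(layout, "gradphen_layout"))
  lm_idx <- match(layout$pot_uid, light_map$pot_uid)
  if (anyNA(lm_idx)) stopf("light map does not cover every pot in the layout")
  clamp01 <- function(x) pmin(pmax(x, 0.01), 1)
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(layout))) {
    pot <- layout[i, ]
    light <- light_map[lm_idx[i], ]
    m <- morphotypes[[pot$species]]
    if (is.null(m)) stopf("no morphotype for species '%s'", pot$species)
    pot_seed <- derive_seed(seed, pot$pot_uid)
    sb <- habit_shape_base(m$habit)
    for (day in schedule) {
      g <- growth_fraction(m, day)
      draws <- with_seed(derive_seed(pot_seed, "dimnoise", day), {
        z <- pmin(pmax(stats::rnorm(3), -2.5), 2.5)
        list(nz = if (noise && m$dim_noise_cv > 0) exp(m$dim_noise_cv * z)
                  else c(1, 1, 1),
             shp = if (noise) exp(stats::rnorm(5, 0, 0.05)) else rep(1, 5),
             col = if (noise && m$color_noise_sd > 0)
                     stats::rnorm(3, 0, m$color_noise_sd / 10)
                   else c(0, 0, 0))
      })
      nz <- draws$nz
      h <- m$height_mm * g * trait_multiplier(m, "height", day, light$ratio) * nz[1]
      w <- m$width_mm * g * trait_multiplier(m, "width", day, light$ratio) * nz[2]
      amult <- trait_multiplier(m, "area", day, light$ratio) * nz[3]
      side_area <- 0.30 * h * w * amult
      top_area <- 0.45 * w^2 * amult

      # silhouette factors: habit base modulated by leaf geometry
      leafmod <- (1 - 0.012 * m$n_leaves) * (0.85 + 0.3 * m$leaf_aspect)
      side_sol <- clamp01(sb["side_sol"] * leafmod * draws$shp[1])
      side_circ <- clamp01(sb["side_circ"] * leafmod * draws$shp[2])
      top_sol <- clamp01(sb["top_sol"] * leafmod * draws$shp[3])
      top_circ <- clamp01(sb["top_circ"] * leafmod * draws$shp[4])
      side_round <- clamp01(min(w, h) / max(w, h))
      top_round <- clamp01(sb["top_round"] * draws$shp[5])

      # colours: side views are back-lit (darker); greenness effect on G
      gm <- trait_multiplier(m, "greenness", day, light$ratio)
      top_rgb <- clip255(c(m$color[1], m$color[2] * gm, m$color[3]) + draws$col)
      side_rgb <- clip255(0.75 * top_rgb)
      hsb_top <- grDevices::rgb2hsv(top_rgb[1], top_rgb[2], top_rgb[3],
                                    maxColorValue = 255)[, 1] * 255
      hsb_side <- grDevices::rgb2hsv(side_rgb[1], side_rgb[2], side_rgb[3],
                                     maxColorValue = 255)[, 1] * 255
      idx <- color_indices(top_rgb[1], top_rgb[2], top_rgb[3])

      k <- k + 1L
      rows[[k]] <- tibble::tibble(
        pot_uid = pot$pot_uid, species = pot$species, day = as.integer(day),
        ratio = light$ratio, post_treatment = day > treatment_days,
        n_side_views = 6L, incomplete = FALSE,
        side_HeightMax = h, side_WidthMax = w, side_AreaMean = side_area,
        side_Roundness = side_round, side_Solidity = unname(side_sol),
        side_Convexity = unname(clamp01(0.9 * sqrt(side_sol))),
        side_Circularity = unname(side_circ),
        side_Compactness = unname(clamp01(0.8 * sqrt(side_round))),
        side_HueMean = hsb_side[1], side_HueCv = 4 * draws$shp[1],
        side_SaturationMean = hsb_side[2], side_BrightnessMean = hsb_side[3],
        side_RedMean = side_rgb[1], side_GreenMean = side_rgb[2],
        side_BlueMean = side_rgb[3],
        side_Density = side_area * mean(side_rgb),
        top_Area = top_area,
        top_MeanFeret = 0.9 * w * sqrt(amult / nz[3]),
        top_Roundness = unname(top_round), top_Solidity = unname(top_sol),
        top_Convexity = unname(clamp01(0.9 * sqrt(top_sol))),
        top_Circularity = unname(top_circ),
        top_Compactness = unname(clamp01(0.8 * sqrt(top_round))),
        top_HueMean = hsb_top[1], top_HueCv = 4 * draws$shp[2],
        top_SaturationMean = hsb_top[2], top_BrightnessMean = hsb_top[3],
        top_RedMean = top_rgb[1], top_GreenMean = top_rgb[2],
        top_BlueMean = top_rgb[3],
        top_Density = top_area * mean(top_rgb),
        top_GLI = idx$GLI, top_TGI = idx$TGI,
        top_Chl_predicted = idx$Chl_predicted,
        Voxel = sqrt(side_area^2 * top_area)
      )
    }
  }
  dplyr::bind_rows(rows)
}
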