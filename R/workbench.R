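# Workbench: run configuration, the generate -> process -> analyze
# pipeline over directories of images and CSV tables, logging, and report
# figures.

#' Assemble a run configuration
#'
#' Collects every tunable of a full run into one serializable object; a run
#' directory always receives a copy of the exact configuration used
#' (`config.yaml`).
#'
#' @param seed Master seed of the run.
#' @param layout A [layout_config()].
#' @param gradient A [gradient_config()].
#' @param scene A [scene_config()].
#' @param schedule Imaging days.
#' @param treatment_days Length of the gradient treatment.
#' @param segmentation List of [segment()] arguments
#'   (`min_area_px`, `threshold`).
#' @param analysis List of analysis options: `log_base`, `baseline`,
#'   `thresholds`, `pca_days` (day window for the PCA panel).
#' @return A list of class `gradphen_run_config`.
#' @export
run_config <- function(seed = 1L,
                       layout = layout_config(),
                       gradient = gradient_config(),
                       scene = scene_config(),
                       schedule = imaging_schedule(),
                       treatment_days = 30,
                       segmentation = list(min_area_px = 25L, threshold = NULL),
                       analysis = list(log_base = exp(1), baseline = "min",
                                       thresholds = c(0.05, 0.01),
                                       pca_days = c(21, 29))) {
  structure(
    list(seed = as.integer(seed), layout = layout, gradient = gradient,
         scene = scene, schedule = schedule,
         treatment_days = treatment_days,
         segmentation = segmentation, analysis = analysis),
    class = "gradphen_run_config"
  )
}

write_config <- function(config, path) {
  plain <- rapply(unclass(config), unclass, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

log_line <- function(log_path, fmt, ...) {
  if (is.null(log_path)) return(invisible())
  cat(sprintf(paste0(fmt, "\n"), ...), file = log_path, append = TRUE)
  invisible()
}

#' Generate a synthetic experiment run directory
#'
#' Builds the layout and light map from the configuration, renders and
#' writes all scenes, and records the light map, configuration and log in
#' the run directory.
#'
#' @param config A [run_config()].
#' @param dir Output run directory.
#' @param morphotypes Named morphotype list (defaults to the built-in
#'   seven-species panel).
#' @param noise Disable generator noise with `FALSE`.
#' @param overwrite Allow reuse of a non-empty directory.
#' @return Invisibly, list with `dir`, `layout`, `light_map`, `metadata`,
#'   `truth`.
#' @export
run_generate <- function(config = run_config(), dir,
                         morphotypes = default_morphotypes(),
                         noise = TRUE, overwrite = FALSE) {
  stopifnot(inherits(config, "gradphen_run_config"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stopf("run directory '%s' is not empty (use overwrite = TRUE)", dir)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (config$gradient$min_ratio == config$gradient$max_ratio) {
    warnf("degenerate gradient (min_ratio == max_ratio): downstream effect sizes will be non-significant")
  }
  layout <- build_layout(config$layout, seed = config$seed)
  light_map <- build_light_map(layout, config$gradient,
                               seed = derive_seed(config$seed, "light"))
  res <- generate_experiment(layout, light_map, morphotypes,
                             schedule = config$schedule,
                             seed = derive_seed(config$seed, "scenes"),
                             dir = dir, config = config$scene, noise = noise,
                             treatment_days = config$treatment_days,
                             overwrite = TRUE)
  utils::write.csv(light_map, file.path(dir, "light_map.csv"),
                   row.names = FALSE)
  utils::write.csv(layout, file.path(dir, "layout.csv"), row.names = FALSE)
  write_config(config, file.path(dir, "config.yaml"))
  invisible(list(dir = dir, layout = layout, light_map = light_map,
                 metadata = res$metadata, truth = res$truth))
}

#' Process a run directory of images into a descriptor table
#'
#' Segments and measures every image listed in the metadata, aggregates
#' the 6 side + 1 top views per pot and day, and writes `descriptors.csv`
#' and a per-image log. Failures are isolated per image: the affected
#' pot/day aggregate is flagged incomplete and processing continues.
#'
#' @param dir Run directory produced by [run_generate()] (or any directory
#'   with `metadata.csv` plus an `images/` folder following the
#'   `<potUID>_<day>_<view>_<frame>.png` convention).
#' @param config A [run_config()] (segmentation options).
#' @param max_failures Fraction of failed images above which the run
#'   errors out.
#' @return The descriptor tibble (one row per pot x day), invisibly also
#'   written to `<dir>/descriptors.csv`.
#' @export
run_process <- function(dir, config = run_config(), max_failures = 0.1) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) stopf("no metadata.csv in '%s'", dir)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  img_dir <- file.path(dir, "images")
  log_path <- file.path(dir, "process.log")
  cat("", file = log_path)

  n_fail <- 0L; n_total <- 0L
  rows <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    md <- meta[i, ]
    files <- c(sprintf("%s_%d_side_%d.png", md$pot_uid, md$day, 0:5),
               sprintf("%s_%d_top_0.png", md$pot_uid, md$day))
    views <- list()
    for (j in seq_along(files)) {
      n_total <- n_total + 1L
      path <- file.path(img_dir, files[j])
      got <- tryCatch({
        rec <- read_image(path, mm_per_px = md$mm_per_px)
        msk <- segment(rec, threshold = config$segmentation$threshold,
                       min_area_px = config$segmentation$min_area_px %||% 25L)
        mv <- measure_view(rec, msk)
        log_line(log_path, "%s view=%s frame=%d fg=%d", md$pot_uid,
                 rec$view, rec$frame, sum(msk$mask))
        mv
      }, error = function(e) {
        log_line(log_path, "%s FAILED %s: %s", md$pot_uid, files[j],
                 conditionMessage(e))
        NULL
      })
      if (is.null(got)) n_fail <- n_fail + 1L else views[[length(views) + 1L]] <- got
    }
    vtab <- dplyr::bind_rows(views)
    if (nrow(vtab) == 0) next
    agg <- aggregate_views(vtab)
    agg$species <- md$species
    agg$ratio <- md$ratio
    agg$post_treatment <- md$post_treatment
    rows[[i]] <- agg
  }
  if (n_total > 0 && n_fail / n_total > max_failures) {
    stopf("%d/%d images failed processing (limit %.0f%%); see %s",
          n_fail, n_total, 100 * max_failures, log_path)
  }
  desc <- dplyr::bind_rows(rows)
  utils::write.csv(desc, file.path(dir, "descriptors.csv"),
                   row.names = FALSE)
  invisible(desc)
}

default_analysis_descriptors <- function() {
  c("side_HeightMax", "side_WidthMax", "side_AreaMean", "top_Area",
    "top_MeanFeret", "Voxel",
    "side_Circularity", "side_Solidity", "top_Circularity", "top_Solidity",
    "side_GreenMean", "top_GreenMean", "top_GLI", "top_TGI",
    "top_Chl_predicted")
}

#' Analyze a processed run: gradient effects, PCA, report figures
#'
#' Joins the descriptor table with the light map, runs the effect-size
#' time course for the chosen descriptors, the PCA species discrimination
#' panel (full set and per-class selections), writes `effects.csv`,
#' `pca_scores.csv`, `pca_loadings.csv`, and renders an effect-size
#' heatmap and time-course figure to `report.pdf`.
#'
#' @param dir Run directory with `descriptors.csv` (from [run_process()]).
#' @param config A [run_config()].
#' @param descriptors Descriptor columns to analyse.
#' @return Invisibly, list with `effects`, `pca` (list per selection),
#'   `dir`.
#' @export
run_analyze <- function(dir, config = run_config(),
                        descriptors = default_analysis_descriptors()) {
  desc_path <- file.path(dir, "descriptors.csv")
  if (!file.exists(desc_path)) stopf("no descriptors.csv in '%s' (run run_process first)", dir)
  desc <- utils::read.csv(desc_path, stringsAsFactors = FALSE)
  if (!all(c("species", "ratio") %in% names(desc))) {
    lm_path <- file.path(dir, "light_map.csv")
    meta_path <- file.path(dir, "metadata.csv")
    if (!file.exists(meta_path)) stopf("descriptors.csv lacks species/ratio and no metadata.csv present")
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    key <- unique(meta[, c("pot_uid", "species", "ratio")])
    miss <- setdiff(desc$pot_uid, key$pot_uid)
    if (length(miss)) stopf("pots missing from metadata: %s",
                            paste(utils::head(miss, 5), collapse = ", "))
    desc <- dplyr::left_join(desc, key, by = "pot_uid")
  }
  descriptors <- intersect(descriptors, names(desc))
  effects <- effect_time_course(
    desc, descriptors,
    treatment_days = config$treatment_days,
    baseline = config$analysis$baseline %||% "min",
    log_base = config$analysis$log_base %||% exp(1),
    thresholds = config$analysis$thresholds %||% c(0.05, 0.01)
  )
  utils::write.csv(effects, file.path(dir, "effects.csv"), row.names = FALSE)

  pca_days <- config$analysis$pca_days %||% c(21, 29)
  selections <- list(
    full = feature_selection(days = pca_days),
    dimensions = feature_selection("dimensions", days = pca_days),
    shape = feature_selection("shape", days = pca_days),
    color = feature_selection("color", days = pca_days)
  )
  pca <- lapply(selections, function(sel) {
    tryCatch(pca_discriminate(desc, sel), error = function(e) NULL)
  })
  if (!is.null(pca$full)) {
    sc <- pca$full$scores
    utils::write.csv(sc, file.path(dir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(pca$full$loadings),
                     file.path(dir, "pca_loadings.csv"), row.names = TRUE)
  }
  report_path <- file.path(dir, "report.pdf")
  tryCatch({
    grDevices::pdf(report_path, width = 9, height = 7)
    print(plot_effect_heatmap(effects, treatment_days = config$treatment_days))
    print(plot_effect_time_course(effects))
    if (!is.null(pca$full)) print(plot_pca_scores(pca$full))
    grDevices::dev.off()
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    warnf("report rendering failed: %s", conditionMessage(e))
  })
  invisible(list(effects = effects, pca = pca, dir = dir))
}

#' Effect-size heatmap (descriptor x species at one timepoint)
#'
#' @param effects An [effect_time_course()] table.
#' @param day Day to display; defaults to the last non-post-treatment day.
#' @param treatment_days Used to pick the default day.
#' @return A ggplot object.
#' @export
plot_effect_heatmap <- function(effects, day = NULL, treatment_days = 30) {
  stopifnot(nrow(effects) > 0)
  if (is.null(day)) {
    pre <- effects$day[effects$day <= treatment_days]
    day <- if (length(pre)) max(pre) else max(effects$day)
  }
  sub <- effects[effects$day == day & is.finite(effects$effect_percent), ]
  sub$label <- ifelse(sub$significance == "NS", "NS",
                      sprintf("%.0f%%", sub$effect_percent))
  ggplot2::ggplot(sub, ggplot2::aes(x = .data$species, y = .data$descriptor,
                                    fill = .data$effect_percent)) +
    ggplot2::geom_tile(color = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 2.6) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "Effect (%)") +
    ggplot2::labs(title = sprintf("Red:blue gradient effect size, day %d", day),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Effect-size time-course figure
#'
#' @param effects An [effect_time_course()] table.
#' @return A ggplot object (descriptor facets, one line per species; point
#'   shape encodes the significance category).
#' @export
plot_effect_time_course <- function(effects) {
  stopifnot(nrow(effects) > 0)
  effects <- effects[is.finite(effects$effect_percent), ]
  effects$significance <- factor(as.character(effects$significance),
                                 levels = levels(effects$significance))
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = .data$day, y = .data$effect_percent,
                               color = .data$species)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significance), size = 2) +
    ggplot2::facet_wrap(~descriptor, scales = "free_y") +
    ggplot2::labs(x = "Day under gradient", y = "Effect size (%)") +
    ggplot2::theme_bw()
}

#' PCA score scatter plot
#'
#' @param pca A [pca_discriminate()] result.
#' @return A ggplot object.
#' @export
plot_pca_scores <- function(pca) {
  stopifnot(inherits(pca, "gradphen_pca"))
  ev <- 100 * pca$explained_variance
  ggplot2::ggplot(pca$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               color = .data$species)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", ev[1]),
      y = sprintf("PC2 (%.1f%%)", ev[2]),
      title = sprintf("Species discrimination (mean silhouette %.2f)",
                      pca$silhouette)
    ) +
    ggplot2::theme_bw()
}
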