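# Layout, light map, schedule and scene generation.

test_that("layout allocates the documented pot counts per species", {
  for (seed in c(1L, 17L, 99L)) {
    lay <- build_layout(layout_config(), seed = seed)
    counts <- table(lay$species)
    expect_equal(unname(counts[["rosetta"]]), 48L)
    for (sp in setdiff(names(counts), "rosetta")) {
      expect_equal(unname(counts[[sp]]), 36L)
    }
    expect_false(anyDuplicated(lay$pot_uid) > 0)
  }
})

test_that("species blocks are contiguous rows and fit the room grid", {
  lay <- build_layout(layout_config(), seed = 5)
  cfg <- attr(lay, "config")
  expect_true(all(lay$row >= 1 & lay$row <= cfg$rows_per_room))
  expect_true(all(lay$column >= 1 & lay$column <= cfg$columns))
  for (sp in unique(lay$species)) {
    sub <- lay[lay$species == sp, ]
    expect_equal(length(unique(sub$room)), 1L)
    rows <- sort(unique(sub$row))
    expect_equal(rows, seq(min(rows), max(rows)))
    # every row of the block fully populated across columns
    expect_true(all(table(sub$row) == cfg$columns))
  }
})

test_that("layout is deterministic in seed and errors on overflow", {
  expect_identical(build_layout(layout_config(), seed = 7),
                   build_layout(layout_config(), seed = 7))
  expect_false(identical(build_layout(layout_config(), seed = 7)$pot_uid,
                         build_layout(layout_config(), seed = 8)$pot_uid))
  expect_error(
    build_layout(layout_config(species = "x",
                               rows_per_species = c(x = 11L),
                               rosette_reference = NULL)),
    "capacity"
  )
})

test_that("light map interpolates log-linearly and respects its band", {
  lay <- build_layout(layout_config(), seed = 1)
  # zero noise: ratios exactly the interpolated set-points, monotone in column
  lmap0 <- build_light_map(lay, gradient_config(noise_sd = 0), seed = 1)
  bycol <- tapply(lmap0$ratio, lmap0$column, unique)
  expect_true(all(lengths(bycol) == 1))
  lnr <- log(unlist(bycol))[order(as.integer(names(bycol)))]
  expect_true(all(diff(lnr) > 0))
  expect_equal(min(lmap0$ratio), 0.1, tolerance = 1e-12)
  expect_equal(max(lmap0$ratio), 10, tolerance = 1e-12)
  # ppfd inside the configured band
  lmap <- build_light_map(lay, gradient_config(), seed = 2)
  expect_true(all(lmap$ppfd >= 100 & lmap$ppfd <= 150))
  expect_true(all(abs(lmap$red_pfd / lmap$blue_pfd - lmap$ratio) < 1e-9))
  # determinism
  expect_identical(lmap, build_light_map(lay, gradient_config(), seed = 2))
})

test_that("degenerate gradient collapses to a single ratio", {
  lay <- build_layout(layout_config(), seed = 1)
  lmap <- build_light_map(lay, gradient_config(min_ratio = 2, max_ratio = 2,
                                               noise_sd = 0), seed = 1)
  expect_true(all(lmap$ratio == 2))
  expect_error(gradient_config(min_ratio = 0), "positive")
  expect_error(gradient_config(min_ratio = 5, max_ratio = 1), ">=")
})

test_that("twice-weekly schedule yields 8-9 sessions over 30 days", {
  sch <- imaging_schedule(30, 2)
  expect_gte(length(sch), 8)
  expect_lte(length(sch), 9)
  expect_equal(sch[1], 0L)
  expect_false(is.unsorted(sch))
})

test_that("scene ground truth at day 0 is independent of the light ratio", {
  m <- default_morphotypes()$lycop
  sc1 <- render_scene(m, list(ratio = 0.1), day = 0, seed = 3, noise = FALSE)
  sc2 <- render_scene(m, list(ratio = 10), day = 0, seed = 3, noise = FALSE)
  expect_equal(sc1$truth$true_HeightMax, sc2$truth$true_HeightMax)
  expect_equal(sc1$truth$true_AreaMean, sc2$truth$true_AreaMean)
  expect_identical(sc1$masks$side_0, sc2$masks$side_0)
})

test_that("zero-effect morphotype shows no gradient in rendered truth", {
  m <- morphotype("null", habit = "caulescent", effects = list())
  lay <- single_species_layout(seed = 2, species = "null")
  lmap <- build_light_map(lay, gradient_config(noise_sd = 0), seed = 2)
  tt <- simulate_descriptor_truth(lay, lmap, morphotypes = list(null = m),
                                  schedule = c(14L, 21L), seed = 11)
  sub <- tt[tt$day == 21, ]
  fit <- fit_descriptor_gradient(sub$side_HeightMax, sub$ratio)
  se <- sqrt(fit$sigma2 / fit$sxx)
  expect_true(abs(fit$slope) < stats::qt(0.995, fit$n - 2) * se)
})

test_that("seed changes move ground truth only within the noise scale", {
  m <- default_morphotypes()$lycop
  h <- vapply(1:20, function(s) {
    render_scene(m, list(ratio = 1), day = 14, seed = s)$truth$true_HeightMax
  }, numeric(1))
  expect_lt(stats::sd(h) / mean(h), 3 * m$dim_noise_cv)
  expect_gt(stats::sd(h), 0)
})

test_that("plants larger than the frame raise a resize error", {
  m <- morphotype("huge", height_mm = 600, width_mm = 300)
  expect_error(render_scene(m, list(ratio = 1), day = 30, seed = 1,
                            noise = FALSE),
               "exceeds frame")
})

test_that("generate_experiment writes the full image/metadata set deterministically", {
  lay <- build_layout(layout_config(species = c("a", "b"),
                                    rows_per_species = c(a = 1L, b = 1L),
                                    rosette_reference = NULL,
                                    columns = 4L, rows_per_room = 4L),
                      seed = 1)
  lmap <- build_light_map(lay, gradient_config(), seed = 1)
  morphs <- list(
    a = morphotype("a", height_mm = 80, width_mm = 60, dim_noise_cv = 0.05),
    b = morphotype("b", habit = "grass", height_mm = 90, width_mm = 70,
                   dim_noise_cv = 0.05)
  )
  sch <- c(0L, 14L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res <- generate_experiment(lay, lmap, morphs, schedule = sch, seed = 4,
                             dir = d1, overwrite = TRUE)
  expect_equal(length(list.files(file.path(d1, "images"))),
               nrow(lay) * length(sch) * 7)
  expect_equal(nrow(res$metadata), nrow(lay) * length(sch))
  expect_true(file.exists(file.path(d1, "truth.csv")))
  generate_experiment(lay, lmap, morphs, schedule = sch, seed = 4,
                      dir = d2, overwrite = TRUE)
  expect_identical(readLines(file.path(d1, "metadata.csv")),
                   readLines(file.path(d2, "metadata.csv")))
  expect_identical(readLines(file.path(d1, "truth.csv")),
                   readLines(file.path(d2, "truth.csv")))
})
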