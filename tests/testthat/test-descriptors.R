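# Shape factors, colour statistics, colour indices and view aggregation.

test_that("ideal circle and square shape factors match closed forms", {
  r <- 10
  circle <- shape_factors(area = pi * r^2, perimeter = 2 * pi * r,
                          hull_area = pi * r^2, hull_perimeter = 2 * pi * r,
                          major_axis = 2 * r, minor_axis = 2 * r)
  expect_equal(as.numeric(circle), rep(1, 5), tolerance = 1e-12)
  s <- 4
  square <- shape_factors(area = s^2, perimeter = 4 * s, hull_area = s^2,
                          hull_perimeter = 4 * s,
                          major_axis = s * sqrt(2), minor_axis = s)
  expect_equal(square$Circularity, pi / 4, tolerance = 1e-12)
  expect_equal(square$Solidity, 1)
  expect_equal(square$Convexity, 1)
})

test_that("zero denominators give NA markers, not zeros", {
  sf <- shape_factors(10, 0, 0, 5, 0, 0)
  expect_true(is.na(sf$Circularity))
  expect_true(is.na(sf$Solidity))
  expect_true(is.na(sf$Roundness))
  expect_true(is.na(sf$Compactness))
})

test_that("colour statistics over a uniform foreground are exact", {
  px <- array(0, dim = c(20, 20, 3))
  px[, , 2] <- 255
  mfg <- matrix(FALSE, 20, 20); mfg[5:15, 5:15] <- TRUE
  img <- image_record(px, "P1", "top", 0L, 0L, 1)
  msk <- plant_mask(mfg, 1, "top", "P1", 0L)
  cs <- color_statistics(img, msk)
  expect_equal(cs$RedMean, 0)
  expect_equal(cs$GreenMean, 255)
  expect_equal(cs$BlueMean, 0)
  expect_equal(cs$HueCv, 0)       # uniform colour: zero hue dispersion
  expect_equal(cs$BrightnessMean, 255)
  expect_equal(cs$Density, sum(mfg) * 255 / 3)
  empty <- color_statistics(img, plant_mask(matrix(FALSE, 20, 20), 1))
  expect_true(is.na(empty$RedMean))
})

test_that("scene colour means recover the generator ground truth", {
  m <- default_morphotypes()$lycop
  sc <- render_scene(m, list(ratio = 1), day = 20, seed = 4)
  img <- sc$images$top_0
  msk <- plant_mask(sc$masks$top_0, 1, "top")
  cs <- color_statistics(img, msk)
  n <- sum(sc$masks$top_0)
  tol <- 3 * m$color_noise_sd / sqrt(n) + 0.5  # noise SE plus clipping bias
  expect_lt(abs(cs$RedMean - sc$truth$true_top_RedMean), tol)
  expect_lt(abs(cs$GreenMean - sc$truth$true_top_GreenMean), tol)
  expect_lt(abs(cs$BlueMean - sc$truth$true_top_BlueMean), tol)
})

test_that("colour indices evaluate their published formulas", {
  expect_equal(color_indices(0, 0, 0)$Chl_predicted, 440)
  expect_equal(color_indices(100, 120, 80)$Chl_predicted, 243.18,
               tolerance = 1e-12)
  expect_equal(color_indices(100, 50, 0)$TGI, 12.5, tolerance = 1e-12)
  grey <- color_indices(128, 128, 128)
  expect_equal(grey$GLI, 0)
  expect_equal(grey$TGI, 0)
  expect_true(is.na(color_indices(0, 0, 0)$GLI))
  expect_error(color_indices(300, 0, 0))
})

test_that("view aggregation computes the documented summaries", {
  views <- dplyr::bind_rows(
    lapply(0:5, function(f) make_view_row("side", f, area = 100)),
    make_view_row("top", 0, area = 25)
  )
  agg <- aggregate_views(views)
  expect_equal(agg$Voxel, sqrt(100 * 100 * 25))  # = 500
  expect_equal(agg$side_AreaMean, 100)
  expect_false(agg$incomplete)

  areas <- c(64, 70, 80, 90, 95, 100)
  views2 <- dplyr::bind_rows(
    lapply(0:5, function(f) make_view_row("side", f, area = areas[f + 1])),
    make_view_row("top", 0, area = 25)
  )
  agg2 <- aggregate_views(views2)
  expect_equal(agg2$Voxel, sqrt(100 * 64 * 25))  # = 400
  expect_equal(agg2$side_AreaMean, mean(areas))

  hw <- dplyr::bind_rows(
    lapply(0:5, function(f) make_view_row("side", f, area = 50,
                                          height = 10 + f, width = 20 - f)),
    make_view_row("top", 0, area = 25)
  )
  agg3 <- aggregate_views(hw)
  expect_equal(agg3$side_HeightMax, 15)
  expect_equal(agg3$side_WidthMax, 20)
})

test_that("a missing top view leaves top descriptors and Voxel undefined", {
  views <- dplyr::bind_rows(lapply(0:4, function(f)
    make_view_row("side", f, area = 100)))
  agg <- aggregate_views(views)
  expect_true(agg$incomplete)
  expect_true(is.na(agg$Voxel))
  expect_true(is.na(agg$top_Area))
  expect_true(is.na(agg$top_GLI))
  expect_equal(agg$n_side_views, 5L)
})

test_that("aggregated records follow the frozen descriptor schema", {
  views <- dplyr::bind_rows(
    lapply(0:5, function(f) make_view_row("side", f, area = 100)),
    make_view_row("top", 0, area = 25)
  )
  agg <- aggregate_views(views)
  expect_identical(names(agg), descriptor_schema())
})

test_that("measured descriptors on a rendered scene match generator truth", {
  m <- default_morphotypes()$brachy
  sc <- render_scene(m, list(ratio = 3), day = 21, seed = 8, noise = FALSE)
  views <- dplyr::bind_rows(lapply(names(sc$images), function(v) {
    img <- sc$images[[v]]
    measure_view(img, plant_mask(sc$masks[[v]], img$mm_per_px, img$view,
                                 img$pot_uid, img$day))
  }))
  agg <- aggregate_views(views)
  cal <- sc$images$side_0$mm_per_px
  expect_lte(abs(agg$side_HeightMax - sc$truth$true_HeightMax), cal + 1e-9)
  expect_lte(abs(agg$side_WidthMax - sc$truth$true_WidthMax), cal + 1e-9)
  expect_equal(agg$side_AreaMean, sc$truth$true_AreaMean, tolerance = 1e-9)
  expect_equal(agg$top_Area, sc$truth$true_Area, tolerance = 1e-9)
  expect_equal(agg$Voxel, sc$truth$true_Voxel, tolerance = 1e-9)
})
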