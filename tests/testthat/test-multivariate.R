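# PCA species discrimination and the silhouette diagnostic.

sim_panel <- function(morphs, seed = 1, days = c(21L, 24L, 28L)) {
  lay <- build_layout(
    layout_config(species = names(morphs),
                  rows_per_species = stats::setNames(rep(1L, length(morphs)),
                                                     names(morphs)),
                  rosette_reference = NULL, columns = 12L,
                  rows_per_room = length(morphs)),
    seed = seed
  )
  lmap <- build_light_map(lay, gradient_config(), seed = seed)
  simulate_descriptor_truth(lay, lmap, morphs, schedule = days, seed = seed)
}

test_that("morphotypes differing only in height separate on dimensions, not colour", {
  morphs <- list(
    short = morphotype("short", height_mm = 40, width_mm = 90,
                       dim_noise_cv = 0.05),
    tall = morphotype("tall", height_mm = 200, width_mm = 90,
                      dim_noise_cv = 0.05)
  )
  # a single timepoint isolates the programmed height contrast from growth;
  # with width held equal, half the dimension features are inert, so the
  # second component is noise and bounds the two-component silhouette
  # near 0.5
  tab <- sim_panel(morphs, seed = 6, days = 24L)
  p_dim <- pca_discriminate(tab, feature_selection("dimensions"))
  p_col <- pca_discriminate(tab, feature_selection("color"))
  expect_gt(p_dim$silhouette, 0.45)
  expect_lt(abs(p_col$silhouette), 0.2)
  expect_gt(p_dim$silhouette - p_col$silhouette, 0.4)
})

test_that("identical morphotypes yield near-zero silhouette", {
  sils <- vapply(1:20, function(s) {
    morphs <- list(a = morphotype("a"), b = morphotype("b"))
    tab <- sim_panel(morphs, seed = s, days = c(21L, 24L))
    pca_discriminate(tab, feature_selection())$silhouette
  }, numeric(1))
  expect_true(all(abs(sils) < 0.15))
})

test_that("the full descriptor set discriminates best across seven morphotypes", {
  lay <- build_layout(layout_config(), seed = 2)
  lmap <- build_light_map(lay, gradient_config(), seed = 2)
  tab <- simulate_descriptor_truth(lay, lmap, schedule = c(21L, 24L, 28L),
                                   seed = 2)
  s_full <- pca_discriminate(tab, feature_selection())$silhouette
  for (cl in c("dimensions", "shape", "color")) {
    expect_gt(s_full, pca_discriminate(tab, feature_selection(cl))$silhouette)
  }
  expect_equal(nrow(pca_discriminate(tab, feature_selection())$silhouette_pairs),
               choose(7, 2))
})

test_that("explained variance ratios are non-increasing and sum below 1", {
  tab <- sim_panel(list(a = morphotype("a"),
                        b = morphotype("b", habit = "grass")), seed = 3)
  p <- pca_discriminate(tab, feature_selection(), n_components = 4L)
  ev <- p$explained_variance_all
  expect_true(all(diff(ev) <= 1e-12))
  expect_lte(sum(ev), 1 + 1e-9)
  expect_gte(min(ev), 0)
})

test_that("the decomposition matches an independent eigendecomposition", {
  tab <- sim_panel(list(a = morphotype("a"),
                        b = morphotype("b", height_mm = 60)), seed = 5)
  sel <- feature_selection("dimensions")
  p <- pca_discriminate(tab, sel, n_components = 3L)
  X <- as.matrix(tab[, intersect(sel$columns, names(tab))])
  ee <- eigen(stats::cor(X))
  ev_oracle <- ee$values / sum(ee$values)
  expect_equal(p$explained_variance_all[1:3], ev_oracle[1:3],
               tolerance = 1e-8)
  # loadings agree up to sign; the convention fixes the largest one positive
  for (k in 1:2) {
    expect_equal(abs(p$loadings[, k]), abs(ee$vectors[, k]),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }
})

test_that("standardization makes discrimination invariant to units", {
  tab <- sim_panel(list(a = morphotype("a"),
                        b = morphotype("b", height_mm = 200)), seed = 8)
  tab2 <- tab
  tab2$side_HeightMax <- tab2$side_HeightMax * 1000  # mm -> micron
  s1 <- pca_discriminate(tab, feature_selection("dimensions"))$silhouette
  s2 <- pca_discriminate(tab2, feature_selection("dimensions"))$silhouette
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("constant features are dropped with a warning, missing rows deleted", {
  tab <- sim_panel(list(a = morphotype("a"), b = morphotype("b")), seed = 9)
  tab$side_HeightMax <- 5
  expect_warning(p <- pca_discriminate(tab, feature_selection("dimensions")),
                 "constant")
  expect_true("side_HeightMax" %in% p$dropped_features)
  tab2 <- sim_panel(list(a = morphotype("a"), b = morphotype("b")), seed = 10)
  tab2$top_Area[1:5] <- NA
  expect_message(p2 <- pca_discriminate(tab2, feature_selection("dimensions")),
                 "dropped 5 row")
  expect_equal(p2$n_rows, nrow(tab2) - 5)
})

test_that("side-view selections can exclude the rosette reference species", {
  tab <- sim_panel(list(ros = morphotype("ros", habit = "rosette",
                                         height_mm = 30),
                        a = morphotype("a"), b = morphotype("b")), seed = 11)
  p <- pca_discriminate(tab, feature_selection(views = c("side", "top")),
                        exclude_side_for = "ros")
  expect_false("ros" %in% p$scores$species)
  p_top <- pca_discriminate(tab, feature_selection(views = "top"),
                            exclude_side_for = "ros")
  expect_true("ros" %in% p_top$scores$species)
})
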