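# PCA species discrimination over selectable descriptor subsets and
# camera views, with a silhouette-based separation diagnostic.

descriptor_classes <- function() {
  dims_side <- c("side_HeightMax", "side_WidthMax", "side_AreaMean")
  dims_top <- c("top_Area", "top_MeanFeret")
  shape <- c("Roundness", "Solidity", "Convexity", "Circularity",
             "Compactness")
  color <- c("HueMean", "HueCv", "SaturationMean", "BrightnessMean",
             "RedMean", "GreenMean", "BlueMean", "Density")
  list(
    dimensions = list(side = dims_side, top = dims_top, both = "Voxel"),
    shape = list(side = paste0("side_", shape), top = paste0("top_", shape),
                 both = character(0)),
    color = list(side = paste0("side_", color),
                 top = c(paste0("top_", color), "top_GLI", "top_TGI",
                         "top_Chl_predicted"),
                 both = character(0))
  )
}

#' Select descriptor columns by class and view
#'
#' @param classes Subset of `c("dimensions", "shape", "color")`.
#' @param views Subset of `c("side", "top")`.
#' @param days Optional day window `c(min, max)` applied by
#'   [pca_discriminate()].
#' @return A list of class `gradphen_selection` with the resolved column
#'   names.
#' @export
feature_selection <- function(classes = c("dimensions", "shape", "color"),
                              views = c("side", "top"), days = NULL) {
  classes <- match.arg(classes, several.ok = TRUE)
  views <- match.arg(views, several.ok = TRUE)
  cls <- descriptor_classes()
  cols <- unlist(lapply(classes, function(cl) {
    c(unlist(lapply(views, function(v) cls[[cl]][[v]])),
      if (length(views) == 2) cls[[cl]]$both else character(0))
  }), use.names = FALSE)
  if (length(cols) == 0) stopf("empty feature selection")
  structure(list(classes = classes, views = views, days = days,
                 columns = cols),
            class = "gradphen_selection")
}

#' PCA species discrimination over a descriptor subset
#'
#' Standardizes (z-scores) the selected descriptor columns, drops constant
#' features (with a warning) and rows with missing values, and decomposes
#' the correlation structure by PCA. Components are oriented so that each
#' one's largest-magnitude loading is positive. Separation is summarized by
#' the silhouette score of the species labels on the first two component
#' scores: the overall mean and the mean per species pair.
#'
#' @param data Descriptor table with a `species` column (and `day` if the
#'   selection restricts days).
#' @param selection A [feature_selection()].
#' @param n_components Number of components to retain (truncated to the
#'   number of usable features).
#' @param exclude_side_for Optional species labels whose rows are dropped
#'   whenever the selection includes side views (e.g. a flat rosette that
#'   cannot be measured from the side).
#' @return A list of class `gradphen_pca`: `scores` (tibble with species),
#'   `loadings`, `explained_variance` (ratios), `silhouette` (overall mean
#'   on PC1-2), `silhouette_pairs` (tibble per species pair), `n_rows`,
#'   `dropped_features`.
#' @export
pca_discriminate <- function(data, selection = feature_selection(),
                             n_components = 2L,
                             exclude_side_for = NULL) {
  stopifnot(inherits(selection, "gradphen_selection"),
            "species" %in% names(data))
  cols <- intersect(selection$columns, names(data))
  missing_cols <- setdiff(selection$columns, names(data))
  if (length(missing_cols)) {
    stopf("selected columns absent from data: %s",
          paste(missing_cols, collapse = ", "))
  }
  if (!is.null(selection$days) && "day" %in% names(data)) {
    data <- data[data$day >= selection$days[1] & data$day <= selection$days[2], ]
  }
  if ("side" %in% selection$views && !is.null(exclude_side_for)) {
    data <- data[!(data$species %in% exclude_side_for), ]
  }
  if (length(unique(data$species)) < 2) {
    stopf("need at least 2 species for discrimination")
  }
  X <- as.matrix(data[, cols, drop = FALSE])
  keep_rows <- stats::complete.cases(X)
  if (sum(!keep_rows) > 0) {
    message(sprintf("pca_discriminate: dropped %d row(s) with missing values",
                    sum(!keep_rows)))
  }
  X <- X[keep_rows, , drop = FALSE]
  species <- as.character(data$species[keep_rows])
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0 | !is.finite(sds)]
  if (length(dropped)) {
    warnf("dropping constant feature(s): %s", paste(dropped, collapse = ", "))
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  if (ncol(X) < 2) stopf("fewer than 2 usable features after selection")
  n_components <- min(n_components, ncol(X), nrow(X) - 1)

  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  for (k in seq_len(ncol(rot))) {
    imax <- which.max(abs(rot[, k]))
    if (rot[imax, k] < 0) {
      rot[, k] <- -rot[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores$species <- species
  ev <- pc$sdev^2 / sum(pc$sdev^2)

  sil_dims <- seq_len(min(2L, n_components))
  sil_scores <- as.matrix(pc$x[, sil_dims, drop = FALSE])
  sil_overall <- silhouette_mean(sil_scores, species)
  sp <- sort(unique(species))
  pairs <- utils::combn(sp, 2)
  sil_pairs <- dplyr::bind_rows(lapply(seq_len(ncol(pairs)), function(j) {
    sel <- species %in% pairs[, j]
    tibble::tibble(
      species_a = pairs[1, j], species_b = pairs[2, j],
      silhouette = silhouette_mean(sil_scores[sel, , drop = FALSE],
                                   species[sel])
    )
  }))
  structure(
    list(scores = scores, loadings = rot,
         explained_variance = ev[seq_len(n_components)],
         explained_variance_all = ev,
         silhouette = sil_overall, silhouette_pairs = sil_pairs,
         n_rows = nrow(X), dropped_features = dropped),
    class = "gradphen_pca"
  )
}

# Mean silhouette width of labelled points (euclidean).
silhouette_mean <- function(xy, labels) {
  f <- factor(labels)
  if (nlevels(f) < 2) return(NA_real_)
  sil <- cluster::silhouette(as.integer(f), stats::dist(xy))
  mean(sil[, "sil_width"])
}
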