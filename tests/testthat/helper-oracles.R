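# Fixture builders and independent brute-force oracles used across the
# suite. Oracles deliberately use different algorithms from the package
# (gift-wrapping instead of chull, all-pairs/all-direction search instead
# of rotating calipers, double-loop moment sums, normal equations instead
# of lm).

rasterize_disk <- function(r, pad = 4L) {
  n <- 2L * (r + pad)
  c0 <- r + pad + 0.5
  outer(seq_len(n), seq_len(n),
        function(y, x) (x - c0)^2 + (y - c0)^2 <= r^2)
}

rasterize_rect <- function(h, w, pad = 3L) {
  m <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  m[(pad + 1):(pad + h), (pad + 1):(pad + w)] <- TRUE
  m
}

# Random blob: union of a few random ellipses on a small grid.
random_blob <- function(seed, size = 48L) {
  set.seed(seed)
  m <- matrix(FALSE, size, size)
  for (k in seq_len(sample(2:4, 1))) {
    cx <- runif(1, size * 0.3, size * 0.7)
    cy <- runif(1, size * 0.3, size * 0.7)
    a <- runif(1, 3, size * 0.22)
    b <- runif(1, 3, size * 0.22)
    th <- runif(1, 0, pi)
    xs <- matrix(rep(seq_len(size), each = size), size)
    ys <- matrix(rep(seq_len(size), times = size), size)
    u <- ((xs - cx) * cos(th) + (ys - cy) * sin(th)) / a
    v <- (-(xs - cx) * sin(th) + (ys - cy) * cos(th)) / b
    m <- m | (u^2 + v^2 <= 1)
  }
  m
}

# pixel corner cloud matching the package's hull convention
corner_points <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  x <- idx[, 2]; y <- idx[, 1]
  cbind(c(x - 0.5, x + 0.5, x - 0.5, x + 0.5),
        c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
}

# O(n*h) gift-wrapping convex hull (counter-clockwise vertex list)
oracle_hull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2) return(pts)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2L else 1L
    for (j in seq_len(n)) {
      if (j == cur || j == cand) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
        (pts[cand, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      if (cr < 0 ||
          (abs(cr) < 1e-12 &&
             sum((pts[j, ] - pts[cur, ])^2) > sum((pts[cand, ] - pts[cur, ])^2))) {
        cand <- j
      }
    }
    cur <- cand
    if (cur == hull[1]) break
  }
  pts[hull, , drop = FALSE]
}

oracle_poly_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

oracle_poly_perimeter <- function(v) {
  d <- diff(rbind(v, v[1, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

# all-pairs max distance over hull vertices
oracle_feret_max <- function(hull) {
  dmax <- 0
  n <- nrow(hull)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dmax <- max(dmax, sum((hull[i, ] - hull[j, ])^2))
    }
  }
  sqrt(dmax)
}

# min width over every direction spanned by a pair of hull vertices
oracle_feret_min <- function(hull) {
  n <- nrow(hull)
  wmin <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      e <- hull[j, ] - hull[i, ]
      len <- sqrt(sum(e^2))
      if (len < 1e-12) next
      nrm <- c(-e[2], e[1]) / len
      proj <- hull %*% nrm
      wmin <- min(wmin, max(proj) - min(proj))
    }
  }
  wmin
}

# double-loop central moments and eigen-axes of the pixel set
oracle_ellipse_axes <- function(m) {
  idx <- which(m, arr.ind = TRUE)
  xs <- idx[, 2]; ys <- idx[, 1]
  n <- length(xs)
  mx <- sum(xs) / n; my <- sum(ys) / n
  s20 <- 0; s02 <- 0; s11 <- 0
  for (i in seq_len(n)) {
    s20 <- s20 + (xs[i] - mx)^2
    s02 <- s02 + (ys[i] - my)^2
    s11 <- s11 + (xs[i] - mx) * (ys[i] - my)
  }
  ev <- eigen(matrix(c(s20, s11, s11, s02) / n, 2))$values
  list(major = 4 * sqrt(max(ev)), minor = 4 * sqrt(max(0, min(ev))))
}

# closed-form simple OLS with t-test p-value
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  s2 <- sum(res^2) / (n - 2)
  se_b <- sqrt(s2 / sxx)
  tstat <- b / se_b
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sxx * sum((y - mean(y))^2))
  list(slope = b, intercept = a, r = r, r2 = r^2,
       p = 2 * stats::pt(-abs(tstat), n - 2))
}

# minimal per-view measurement rows for aggregate_views arithmetic tests
make_view_row <- function(view, frame, area, height = 10, width = 10,
                          mean_feret = 5) {
  row <- tibble::tibble(
    pot_uid = "P1", day = 0L, view = view, frame = as.integer(frame),
    Height = height, Width = width, Area = area, empty = FALSE,
    Perimeter = 40, HullArea = area * 1.05, HullPerimeter = 38,
    FeretMax = mean_feret * 1.5, FeretMin = mean_feret * 0.5,
    MeanFeret = mean_feret, MajorAxis = 12, MinorAxis = 8
  )
  for (cn in c("Roundness", "Solidity", "Convexity", "Circularity",
               "Compactness")) {
    row[[cn]] <- 0.5
  }
  for (cn in c("HueMean", "SaturationMean", "BrightnessMean", "RedMean",
               "GreenMean", "BlueMean")) {
    row[[cn]] <- 100
  }
  row$HueCv <- 5
  row$Density <- area * 100
  row$hue_wrap <- FALSE
  row
}

# small fixed layout fixtures
single_species_layout <- function(seed = 1L, species = "lycop") {
  build_layout(layout_config(species = species, rosette_reference = NULL),
               seed = seed)
}

two_species_layout <- function(seed = 1L) {
  build_layout(layout_config(species = c("a", "b"),
                             rosette_reference = NULL),
               seed = seed)
}
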