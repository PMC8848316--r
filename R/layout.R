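# Experiment layout: species blocks on the room grid, one pot per position.
#
# Rooms are grids of `rows` x `columns` positions; the columns correspond to
# the cultivation gutters that run along the light gradient, so every column
# of a room sees (nominally) one red:blue ratio. Species are allocated whole
# contiguous rows within a room: a caulescent/grass species occupies 3 rows
# of 12 positions (36 pots) and the rosette reference species 4 rows
# (48 pots). Pots are randomized within the species block.

#' Layout configuration
#'
#' @param species Character vector of species (morphotype) labels.
#' @param rows_per_species Named integer vector giving the number of
#'   contiguous rows allocated to each species; defaults to 3 rows each and
#'   4 rows for the species named by `rosette_reference`.
#' @param rosette_reference Label of the rosette reference species (receives
#'   4 rows by default, like the Arabidopsis block of the original design).
#'   Use `NULL` if no species is singled out.
#' @param columns Number of gradient columns (gutters) per room.
#' @param rows_per_room Number of pot rows a room can hold.
#' @return A list of class `gradphen_layout_config`.
#' @export
layout_config <- function(species = c("rosetta", "brachy", "euphor", "basil",
                                      "oryza", "lycop", "setaria"),
                          rows_per_species = NULL,
                          rosette_reference = "rosetta",
                          columns = 12L,
                          rows_per_room = 10L) {
  stopifnot(length(species) >= 1, !anyDuplicated(species))
  if (is.null(rows_per_species)) {
    rows_per_species <- stats::setNames(rep(3L, length(species)), species)
    if (!is.null(rosette_reference) && rosette_reference %in% species) {
      rows_per_species[rosette_reference] <- 4L
    }
  }
  if (!all(species %in% names(rows_per_species))) {
    stopf("rows_per_species must name every species")
  }
  structure(
    list(species = species,
         rows_per_species = rows_per_species[species],
         rosette_reference = rosette_reference,
         columns = as.integer(columns),
         rows_per_room = as.integer(rows_per_room)),
    class = "gradphen_layout_config"
  )
}

pot_uid <- function(room, row, column) {
  sprintf("R%d-r%02d-c%02d", as.integer(room), as.integer(row),
          as.integer(column))
}

#' Build a randomized experiment layout
#'
#' Packs species blocks (contiguous rows of pots) into rooms in the order
#' given, opening a new room whenever the next block does not fit, then
#' shuffles pot positions within each species block. Deterministic given
#' `seed`.
#'
#' @param config A [layout_config()].
#' @param seed Integer seed controlling the within-block randomization.
#' @return A tibble of class `gradphen_layout` with one row per pot:
#'   `pot_uid`, `species`, `room`, `row` (within room), `column`.
#' @export
build_layout <- function(config = layout_config(), seed = 1L) {
  stopifnot(inherits(config, "gradphen_layout_config"))
  rows_needed <- config$rows_per_species
  if (any(rows_needed > config$rows_per_room)) {
    stopf("species block of %d rows exceeds room capacity of %d rows",
          max(rows_needed), config$rows_per_room)
  }

  # first-fit packing of blocks into rooms, preserving species order
  room <- 1L
  next_row <- 1L
  blocks <- vector("list", length(config$species))
  for (i in seq_along(config$species)) {
    nr <- rows_needed[[i]]
    if (next_row + nr - 1L > config$rows_per_room) {
      room <- room + 1L
      next_row <- 1L
    }
    blocks[[i]] <- list(species = config$species[[i]], room = room,
                        rows = seq(next_row, next_row + nr - 1L))
    next_row <- next_row + nr
  }

  pots <- with_seed(seed, {
    dplyr::bind_rows(lapply(blocks, function(b) {
      grid <- expand.grid(row = b$rows, column = seq_len(config$columns))
      # randomization within the species block: permute pots over positions
      grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
      tibble::tibble(
        species = b$species,
        room = b$room,
        row = as.integer(grid$row),
        column = as.integer(grid$column)
      )
    }))
  })
  pots$pot_uid <- pot_uid(pots$room, pots$row, pots$column)
  if (anyDuplicated(pots$pot_uid)) stopf("internal error: duplicate pot UIDs")
  out <- pots[, c("pot_uid", "species", "room", "row", "column")]
  class(out) <- c("gradphen_layout", class(out))
  attr(out, "config") <- config
  out
}

#' Gradient (light map) configuration
#'
#' The red:blue ratio varies across the gradient columns between the
#' set-points of 5 equally spaced luminary clusters; set-points are placed
#' log-linearly between `min_ratio` and `max_ratio`, and each pot position
#' receives the interpolated set-point plus multiplicative log-normal
#' measurement noise. Total irradiance (PPFD) is drawn uniformly inside
#' `ppfd_band`.
#'
#' @param min_ratio,max_ratio Red:blue ratio end points; both must be
#'   positive with `max_ratio >= min_ratio`.
#' @param n_clusters Number of luminary clusters spanning the columns.
#' @param ppfd_band Length-2 numeric, admissible PPFD range
#'   (µmol m^-2 s^-1).
#' @param noise_sd Standard deviation of the per-pot noise on ln(ratio);
#'   0 gives exactly the interpolated set-points.
#' @return A list of class `gradphen_gradient_config`.
#' @export
gradient_config <- function(min_ratio = 0.1, max_ratio = 10,
                            n_clusters = 5L,
                            ppfd_band = c(100, 150),
                            noise_sd = 0.05) {
  if (min_ratio <= 0 || max_ratio <= 0) stopf("ratios must be positive")
  if (max_ratio < min_ratio) stopf("max_ratio must be >= min_ratio")
  stopifnot(length(ppfd_band) == 2, ppfd_band[1] <= ppfd_band[2],
            noise_sd >= 0, n_clusters >= 2)
  structure(
    list(min_ratio = min_ratio, max_ratio = max_ratio,
         n_clusters = as.integer(n_clusters),
         ppfd_band = as.numeric(ppfd_band), noise_sd = noise_sd),
    class = "gradphen_gradient_config"
  )
}

#' Build the per-pot light map
#'
#' Interpolates ln(red:blue) linearly between the cluster set-points across
#' the column axis of every room and adds per-pot measurement noise, then
#' splits the ratio into red and blue photon flux densities under the drawn
#' PPFD (red + blue = PPFD is the simplification used here).
#'
#' @param layout A [build_layout()] result.
#' @param config A [gradient_config()].
#' @param seed Integer seed for measurement noise.
#' @return A tibble with one row per pot: `pot_uid`, `column`, `ratio`,
#'   `red_pfd`, `blue_pfd`, `ppfd`.
#' @export
build_light_map <- function(layout, config = gradient_config(), seed = 1L) {
  stopifnot(inherits(layout, "gradphen_layout"))
  lcfg <- attr(layout, "config")
  ncol_ <- lcfg$columns
  # cluster positions along the column axis, end clusters at the end columns
  cluster_pos <- seq(1, ncol_, length.out = config$n_clusters)
  setpoints <- seq(log(config$min_ratio), log(config$max_ratio),
                   length.out = config$n_clusters)
  ln_col <- stats::approx(cluster_pos, setpoints, xout = seq_len(ncol_))$y

  n <- nrow(layout)
  lm_tab <- with_seed(seed, {
    noise <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)
    ppfd <- stats::runif(n, config$ppfd_band[1], config$ppfd_band[2])
    tibble::tibble(
      pot_uid = layout$pot_uid,
      column = layout$column,
      ratio = exp(ln_col[layout$column] + noise),
      ppfd = ppfd
    )
  })
  # split total PPFD into the two colour bands according to the ratio
  lm_tab$blue_pfd <- lm_tab$ppfd / (1 + lm_tab$ratio)
  lm_tab$red_pfd <- lm_tab$ppfd - lm_tab$blue_pfd
  stopifnot(all(lm_tab$ratio > 0))
  lm_tab[, c("pot_uid", "column", "ratio", "red_pfd", "blue_pfd", "ppfd")]
}
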