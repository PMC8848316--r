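# Morphotypes: parametric stand-ins for a species' habit and its response to
# the light-quality gradient. A morphotype carries baseline growth
# parameters, a base colour, and per-trait effect functions giving the slope
# of the trait versus ln(red:blue ratio) as a function of time.

#' Define an effect function (slope of trait vs ln ratio over time)
#'
#' The slope follows a rise-peak-decay curve: zero before `onset`, rising to
#' `peak_slope` at `peak_day` and decaying afterwards. With `shape = 0` the
#' slope steps to `peak_slope` at onset and stays constant (the
#' constant-slope special case); larger `shape` gives a sharper, more
#' transient peak.
#'
#' @param peak_slope Slope of the trait multiplier per unit ln(ratio) at the
#'   peak (see [slope_for_effect()] to derive it from a target % effect).
#' @param onset_day Day the response starts (0 = treatment start).
#' @param peak_day Day of maximal response; must exceed `onset_day` when
#'   `shape > 0`.
#' @param shape Non-negative shape parameter of the gamma-like transient.
#' @return A list of class `gradphen_effect`.
#' @export
effect_fun <- function(peak_slope = 0, onset_day = 0, peak_day = 14,
                       shape = 0) {
  stopifnot(shape >= 0, peak_day >= onset_day)
  if (shape > 0 && peak_day <= onset_day) {
    stopf("peak_day must exceed onset_day for a transient effect")
  }
  structure(list(peak_slope = peak_slope, onset_day = onset_day,
                 peak_day = peak_day, shape = shape),
            class = "gradphen_effect")
}

#' Evaluate an effect function at given days
#'
#' @param effect A [effect_fun()].
#' @param day Numeric vector of days since treatment start.
#' @return Slope (per unit ln ratio) at each day; 0 before onset.
#' @export
effect_slope_at <- function(effect, day) {
  stopifnot(inherits(effect, "gradphen_effect"))
  out <- numeric(length(day))
  active <- day >= effect$onset_day
  if (!any(active)) return(out)
  if (effect$shape == 0) {
    out[active] <- effect$peak_slope
  } else {
    u <- (day[active] - effect$onset_day) /
      (effect$peak_day - effect$onset_day)
    out[active] <- effect$peak_slope * (u * exp(1 - u))^effect$shape
  }
  out
}

#' Slope needed for a target percent effect across a gradient
#'
#' The generator applies a trait multiplier `1 + slope * ln(ratio)`. This
#' inverts the regression effect-size definition
#' `100 * (y(max) - y(min)) / y(min)` so that a programmed effect of
#' `effect_percent` across `[min_ratio, max_ratio]` holds exactly for the
#' noiseless trait.
#'
#' @param effect_percent Target signed percent difference across the
#'   gradient.
#' @param min_ratio,max_ratio Gradient end-point ratios.
#' @return The slope per unit ln(ratio).
#' @export
slope_for_effect <- function(effect_percent, min_ratio = 0.1,
                             max_ratio = 10) {
  stopifnot(min_ratio > 0, max_ratio > min_ratio)
  e <- effect_percent / 100
  L <- log(max_ratio) - log(min_ratio)
  b <- e / (L - e * log(min_ratio))
  if (1 + b * log(min_ratio) <= 0) {
    stopf("requested effect gives non-positive trait at min_ratio")
  }
  b
}

#' Define a synthetic morphotype
#'
#' @param name Species label.
#' @param habit One of `"rosette"`, `"caulescent"`, `"grass"`, `"bush"`;
#'   controls the procedural plant geometry.
#' @param height_mm,width_mm Asymptotic shoot height and spread (mm).
#' @param n_leaves Leaf (or tiller/branch) count of the mature plant.
#' @param leaf_angle_deg Typical leaf elevation above horizontal (degrees).
#' @param leaf_aspect Leaf width / leaf length ratio.
#' @param n_plants Plants per pot (bushes are sown in groups).
#' @param color Length-3 base RGB of plant tissue, 0-255.
#' @param growth_tau_days Time constant of the saturating growth curve.
#' @param start_fraction Fraction of asymptotic size already reached at
#'   treatment start (plants are pre-grown before the gradient).
#' @param effects Named list of [effect_fun()] for traits among `"height"`,
#'   `"width"`, `"area"`, `"greenness"`; missing traits respond with 0.
#' @param dim_noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise on dimensions.
#' @param color_noise_sd Per-pixel Gaussian noise SD on colour channels
#'   (0-255 scale).
#' @return A list of class `gradphen_morphotype`.
#' @export
morphotype <- function(name,
                       habit = c("caulescent", "rosette", "grass", "bush"),
                       height_mm = 150, width_mm = 90,
                       n_leaves = 8, leaf_angle_deg = 30,
                       leaf_aspect = 0.4, n_plants = 1,
                       color = c(70, 120, 55),
                       growth_tau_days = 18,
                       start_fraction = 0.35,
                       effects = list(),
                       dim_noise_cv = 0.08,
                       color_noise_sd = 6) {
  habit <- match.arg(habit)
  stopifnot(length(color) == 3, all(color >= 0), all(color <= 255),
            height_mm > 0, width_mm > 0, n_leaves >= 1,
            dim_noise_cv >= 0, color_noise_sd >= 0,
            start_fraction > 0, start_fraction <= 1)
  known <- c("height", "width", "area", "greenness")
  if (!all(names(effects) %in% known)) {
    stopf("effects must be named among: %s", paste(known, collapse = ", "))
  }
  stopifnot(all(vapply(effects, inherits, TRUE, "gradphen_effect")))
  structure(
    list(name = name, habit = habit, height_mm = height_mm,
         width_mm = width_mm, n_leaves = n_leaves,
         leaf_angle_deg = leaf_angle_deg, leaf_aspect = leaf_aspect,
         n_plants = n_plants, color = as.numeric(color),
         growth_tau_days = growth_tau_days,
         start_fraction = start_fraction,
         effects = effects, dim_noise_cv = dim_noise_cv,
         color_noise_sd = color_noise_sd),
    class = "gradphen_morphotype"
  )
}

# Saturating growth multiplier in [start_fraction, 1).
growth_fraction <- function(m, day) {
  f <- 1 - (1 - m$start_fraction) * exp(-day / m$growth_tau_days)
  f
}

# Trait multiplier 1 + slope(day) * ln(ratio) for a named trait.
trait_multiplier <- function(m, trait, day, ratio) {
  eff <- m$effects[[trait]]
  if (is.null(eff)) return(rep(1, length(day)))
  mult <- 1 + effect_slope_at(eff, day) * log(ratio)
  if (any(mult <= 0)) {
    stopf("effect on '%s' drives trait non-positive at ratio %.3g", trait,
          ratio)
  }
  mult
}

#' Default panel of seven synthetic morphotypes
#'
#' A diverse panel mirroring the architectural spread of a multi-species
#' light-quality screen: one rosette reference, large- and small-leaf
#' caulescent dicots, a bushy multi-plant pot, and three grasses. Effect
#' dynamics are species-specific and partly transient.
#'
#' @return Named list of [morphotype()] objects.
#' @export
default_morphotypes <- function() {
  list(
    rosetta = morphotype(
      "rosetta", habit = "rosette", height_mm = 28, width_mm = 95,
      n_leaves = 11, leaf_angle_deg = 10, leaf_aspect = 0.55,
      color = c(62, 118, 52),
      effects = list(
        area = effect_fun(peak_slope = -0.05, onset_day = 4, peak_day = 18,
                          shape = 1),
        greenness = effect_fun(peak_slope = -0.03, onset_day = 4,
                               peak_day = 20, shape = 0)
      )
    ),
    lycop = morphotype(
      "lycop", habit = "caulescent", height_mm = 175, width_mm = 120,
      n_leaves = 9, leaf_angle_deg = 25, leaf_aspect = 0.45,
      color = c(68, 125, 58),
      effects = list(
        height = effect_fun(peak_slope = 0.10, onset_day = 2, peak_day = 14,
                            shape = 2),
        greenness = effect_fun(peak_slope = -0.04, onset_day = 2,
                               peak_day = 14, shape = 1)
      )
    ),
    basil = morphotype(
      "basil", habit = "bush", height_mm = 110, width_mm = 100,
      n_leaves = 7, leaf_angle_deg = 35, leaf_aspect = 0.6, n_plants = 6,
      color = c(55, 115, 50),
      effects = list()
    ),
    euphor = morphotype(
      "euphor", habit = "bush", height_mm = 95, width_mm = 85,
      n_leaves = 6, leaf_angle_deg = 40, leaf_aspect = 0.5, n_plants = 6,
      color = c(80, 130, 60),
      effects = list(
        area = effect_fun(peak_slope = 0.06, onset_day = 5, peak_day = 24,
                          shape = 1)
      )
    ),
    brachy = morphotype(
      "brachy", habit = "grass", height_mm = 140, width_mm = 110,
      n_leaves = 14, leaf_angle_deg = 55, leaf_aspect = 0.12,
      color = c(75, 128, 62),
      effects = list(
        height = effect_fun(peak_slope = 0.08, onset_day = 3, peak_day = 26,
                            shape = 1),
        area = effect_fun(peak_slope = 0.09, onset_day = 3, peak_day = 26,
                          shape = 1)
      )
    ),
    oryza = morphotype(
      "oryza", habit = "grass", height_mm = 160, width_mm = 95,
      n_leaves = 10, leaf_angle_deg = 65, leaf_aspect = 0.10,
      color = c(70, 122, 58),
      effects = list(
        width = effect_fun(peak_slope = -0.05, onset_day = 4, peak_day = 22,
                           shape = 1),
        greenness = effect_fun(peak_slope = -0.03, onset_day = 4,
                               peak_day = 22, shape = 1)
      )
    ),
    setaria = morphotype(
      "setaria", habit = "grass", height_mm = 130, width_mm = 85,
      n_leaves = 12, leaf_angle_deg = 50, leaf_aspect = 0.12,
      color = c(82, 132, 64),
      effects = list(
        greenness = effect_fun(peak_slope = 0.025, onset_day = 6,
                               peak_day = 20, shape = 1)
      )
    )
  )
}
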