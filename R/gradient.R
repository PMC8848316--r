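# Gradient statistics: per-descriptor ordinary least squares of the
# descriptor value on the log red:blue ratio, the percent effect size
# between the predicted values at the gradient extremes, significance
# categories, and the per-timepoint effect time course.

#' Fit a descriptor against the log red:blue ratio
#'
#' Ordinary least squares of `values` on `ln(ratios)` with the Pearson
#' correlation and the two-sided p-value of the slope (identical to the
#' correlation test p-value for simple OLS). Constant values are a valid
#' degenerate case (slope 0, r 0, p 1); constant ratios are an error since
#' the gradient is then unidentifiable.
#'
#' @param values Numeric descriptor values, one per pot.
#' @param ratios Positive red:blue ratios, one per pot.
#' @param log_base Base of the logarithm used for the regressor (slope and
#'   intercept are reported in this base; effect sizes and p-values are
#'   base-invariant).
#' @return A list of class `gradphen_fit`: `slope`, `intercept`,
#'   `pearson_r`, `r_squared`, `p_value`, `n`, plus internals used for the
#'   effect-size delta-method CI (`sigma2`, `sxx`, `xbar`, `log_base`).
#' @export
fit_descriptor_gradient <- function(values, ratios, log_base = exp(1)) {
  ok <- is.finite(values) & is.finite(ratios)
  values <- values[ok]; ratios <- ratios[ok]
  if (length(values) < 3) stopf("need at least 3 finite value/ratio pairs")
  if (any(ratios <= 0)) stopf("ratios must be positive")
  x <- log(ratios, base = log_base)
  n <- length(x)
  if (stats::var(x) == 0) {
    stopf("all ratios identical: gradient fit is undefined")
  }
  if (stats::var(values) == 0) {
    fit <- list(slope = 0, intercept = values[1], pearson_r = 0,
                r_squared = 0, p_value = 1, n = n,
                sigma2 = 0, sxx = sum((x - mean(x))^2), xbar = mean(x),
                log_base = log_base)
    class(fit) <- "gradphen_fit"
    return(fit)
  }
  lmfit <- stats::lm(values ~ x)
  # noiseless synthetic data fits exactly; the perfect-fit warning is
  # expected there, and the slope p-value (~0) remains the right answer
  sm <- withCallingHandlers(
    summary(lmfit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- sm$coefficients
  r <- stats::cor(x, values)
  fit <- list(
    slope = unname(co[2, 1]), intercept = unname(co[1, 1]),
    pearson_r = r, r_squared = r^2,
    p_value = unname(co[2, 4]), n = n,
    sigma2 = sm$sigma^2, sxx = sum((x - mean(x))^2), xbar = mean(x),
    log_base = log_base
  )
  class(fit) <- "gradphen_fit"
  fit
}

#' Percent effect size across the gradient
#'
#' Predicts the descriptor at the minimal and maximal observed red:blue
#' ratios from the fitted regression; the effect size is the signed percent
#' difference between the two predictions,
#' `100 * (y_max - y_min) / baseline`. The default baseline is the
#' prediction at the minimal ratio. The result does not depend on the
#' logarithm base used in fitting. A confidence interval is attached via
#' the delta method on (intercept, slope) with t(n - 2) quantiles.
#'
#' @param fit A [fit_descriptor_gradient()] result.
#' @param min_ratio,max_ratio The gradient extremes (both observed;
#'   `min_ratio < max_ratio`).
#' @param baseline `"min"`, `"max"` or `"mid"`: which predicted value is
#'   the denominator.
#' @param conf_level Confidence level of the attached interval.
#' @return A list: `effect_percent`, `y_at_min`, `y_at_max`, `conf_low`,
#'   `conf_high`, `undefined` (TRUE when the baseline prediction is not
#'   positive, which invalidates a percent reading).
#' @export
effect_size <- function(fit, min_ratio, max_ratio, baseline = c("min", "max", "mid"),
                        conf_level = 0.95) {
  stopifnot(inherits(fit, "gradphen_fit"))
  baseline <- match.arg(baseline)
  if (!(min_ratio > 0 && max_ratio > min_ratio)) {
    stopf("need 0 < min_ratio < max_ratio")
  }
  x1 <- log(min_ratio, base = fit$log_base)
  x2 <- log(max_ratio, base = fit$log_base)
  a <- fit$intercept; b <- fit$slope
  y1 <- a + b * x1
  y2 <- a + b * x2
  y0 <- switch(baseline, min = y1, max = y2, mid = (y1 + y2) / 2)
  if (!is.finite(y0) || y0 <= 0) {
    return(list(effect_percent = NA_real_, y_at_min = y1, y_at_max = y2,
                conf_low = NA_real_, conf_high = NA_real_, undefined = TRUE))
  }
  g <- 100 * (y2 - y1) / y0
  # delta method: gradient of g wrt (a, b) and the OLS covariance
  dy0 <- switch(baseline,
                min = c(1, x1), max = c(1, x2),
                mid = c(1, (x1 + x2) / 2))
  dg_da <- -100 * (y2 - y1) * dy0[1] / y0^2  # y2 - y1 is intercept-free
  dg_db <- 100 * ((x2 - x1) * y0 - (y2 - y1) * dy0[2]) / y0^2
  var_a <- fit$sigma2 * (1 / fit$n + fit$xbar^2 / fit$sxx)
  var_b <- fit$sigma2 / fit$sxx
  cov_ab <- -fit$sigma2 * fit$xbar / fit$sxx
  var_g <- dg_da^2 * var_a + dg_db^2 * var_b + 2 * dg_da * dg_db * cov_ab
  se <- sqrt(max(var_g, 0))
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = fit$n - 2)
  list(effect_percent = g, y_at_min = y1, y_at_max = y2,
       conf_low = g - tq * se, conf_high = g + tq * se, undefined = FALSE)
}

#' Significance category of a gradient fit
#'
#' Ordered categories with strict inequalities: `NS`, then `p<0.05`, then
#' `p<0.01` (threshold labels follow the configured cut-offs).
#'
#' @param p_value Numeric vector of p-values in [0, 1].
#' @param thresholds Decreasing significance cut-offs.
#' @return Ordered factor with levels `NS < p<0.05 < p<0.01` (for the
#'   default thresholds).
#' @export
classify_significance <- function(p_value, thresholds = c(0.05, 0.01)) {
  stopifnot(all(p_value >= 0 & p_value <= 1, na.rm = TRUE),
            !is.unsorted(rev(thresholds)))
  labels <- c("NS", paste0("p<", thresholds))
  idx <- rep(1L, length(p_value))
  for (k in seq_along(thresholds)) {
    idx[!is.na(p_value) & p_value < thresholds[k]] <- k + 1L
  }
  idx[is.na(p_value)] <- NA_integer_
  factor(labels[idx], levels = labels, ordered = TRUE)
}

#' Effect-size time course over species, descriptors and days
#'
#' Runs the gradient regression for every species x descriptor x day cell
#' of a long descriptor table and attaches effect sizes (computed between
#' the per-species observed minimal and maximal ratios), significance
#' categories and a post-treatment flag. Cells with fewer than `min_n`
#' usable pots, or an undefined fit, are omitted with a message.
#'
#' @param data Data frame with columns `species`, `day`, `ratio` and the
#'   descriptor columns.
#' @param descriptors Character vector of descriptor column names to
#'   analyse.
#' @param treatment_days Days after which a timepoint is flagged
#'   post-treatment.
#' @param baseline,log_base,thresholds Passed to the component functions.
#' @param min_n Minimum pots per cell.
#' @return Tibble: one row per species x descriptor x day with `slope`,
#'   `intercept`, `pearson_r`, `r_squared`, `p_value`, `n`, `y_at_min`,
#'   `y_at_max`, `effect_percent`, `conf_low`, `conf_high`,
#'   `significance`, `post_treatment`.
#' @export
effect_time_course <- function(data, descriptors,
                               treatment_days = 30,
                               baseline = "min", log_base = exp(1),
                               thresholds = c(0.05, 0.01), min_n = 3L) {
  stopifnot(all(c("species", "day", "ratio") %in% names(data)))
  missing_cols <- setdiff(descriptors, names(data))
  if (length(missing_cols)) {
    stopf("descriptor columns not in data: %s",
          paste(missing_cols, collapse = ", "))
  }
  if (length(unique(data$day)) < 2) {
    stopf("effect_time_course needs at least 2 timepoints")
  }
  cells <- expand.grid(species = unique(data$species),
                       day = sort(unique(data$day)),
                       descriptor = descriptors,
                       stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  skipped <- 0L
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    sub <- data[data$species == cl$species & data$day == cl$day, ]
    v <- sub[[cl$descriptor]]
    ok <- is.finite(v) & is.finite(sub$ratio) & sub$ratio > 0
    if (sum(ok) < min_n) {
      skipped <- skipped + 1L
      next
    }
    rmin <- min(sub$ratio[ok]); rmax <- max(sub$ratio[ok])
    if (rmin >= rmax) {
      skipped <- skipped + 1L
      next
    }
    fit <- fit_descriptor_gradient(v[ok], sub$ratio[ok], log_base = log_base)
    es <- effect_size(fit, rmin, rmax, baseline = baseline)
    rows[[i]] <- tibble::tibble(
      species = cl$species, descriptor = cl$descriptor,
      day = cl$day, n = fit$n,
      slope = fit$slope, intercept = fit$intercept,
      pearson_r = fit$pearson_r, r_squared = fit$r_squared,
      p_value = fit$p_value,
      y_at_min = es$y_at_min, y_at_max = es$y_at_max,
      effect_percent = es$effect_percent,
      conf_low = es$conf_low, conf_high = es$conf_high,
      post_treatment = cl$day > treatment_days
    )
  }
  if (skipped > 0) {
    message(sprintf("effect_time_course: %d cell(s) omitted (too few pots or degenerate ratios)",
                    skipped))
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out$significance <- classify_significance(out$p_value, thresholds)
  }
  out
}
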