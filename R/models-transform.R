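#' Fold change in richness per tenfold increase of range size
#'
#' A slope `b` on the log10-log10 scale means a tenfold increase of range
#' size multiplies richness by `10^b`.
#'
#' @param beta Slope of log10 richness per log10 km2.
#' @return Fold change (e.g. 0.218 -> 1.65).
#' @export
backtransform_per_decade <- function(beta) {
  stopifnot(is.finite(beta))
  10^beta
}

#' Percent richness increase per 100-year earlier introduction
#'
#' With a (negative) slope `b` per calendar year on the log10 scale, an
#' introduction 100 years earlier multiplies richness by `10^(-100 b)`;
#' the return value is that change expressed in percent.
#'
#' @param beta Slope of log10 richness per calendar year.
#' @return Percent increase (e.g. -0.00097 -> 25).
#' @export
backtransform_per_century <- function(beta) {
  stopifnot(is.finite(beta))
  (10^(-beta * 100) - 1) * 100
}

#' Percent richness difference across a distance contrast
#'
#' Evaluates `(exp(beta * delta_km) - 1) * 100`: the percent difference in
#' richness between two native-range distances `delta_km` apart. A negative
#' slope and negative delta (closer origin) give a positive percentage.
#'
#' @param beta Slope per km.
#' @param delta_km Distance contrast in km (e.g. -14868, the negated span
#'   of observed centroid distances).
#' @return Percent difference.
#' @export
distance_effect_percent <- function(beta, delta_km) {
  stopifnot(is.finite(beta), is.finite(delta_km))
  (exp(beta * delta_km) - 1) * 100
}

#' Years of residence implied by a crossover introduction year
#'
#' @param crossover_year Introduction year at which predicted richness
#'   reaches the target.
#' @param reference_year Present-day reference (default 2025).
#' @return `reference_year - crossover_year`.
#' @export
residence_years <- function(crossover_year, reference_year = 2025) {
  stopifnot(is.finite(crossover_year), is.finite(reference_year))
  if (any(reference_year < crossover_year)) {
    stop("reference_year must not precede crossover_year", call. = FALSE)
  }
  reference_year - crossover_year
}

#' Group means, standard errors and fold contrasts of a response
#'
#' Arithmetic mean and SE of the raw-scale response per origin x woodiness
#' group, with the derived contrasts: the native/non-native fold (and
#' percent difference) within each woodiness class, and the
#' woody/non-woody fold within each origin.
#'
#' @param plants Data frame with `origin`, `woodiness` and the response.
#' @param response Response column name (default `"richness"`).
#' @return A `troph_group_summary`: list with `groups` and `contrasts`
#'   tibbles.
#' @export
group_summary <- function(plants, response = "richness") {
  stopifnot(all(c("origin", "woodiness", response) %in% names(plants)))
  d <- plants[plants$woodiness %in% c("woody", "non-woody"), ]
  groups <- d |>
    dplyr::group_by(.data$origin, .data$woodiness) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[response]]),
                     se = sd(.data[[response]]) / sqrt(dplyr::n()),
                     .groups = "drop")
  if (any(groups$n == 0)) stop("empty origin x woodiness group",
                               call. = FALSE)
  gm <- function(o, w) groups$mean[groups$origin == o & groups$woodiness == w]
  contrasts <- list()
  for (w in intersect(c("non-woody", "woody"), groups$woodiness)) {
    if (length(gm("native", w)) && length(gm("non-native", w))) {
      contrasts[[length(contrasts) + 1L]] <- tibble::tibble(
        contrast = sprintf("native vs non-native (%s)", w),
        fold = fold_ratio(gm("native", w), gm("non-native", w)))
    }
  }
  for (o in intersect(c("native", "non-native"), groups$origin)) {
    if (length(gm(o, "woody")) && length(gm(o, "non-woody"))) {
      contrasts[[length(contrasts) + 1L]] <- tibble::tibble(
        contrast = sprintf("woody vs non-woody (%s)", o),
        fold = fold_ratio(gm(o, "woody"), gm(o, "non-woody")))
    }
  }
  contrasts <- dplyr::bind_rows(contrasts)
  if (nrow(contrasts) > 0) contrasts$percent <- (contrasts$fold - 1) * 100
  structure(list(groups = groups, contrasts = contrasts),
            class = "troph_group_summary")
}

#' Ratio of two group means and its percent form
#'
#' @param mean_a,mean_b Group means (`mean_b` > 0).
#' @return Fold ratio `mean_a / mean_b`.
#' @export
fold_ratio <- function(mean_a, mean_b) {
  stopifnot(is.finite(mean_a), is.finite(mean_b), mean_b > 0)
  mean_a / mean_b
}

#' @export
print.troph_group_summary <- function(x, ...) {
  cat("Group means (raw scale)\n")
  print(x$groups)
  cat("\nContrasts\n")
  print(x$contrasts)
  invisible(x)
}

#' Covariate value at which predicted richness reaches a target
#'
#' Inverts a fitted drivers model: holding the other covariates at
#' reference values (by default the means of the fitted sample, relatedness
#' at its modal level), finds the predictor value at which the predicted
#' mean log10 richness equals `log10(target_mean_richness)` for the given
#' woodiness class. The prediction is linear in the predictor, so the
#' inversion is exact.
#'
#' @param fit A drivers `troph_fit`.
#' @param target_mean_richness Target richness on the natural scale (e.g.
#'   the mean richness of native plants).
#' @param predictor `"range_size"` (solves on log10 AOO, returns km2) or
#'   `"intro_year"` (returns a calendar year).
#' @param woodiness `"non-woody"` or `"woody"`.
#' @param reference_values Optional named list overriding reference values
#'   of `log10_aoo`, `intro_year`, `centroid_dist_km` (original scales) or
#'   `relatedness`.
#' @return The crossover value on the predictor's natural scale.
#' @export
crossover_threshold <- function(fit, target_mean_richness,
                                predictor = c("range_size", "intro_year"),
                                woodiness = c("non-woody", "woody"),
                                reference_values = NULL) {
  stopifnot(inherits(fit, "troph_fit"), fit$type == "drivers",
            target_mean_richness > 0)
  predictor <- match.arg(predictor)
  woodiness <- match.arg(woodiness)
  d <- fit$data

  ref <- list(
    log10_aoo = fit$centers[["log10_aoo"]] +
      mean(d$log10_aoo) * fit$scales[["log10_aoo"]],
    intro_year = fit$centers[["intro_year"]] +
      mean(d$intro_year_s) * fit$scales[["intro_year"]],
    centroid_dist_km = fit$centers[["centroid_dist_km"]] +
      mean(d$centroid_dist_s) * fit$scales[["centroid_dist_km"]],
    relatedness = names(which.max(table(d$relatedness))))
  if (!is.null(reference_values)) ref <- modifyList(ref, reference_values)

  newrow <- function(value) {
    x <- tibble::tibble(
      woodiness = factor(woodiness, levels = levels(d$woodiness)),
      relatedness = factor(ref$relatedness, levels = levels(d$relatedness)),
      log10_aoo = (ref$log10_aoo - fit$centers[["log10_aoo"]]) /
        fit$scales[["log10_aoo"]],
      intro_year_s = (ref$intro_year - fit$centers[["intro_year"]]) /
        fit$scales[["intro_year"]],
      centroid_dist_s = (ref$centroid_dist_km -
                           fit$centers[["centroid_dist_km"]]) /
        fit$scales[["centroid_dist_km"]])
    col <- switch(predictor, range_size = "log10_aoo",
                  intro_year = "intro_year_s")
    x[[col]] <- value
    x
  }
  pred <- function(value) {
    predict(fit$model, newdata = newrow(value), re.form = NA)
  }
  p0 <- 0
  slope <- pred(1) - pred(0)
  if (abs(slope) < 1e-12) {
    stop("predictor slope is zero at this woodiness level: no crossover",
         call. = FALSE)
  }
  internal <- unname(p0 + (log10(target_mean_richness) - pred(p0)) / slope)
  switch(predictor,
         range_size = 10^(internal * fit$scales[["log10_aoo"]] +
                            fit$centers[["log10_aoo"]]),
         intro_year = internal * fit$scales[["intro_year"]] +
           fit$centers[["intro_year"]])
}
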