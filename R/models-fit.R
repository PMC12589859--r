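#' Fit the origin x woodiness mixed model
#'
#' REML linear mixed model with `log10(response)` as outcome, plant origin,
#' woodiness and their interaction as fixed effects, and a random intercept
#' per plant family to absorb phylogenetic non-independence. Rows with
#' missing fixed-effect columns are dropped listwise with a reported count.
#'
#' @param data Data frame with columns `origin` (`"native"`/`"non-native"`),
#'   `woodiness` (`"woody"`/`"non-woody"`; `"unknown"` rows are dropped),
#'   `family`, and the response column.
#' @param response Name of the strictly positive response column
#'   (`"richness"` by default; use `"mean_breadth"` for the host-breadth
#'   model).
#' @param p_values `"normal"` for Wald z-tests, `"satterthwaite"` for
#'   Satterthwaite degrees of freedom (requires lmerTest).
#' @return A `troph_fit`: coefficient table, variance components
#'   (`sigma2_family`, `sigma2_resid`, `sigma2_fixed`), sample sizes,
#'   log-likelihood and the fitted lme4 model.
#' @export
fit_origin_model <- function(data, response = "richness",
                             p_values = c("normal", "satterthwaite")) {
  p_values <- match.arg(p_values)
  vars <- c(response, "origin", "woodiness", "family")
  d <- complete_model_rows(data, vars, response)
  d <- d[d$woodiness %in% c("woody", "non-woody"), , drop = FALSE]
  d$origin <- factor(d$origin, levels = c("native", "non-native"))
  d$woodiness <- factor(d$woodiness, levels = c("non-woody", "woody"))
  d$.y <- log10(d[[response]])
  fit_troph_lmm(.y ~ origin * woodiness + (1 | family), d,
                type = "origin", response = response, centers = NULL,
                p_values = p_values)
}

#' Fit the four-predictor drivers model for non-native plants
#'
#' REML linear mixed model of `log10(richness)` on log10 range size,
#' introduction year, native-range centroid distance and relatedness to the
#' native flora, each interacting with woodiness, with a family random
#' intercept. Covariates are centred (and year/distance internally rescaled
#' for numerical stability); reported slopes are on the original per-unit
#' scales: per log10 km2, per calendar year, per km.
#'
#' @param data Non-native plants with columns `richness`, `aoo_km2`
#'   (> 0), `intro_year`, `centroid_dist_km`, `relatedness`
#'   (`congeneric`/`confamilial`/`unrelated`), `woodiness`, `family`.
#'   Incomplete rows are dropped listwise with a reported count.
#' @param p_values See [fit_origin_model()].
#' @return A `troph_fit`.
#' @export
fit_drivers_model <- function(data, p_values = c("normal", "satterthwaite")) {
  p_values <- match.arg(p_values)
  vars <- c("richness", "aoo_km2", "intro_year", "centroid_dist_km",
            "relatedness", "woodiness", "family")
  d <- complete_model_rows(data, vars, "richness")
  d <- d[d$woodiness %in% c("woody", "non-woody") & d$aoo_km2 > 0, ,
         drop = FALSE]
  if (nrow(d) == 0) stop("no complete rows to fit", call. = FALSE)
  d$woodiness <- factor(d$woodiness, levels = c("non-woody", "woody"))
  d$relatedness <- factor(d$relatedness,
                          levels = c("congeneric", "confamilial",
                                     "unrelated"))
  centers <- c(log10_aoo = mean(log10(d$aoo_km2)),
               intro_year = mean(d$intro_year),
               centroid_dist_km = mean(d$centroid_dist_km))
  # internal scales: year in centuries, distance in Mm, undone on report
  scales <- c(log10_aoo = 1, intro_year = 100, centroid_dist_km = 1000)
  d$log10_aoo <- (log10(d$aoo_km2) - centers[["log10_aoo"]]) /
    scales[["log10_aoo"]]
  d$intro_year_s <- (d$intro_year - centers[["intro_year"]]) /
    scales[["intro_year"]]
  d$centroid_dist_s <- (d$centroid_dist_km - centers[["centroid_dist_km"]]) /
    scales[["centroid_dist_km"]]
  d$.y <- log10(d$richness)
  fit_troph_lmm(
    .y ~ woodiness * (log10_aoo + intro_year_s + centroid_dist_s +
                        relatedness) + (1 | family),
    d, type = "drivers", response = "richness", centers = centers,
    scales = scales, p_values = p_values)
}

complete_model_rows <- function(data, vars, response) {
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    stop("model data lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- stats::complete.cases(data[vars])
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(sprintf("dropping %d rows with missing model variables", n_drop))
  }
  d <- data[keep, , drop = FALSE]
  if (any(d[[response]] <= 0)) {
    stop("response must be strictly positive for the log10 transform",
         call. = FALSE)
  }
  d
}

fit_troph_lmm <- function(formula, d, type, response, centers,
                          scales = NULL, p_values = "normal") {
  if (dplyr::n_distinct(d$family) < 2) {
    stop("need at least 2 plant families to fit a family random intercept",
         call. = FALSE)
  }
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  model <- lme4::lmer(formula, data = d, REML = TRUE, control = ctrl)
  if (lme4::isSingular(model)) {
    warning("singular fit: family variance estimated at (or near) zero",
            call. = FALSE)
  }
  coefs <- extract_coefficients(model, d, formula, p_values)

  # undo internal covariate rescaling so slopes are per original unit
  if (!is.null(scales)) {
    relab <- c(log10_aoo = "log10_aoo", intro_year_s = "intro_year",
               centroid_dist_s = "centroid_dist_km")
    for (nm in names(relab)) {
      sc <- scales[[relab[[nm]]]]
      hit <- grepl(nm, coefs$term, fixed = TRUE)
      coefs$estimate[hit] <- coefs$estimate[hit] / sc
      coefs$se[hit] <- coefs$se[hit] / sc
      coefs$term <- sub(nm, relab[[nm]], coefs$term, fixed = TRUE)
    }
  }

  vc <- as.data.frame(lme4::VarCorr(model))
  sigma2_family <- vc$vcov[vc$grp == "family"]
  sigma2_resid <- vc$vcov[vc$grp == "Residual"]
  sigma2_fixed <- var(as.vector(model.matrix(model) %*% lme4::fixef(model)))

  structure(list(
    model = model,
    type = type,
    response = response,
    coefficients = coefs,
    sigma2_family = sigma2_family,
    sigma2_resid = sigma2_resid,
    sigma2_fixed = sigma2_fixed,
    n_obs = nrow(d),
    n_groups = dplyr::n_distinct(d$family),
    logLik = as.numeric(logLik(model)),
    centers = centers,
    scales = scales,
    data = tibble::as_tibble(d)), class = "troph_fit")
}

extract_coefficients <- function(model, d, formula, p_values) {
  if (p_values == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("Satterthwaite p-values need the lmerTest package",
           call. = FALSE)
    }
    m2 <- lmerTest::lmer(formula, data = d, REML = TRUE)
    sm <- summary(m2)$coefficients
    tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], statistic = sm[, "t value"],
                   df = sm[, "df"], p_value = sm[, "Pr(>|t|)"])
  } else {
    sm <- summary(model)$coefficients
    z <- sm[, "t value"]
    tibble::tibble(term = rownames(sm), estimate = sm[, "Estimate"],
                   se = sm[, "Std. Error"], statistic = z,
                   p_value = 2 * pnorm(-abs(z)))
  }
}

#' @export
print.troph_fit <- function(x, ...) {
  cat(sprintf("Mixed model (%s): log10(%s), %d plants in %d families\n",
              x$type, x$response, x$n_obs, x$n_groups))
  cat(sprintf("variance: fixed %.4f | family %.4f | residual %.4f\n",
              x$sigma2_fixed, x$sigma2_family, x$sigma2_resid))
  r2 <- troph_r2_point(x)
  cat(sprintf("marginal R2 %.3f, conditional R2 %.3f\n",
              r2[["marginal"]], r2[["conditional"]]))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Wald confidence intervals for the fixed effects of a fit
#'
#' @param fit A `troph_fit`.
#' @param level Confidence level (default 0.95).
#' @return Coefficient tibble with `lower` and `upper` columns added.
#' @export
fixef_confint <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "troph_fit"))
  z <- qnorm(1 - (1 - level) / 2)
  out <- fit$coefficients
  out$lower <- out$estimate - z * out$se
  out$upper <- out$estimate + z * out$se
  out
}

#' Woodiness-specific slopes from a drivers fit
#'
#' Combines main and interaction coefficients to give, for each continuous
#' predictor, the slope (and SE) within non-woody and woody plants.
#'
#' @param fit A drivers `troph_fit`.
#' @return Tibble with `predictor`, `woodiness`, `estimate`, `se`.
#' @export
woodiness_slopes <- function(fit) {
  stopifnot(inherits(fit, "troph_fit"), fit$type == "drivers")
  V <- as.matrix(stats::vcov(fit$model))
  beta <- lme4::fixef(fit$model)
  terms_raw <- names(beta)
  relab <- c(log10_aoo = "log10_aoo", intro_year_s = "intro_year",
             centroid_dist_s = "centroid_dist_km")
  rows <- list()
  for (nm in names(relab)) {
    sc <- fit$scales[[relab[[nm]]]]
    i_main <- which(terms_raw == nm)
    i_int <- which(terms_raw == paste0("woodinesswoody:", nm))
    b_nw <- beta[i_main] / sc
    se_nw <- sqrt(V[i_main, i_main]) / sc
    b_w <- (beta[i_main] + beta[i_int]) / sc
    se_w <- sqrt(V[i_main, i_main] + V[i_int, i_int] +
                   2 * V[i_main, i_int]) / sc
    rows[[nm]] <- tibble::tibble(
      predictor = relab[[nm]],
      woodiness = c("non-woody", "woody"),
      estimate = c(b_nw, b_w), se = c(se_nw, se_w))
  }
  dplyr::bind_rows(rows)
}
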