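#' Configuration for the synthetic network generator
#'
#' Bundles every knob of the synthetic bipartite plant-microherbivore
#' generator. Defaults describe a European-flora-sized study system:
#' 5751 native non-woody, 1061 native woody, 2074 non-native non-woody and
#' 1379 non-native woody species; log10 richness driven by log10 range size
#' (slopes 0.218 non-woody / 0.308 woody), introduction year (-0.00097 /
#' -0.0014 per year), and native-range centroid distance (-2.31e-5 /
#' -3.33e-5 per km), with family random intercepts; introduction years
#' uniform on 1493-2000 and centroid distances uniform on 2654-17523 km.
#' Group intercepts are calibrated so that mean richness per origin x
#' woodiness group lands near 4.1 / 6.2 (natives) and 1.8 / 2.2
#' (non-natives), giving the heavy-tailed richness distribution (mode 1)
#' seen in real interaction compilations.
#'
#' `recovery = TRUE` switches to a smaller, brighter regime intended for
#' parameter-recovery studies of the model-fitting machinery: 1000
#' non-native plants in 30 families and intercepts high enough (mean
#' richness around 15) that rounding richness to integers and flooring at 1
#' barely distorts the log10 response. Under the realistic default
#' intercepts that discretisation censors plants at richness 1 and
#' attenuates fitted slopes, which is a property of the data regime, not of
#' the estimator.
#'
#' @param n_native_nonwoody,n_native_woody,n_nonnative_nonwoody,n_nonnative_woody
#'   Plant counts per origin x woodiness group.
#' @param n_families,genera_per_family Taxonomy dimensions.
#' @param beta_range_nonwoody,beta_range_woody Slope of log10 richness per
#'   log10 km2 of range size (non-natives).
#' @param beta_year_nonwoody,beta_year_woody Slope per calendar year.
#' @param beta_dist_nonwoody,beta_dist_woody Slope per km of centroid
#'   distance.
#' @param intercept_native_nonwoody,intercept_native_woody,intercept_nonnative_nonwoody,intercept_nonnative_woody
#'   Group intercepts of latent log10 richness (covariates at their
#'   generating midpoints).
#' @param sd_family,sd_resid Family random-intercept and residual SDs on the
#'   log10 scale.
#' @param specialist_fraction Expected proportion of herbivores with a
#'   single-species host set.
#' @param specialist_native_pref Probability that a specialist attaches to a
#'   native host.
#' @param p_family_restricted Probability that a multi-host herbivore is
#'   confined to one plant family (the source of oligophagy).
#' @param missing_woodiness_fraction Fraction of plants whose reported
#'   woodiness is `"unknown"` (true state retained separately).
#' @param p_congeneric,p_confamilial Relatedness mix of non-natives (the
#'   remainder is unrelated).
#' @param pre1492_fraction Fraction of non-natives given a spurious
#'   pre-1492 first record (they are then excluded downstream).
#' @param near_fraction Fraction of non-natives with native-range centroids
#'   closer than 2500 km to Europe (excluded downstream).
#' @param year_min,year_max Introduction-year span.
#' @param dist_min_km,dist_max_km Centroid-distance span.
#' @param min_cells,max_cells Occupied-cell counts are log-uniform on this
#'   range.
#' @param cell_area_km2 Area of one grid cell.
#' @param region_ni,region_nj Dimensions of the focal-region grid.
#' @param synonym_fraction,genus_only_records,duplicate_records Ingestion
#'   noise written into the raw CSVs: aliased plant names, genus-level rows,
#'   duplicated rows.
#' @param seed Integer RNG seed; all generation is reproducible given the
#'   config.
#' @param recovery Use the parameter-recovery preset (see Details).
#' @return A list of class `troph_config`.
#' @export
synthetic_config <- function(n_native_nonwoody = 5751,
                             n_native_woody = 1061,
                             n_nonnative_nonwoody = 2074,
                             n_nonnative_woody = 1379,
                             n_families = 100,
                             genera_per_family = 12,
                             beta_range_nonwoody = 0.218,
                             beta_range_woody = 0.308,
                             beta_year_nonwoody = -0.00097,
                             beta_year_woody = -0.0014,
                             beta_dist_nonwoody = -2.31e-5,
                             beta_dist_woody = -3.33e-5,
                             intercept_native_nonwoody = 0.44,
                             intercept_native_woody = 0.62,
                             intercept_nonnative_nonwoody = -0.05,
                             intercept_nonnative_woody = -0.05,
                             sd_family = 0.15,
                             sd_resid = 0.35,
                             specialist_fraction = 0.35,
                             specialist_native_pref = 0.9,
                             p_family_restricted = 0.4,
                             missing_woodiness_fraction = 0.22,
                             p_congeneric = 0.703,
                             p_confamilial = 0.258,
                             pre1492_fraction = 0.007,
                             near_fraction = 0.005,
                             year_min = 1493,
                             year_max = 2000,
                             dist_min_km = 2654,
                             dist_max_km = 17523,
                             min_cells = 1,
                             max_cells = 2000,
                             cell_area_km2 = 2500,
                             region_ni = 80,
                             region_nj = 60,
                             synonym_fraction = 0.02,
                             genus_only_records = 25,
                             duplicate_records = 25,
                             seed = 1,
                             recovery = FALSE) {
  cfg <- as.list(environment())
  cfg$recovery <- NULL
  if (isTRUE(recovery)) {
    preset <- list(
      n_native_nonwoody = 250, n_native_woody = 250,
      n_nonnative_nonwoody = 500, n_nonnative_woody = 500,
      n_families = 30, genera_per_family = 10,
      intercept_native_nonwoody = 1.2, intercept_native_woody = 1.35,
      intercept_nonnative_nonwoody = 1.1, intercept_nonnative_woody = 1.3,
      missing_woodiness_fraction = 0, pre1492_fraction = 0,
      near_fraction = 0, synonym_fraction = 0,
      genus_only_records = 0, duplicate_records = 0)
    # explicit user arguments win over the preset
    user <- names(match.call())[-1]
    preset <- preset[setdiff(names(preset), user)]
    cfg <- modifyList(cfg, preset)
  }
  validate_config(cfg)
  structure(cfg, class = "troph_config")
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_native_nonwoody, cfg$n_native_woody,
              cfg$n_nonnative_nonwoody, cfg$n_nonnative_woody)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("plant counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("configuration yields zero plants", call. = FALSE)
  if (cfg$sd_family < 0 || cfg$sd_resid < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  for (p in c("specialist_fraction", "specialist_native_pref",
              "p_family_restricted", "missing_woodiness_fraction",
              "pre1492_fraction", "near_fraction", "synonym_fraction")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop(p, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$p_congeneric + cfg$p_confamilial > 1) {
    stop("p_congeneric + p_confamilial must not exceed 1", call. = FALSE)
  }
  if (cfg$n_families < 1 || cfg$genera_per_family < 1) {
    stop("need at least one family and one genus per family", call. = FALSE)
  }
  if (cfg$min_cells < 1 || cfg$max_cells < cfg$min_cells) {
    stop("cell-count range invalid", call. = FALSE)
  }
  if (cfg$max_cells > cfg$region_ni * cfg$region_nj) {
    stop("max_cells exceeds the number of region grid cells", call. = FALSE)
  }
  if (cfg$year_min > cfg$year_max || cfg$dist_min_km > cfg$dist_max_km) {
    stop("year or distance span inverted", call. = FALSE)
  }
  if (length(cfg$seed) != 1 || !is.finite(cfg$seed)) {
    stop("seed must be a single finite integer", call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic sub-seed per generation stage, kept inside 32-bit range.
sub_seed <- function(seed, stage) {
  as.integer((abs(seed) + stage * 1000003) %% 2147483647L)
}

# Generating-model centering constants: covariate midpoints, so that group
# intercepts are the expected log10 richness of an average plant.
config_centers <- function(cfg) {
  c(log10_aoo = (log10(cfg$min_cells * cfg$cell_area_km2) +
                   log10(cfg$max_cells * cfg$cell_area_km2)) / 2,
    intro_year = (cfg$year_min + cfg$year_max) / 2,
    centroid_dist_km = (cfg$dist_min_km + cfg$dist_max_km) / 2)
}
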