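#' Pipeline configuration
#'
#' Assembles input locations (or a simulate block), the filtering
#' thresholds of the analysis (each exposed with its standard default), and
#' model options into a single validated list for [run_pipeline()].
#'
#' @param simulate A [synthetic_config()] to generate the raw inputs, or
#'   `NULL` to read existing files.
#' @param paths Named list of input CSV paths (`interactions`, `plants`,
#'   `occurrences`, `region_centroids`, `synonyms`, `first_records`);
#'   filled in automatically when simulating.
#' @param outdir Output directory for result tables and the manifest.
#' @param proximity_km Native-range proximity exclusion radius.
#' @param cutoff_year Introduction-year cutoff (records at or before it
#'   drop the species).
#' @param integration_woody_km2,integration_nonwoody_km2 Range-size
#'   thresholds defining trophically well-integrated non-natives.
#' @param cell_area_km2 Grid-cell area for AOO.
#' @param region_ni,region_nj Focal-region grid dimensions (cells `(i, j)`
#'   with `1 <= i <= region_ni`, `1 <= j <= region_nj`).
#' @param europe_lat,europe_lon Reference point for centroid distances.
#' @param n_boot Bootstrap draws for R2 confidence intervals (0 = none).
#' @param p_values `"normal"` or `"satterthwaite"`.
#' @param reference_year Present-day year for residence times.
#' @param seed Seed for stochastic steps (bootstrap); mandatory.
#' @return List of class `troph_pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL,
                            outdir = tempfile("trophinet-run-"),
                            proximity_km = 2500, cutoff_year = 1492,
                            integration_woody_km2 = 270000,
                            integration_nonwoody_km2 = 1.1e6,
                            cell_area_km2 = 2500,
                            region_ni = 80, region_nj = 60,
                            europe_lat = 59.56, europe_lon = 28.21,
                            n_boot = 0,
                            p_values = c("normal", "satterthwaite"),
                            reference_year = 2025, seed = 1) {
  p_values <- match.arg(p_values)
  if (is.null(simulate) && is.null(paths)) {
    stop("either a simulate block or input paths must be given",
         call. = FALSE)
  }
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "troph_config"))
    cell_area_km2 <- simulate$cell_area_km2
    region_ni <- simulate$region_ni
    region_nj <- simulate$region_nj
  } else {
    needed <- c("interactions", "plants", "occurrences",
                "region_centroids", "first_records")
    missing_paths <- setdiff(needed, names(paths))
    if (length(missing_paths) > 0) {
      stop("paths lacks entries: ", paste(missing_paths, collapse = ", "),
           call. = FALSE)
    }
    for (p in unlist(paths)) {
      if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    }
  }
  if (length(seed) != 1 || !is.finite(seed)) {
    stop("a single finite seed is mandatory", call. = FALSE)
  }
  structure(as.list(environment()), class = "troph_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> ingest -> covariates -> specialisation
#' -> models, writing result tables and a run manifest with the seed and
#' row counts at every filtering step. Identical configuration and seed
#' yield identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a result bundle: plant table with covariates, fits,
#'   R2 decomposition, crossover thresholds, group and specialisation
#'   summaries, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "troph_pipeline_config"))
  cfg <- config
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  manifest <- list(package_version = as.character(packageVersion("trophinet")),
                   seed = cfg$seed, counts = list())
  note <- function(key, value) {
    manifest$counts[[key]] <<- value
  }
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- with_stage("simulate", write_synthetic_dataset(
      cfg$simulate, file.path(cfg$outdir, "raw")))
    cfg$paths <- sim$paths
    truth <- sim$truth
    note("simulated_plants", nrow(sim$plants))
    note("simulated_associations", nrow(sim$interactions))
  }

  # ingest ------------------------------------------------------------
  synonyms <- if (!is.null(cfg$paths$synonyms) &&
                    file.exists(cfg$paths$synonyms)) {
    s <- readr::read_csv(cfg$paths$synonyms, show_col_types = FALSE,
                         progress = FALSE)
    if (nrow(s) > 0) s else NULL
  }
  interactions <- with_stage("ingest", read_interactions(
    cfg$paths$interactions, synonym_map = synonyms))
  note("associations", nrow(interactions))
  note("genus_only_dropped", attr(interactions, "n_genus_only"))
  note("duplicates_collapsed", attr(interactions, "n_duplicates"))
  richness <- richness_per_plant(interactions)

  plants <- with_stage("ingest", read_plants(cfg$paths$plants))
  note("plants_in", nrow(plants))

  # covariates ---------------------------------------------------------
  plants <- with_stage("covariates", fill_woodiness(plants))
  note("woodiness_imputed", attr(plants, "n_imputed"))
  note("woodiness_unresolved", attr(plants, "n_unresolved"))

  native <- plants[plants$origin == "native", ]
  is_non <- plants$origin == "non-native"
  plants$relatedness <- NA_character_
  if (any(is_non)) {
    plants$relatedness[is_non] <- with_stage("covariates",
      classify_relatedness(plants[is_non, ], unique(native$genus),
                           unique(native$family)))
  }

  occurrences <- readr::read_csv(cfg$paths$occurrences,
                                 show_col_types = FALSE, progress = FALSE)
  region_cells <- tidyr::expand_grid(i = seq_len(cfg$region_ni),
                                     j = seq_len(cfg$region_nj))
  aoo <- with_stage("covariates",
                    compute_aoo(occurrences, region_cells,
                                cfg$cell_area_km2))
  plants <- dplyr::left_join(
    plants, dplyr::select(aoo, accepted_name = "species", "aoo_km2"),
    by = "accepted_name")

  first_records <- readr::read_csv(cfg$paths$first_records,
                                   show_col_types = FALSE, progress = FALSE)
  intro <- with_stage("covariates",
                      earliest_introduction(first_records, cfg$cutoff_year))
  note("pre_cutoff_dropped", attr(intro, "n_dropped"))
  plants <- dplyr::left_join(
    plants, dplyr::select(intro, accepted_name = "species", "intro_year"),
    by = "accepted_name")

  centroids <- readr::read_csv(cfg$paths$region_centroids,
                               show_col_types = FALSE, progress = FALSE)
  plants$centroid_dist_km <- NA_real_
  if ("native_regions" %in% names(plants) && any(is_non)) {
    dist <- with_stage("covariates", species_centroid_distances(
      plants[is_non, ], centroids, cfg$europe_lat, cfg$europe_lon))
    plants$centroid_dist_km[is_non] <- dist
  }
  n_before <- nrow(plants)
  plants <- with_stage("covariates",
                       apply_proximity_exclusion(plants, cfg$proximity_km))
  note("proximity_removed", n_before - nrow(plants))

  plants <- dplyr::inner_join(
    plants, dplyr::rename(richness, accepted_name = "plant_name"),
    by = "accepted_name")
  note("plants_with_interactions", nrow(plants))

  # specialisation ------------------------------------------------------
  interactions <- interactions[interactions$plant_name %in%
                                 plants$accepted_name, ]
  breadths <- with_stage("specialisation", host_breadth(interactions))
  profiles <- with_stage("specialisation",
                         herbivore_profiles(interactions, plants))
  plant_breadth <- per_plant_mean_breadth(interactions, breadths)
  plants <- dplyr::left_join(
    plants, dplyr::rename(plant_breadth, accepted_name = "plant_name"),
    by = "accepted_name")
  composition <- with_stage("specialisation", composition_summary(
    interactions, profiles, plants, weights = "none", by = "group"))

  # models --------------------------------------------------------------
  fit_origin <- with_stage("models", fit_origin_model(
    plants, p_values = cfg$p_values))
  groups <- group_summary(plants)
  fit_drivers <- with_stage("models", fit_drivers_model(
    plants[plants$origin == "non-native", ], p_values = cfg$p_values))
  note("drivers_model_n", fit_drivers$n_obs)
  r2 <- with_stage("models", r2_decomposition(
    fit_drivers, n_boot = cfg$n_boot, seed = cfg$seed))

  native_means <- setNames(groups$groups$mean,
                           paste(groups$groups$origin,
                                 groups$groups$woodiness))
  thresholds <- tibble::tibble(
    predictor = rep(c("range_size", "intro_year"), each = 2),
    woodiness = rep(c("non-woody", "woody"), 2))
  thresholds$value <- mapply(function(p, w) {
    tryCatch(crossover_threshold(
      fit_drivers, native_means[[paste("native", w)]], p, w),
      error = function(e) NA_real_)
  }, thresholds$predictor, thresholds$woodiness)
  thresholds$residence_years <- ifelse(
    thresholds$predictor == "intro_year" & !is.na(thresholds$value) &
      thresholds$value <= cfg$reference_year,
    cfg$reference_year - thresholds$value, NA_real_)

  integrated <- with_stage("specialisation", integration_filter(
    plants, cfg$integration_woody_km2, cfg$integration_nonwoody_km2))
  note("integration_dropped", attr(integrated, "n_dropped"))
  note("integrated_plants", nrow(integrated))
  fit_breadth <- with_stage("models", fit_origin_model(
    integrated, response = "mean_breadth", p_values = cfg$p_values))
  breadth_groups <- group_summary(integrated, response = "mean_breadth")

  # outputs --------------------------------------------------------------
  out_tbl <- plants
  out_tbl$cells <- NULL
  readr::write_csv(out_tbl, file.path(cfg$outdir, "plant_table.csv"),
                   progress = FALSE)
  readr::write_csv(profiles, file.path(cfg$outdir, "herbivore_profiles.csv"),
                   progress = FALSE)
  readr::write_csv(composition, file.path(cfg$outdir, "composition.csv"),
                   progress = FALSE)
  readr::write_csv(fit_origin$coefficients,
                   file.path(cfg$outdir, "coefficients_origin.csv"),
                   progress = FALSE)
  readr::write_csv(fit_drivers$coefficients,
                   file.path(cfg$outdir, "coefficients_drivers.csv"),
                   progress = FALSE)
  readr::write_csv(tibble::as_tibble(r2), file.path(cfg$outdir, "r2.csv"),
                   progress = FALSE)
  readr::write_csv(thresholds, file.path(cfg$outdir, "thresholds.csv"),
                   progress = FALSE)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(structure(list(
    plants = plants, interactions = interactions, profiles = profiles,
    composition = composition, fit_origin = fit_origin,
    fit_drivers = fit_drivers, fit_breadth = fit_breadth, r2 = r2,
    groups = groups, breadth_groups = breadth_groups,
    thresholds = thresholds, manifest = manifest, truth = truth,
    outdir = cfg$outdir), class = "troph_pipeline"))
}

# label errors with the pipeline stage they occurred in
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

# mean native-range centroid and distance to the reference point, per plant
species_centroid_distances <- function(nonnatives, centroids, ref_lat,
                                       ref_lon) {
  vapply(nonnatives$native_regions, function(regs) {
    if (is.na(regs) || !nzchar(regs)) return(NA_real_)
    cen <- native_centroid(strsplit(regs, ";")[[1]], centroids)
    great_circle_km(cen[["lat"]], cen[["lon"]], ref_lat, ref_lon)
  }, numeric(1), USE.NAMES = FALSE)
}

#' @export
print.troph_pipeline <- function(x, ...) {
  cat("trophinet pipeline run\n")
  cat("plants analysed:", nrow(x$plants), "\n")
  cat("outputs in:", x$outdir, "\n")
  print(x$groups)
  invisible(x)
}
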