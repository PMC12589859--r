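#' Great-circle distance between points on the Earth
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the mean Earth
#' radius). Inputs are recycled to a common length, so one point can be
#' compared against many.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in kilometres.
#' @examples
#' great_circle_km(59.56, 28.21, 48.85, 2.35) # Europe centroid to Paris
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  to_rad <- pi / 180
  phi1 <- lat1 * to_rad
  phi2 <- lat2 * to_rad
  dphi <- (lat2 - lat1) * to_rad
  dlam <- (lon2 - lon1) * to_rad
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

check_coords <- function(lat, lon) {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop("coordinates must be finite numbers", call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop("latitude out of range [-90, 90]", call. = FALSE)
  }
  if (any(lon <= -180 | lon > 180)) {
    stop("longitude out of range (-180, 180]", call. = FALSE)
  }
  invisible(TRUE)
}

#' Impute missing woodiness by the genus mode
#'
#' Species with unknown woodiness receive the modal (most frequent) observed
#' state within their genus. Genera with no observed state, or with a tie
#' between states, leave the species unclassified. Observed states are never
#' overwritten.
#'
#' @param plants Data frame with columns `genus` and `woodiness`
#'   (`"woody"`, `"non-woody"`, or `"unknown"`/`NA` for missing).
#' @return `plants` with `woodiness` imputed where possible. Attributes
#'   `n_imputed` and `n_unresolved` carry the bookkeeping counts.
#' @export
fill_woodiness <- function(plants) {
  stopifnot(all(c("genus", "woodiness") %in% names(plants)))
  w <- as.character(plants$woodiness)
  w[is.na(w)] <- "unknown"
  bad <- setdiff(unique(w), c("woody", "non-woody", "unknown"))
  if (length(bad) > 0) {
    stop("unrecognised woodiness state(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  observed <- w != "unknown"
  genus_mode <- tapply(w[observed], plants$genus[observed], function(x) {
    tab <- table(x)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else NA_character_
  })
  missing <- !observed
  mode_for <- genus_mode[as.character(plants$genus[missing])]
  filled <- ifelse(is.na(mode_for), "unknown", mode_for)
  w[missing] <- filled
  out <- plants
  out$woodiness <- w
  n_imputed <- sum(filled != "unknown")
  n_unresolved <- sum(filled == "unknown")
  message(sprintf("fill_woodiness: imputed %d species; %d remain unclassified",
                  n_imputed, n_unresolved))
  attr(out, "n_imputed") <- n_imputed
  attr(out, "n_unresolved") <- n_unresolved
  out
}

#' Classify relatedness of non-native plants to the native flora
#'
#' A non-native species is `congeneric` if its genus contains at least one
#' native species, otherwise `confamilial` if only its family does, and
#' `unrelated` if neither. The three labels partition the non-native set.
#'
#' @param nonnative_plants Data frame with columns `genus` and `family`.
#' @param native_genera,native_families Character vectors of genera and
#'   families represented in the native flora.
#' @return Character vector of labels, one per row of `nonnative_plants`.
#' @export
classify_relatedness <- function(nonnative_plants, native_genera,
                                 native_families) {
  stopifnot(all(c("genus", "family") %in% names(nonnative_plants)))
  if (anyNA(nonnative_plants$genus) || anyNA(nonnative_plants$family)) {
    stop("genus and family must be known for all non-native plants",
         call. = FALSE)
  }
  ifelse(nonnative_plants$genus %in% native_genera, "congeneric",
         ifelse(nonnative_plants$family %in% native_families,
                "confamilial", "unrelated"))
}

#' Native-range centroid of one species
#'
#' Averages the centroids of the species' native botanical regions. The mean
#' is taken directly on latitude and longitude (the convention used when
#' averaging country centroids); ranges straddling the antimeridian are not
#' wrapped.
#'
#' @param regions Character vector of region codes where the species is
#'   native.
#' @param region_centroids Data frame with columns `region_code`, `lat`,
#'   `lon`.
#' @return Named numeric vector `c(lat = , lon = )`.
#' @export
native_centroid <- function(regions, region_centroids) {
  stopifnot(all(c("region_code", "lat", "lon") %in% names(region_centroids)))
  if (length(regions) == 0L) {
    stop("no native regions with a centroid entry", call. = FALSE)
  }
  missing <- setdiff(regions, region_centroids$region_code)
  if (length(missing) > 0) {
    stop("no centroid entry for region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  hit <- region_centroids[region_centroids$region_code %in% regions, ]
  c(lat = mean(hit$lat), lon = mean(hit$lon))
}

#' Exclude species whose native range lies close to Europe
#'
#' Removes plants whose native-range centroid falls strictly within
#' `threshold_km` of the European reference point, guarding against
#' artificial proximity caused by averaging disjunct ranges. Distances
#' exactly at the threshold are retained.
#'
#' @param plants Data frame with a `centroid_dist_km` column. Rows with `NA`
#'   distance are retained (they carry no evidence either way).
#' @param threshold_km Exclusion radius in kilometres (default 2500).
#' @return Filtered data frame; attribute `n_removed` records the count.
#' @export
apply_proximity_exclusion <- function(plants, threshold_km = 2500) {
  stopifnot("centroid_dist_km" %in% names(plants))
  drop <- !is.na(plants$centroid_dist_km) &
    plants$centroid_dist_km < threshold_km
  out <- plants[!drop, , drop = FALSE]
  message(sprintf("proximity exclusion: removed %d species (< %s km)",
                  sum(drop), format(threshold_km)))
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Area of occupancy from gridded occurrences
#'
#' AOO is the number of occupied equal-area grid cells that fall inside the
#' focal region, times the cell area. Cells are abstract integer `(i, j)`
#' indices; partially occupied cells count in full.
#'
#' @param occurrences Data frame with columns `species`, `i`, `j` (one row
#'   per occupied cell; duplicates are ignored).
#' @param region_cells Data frame with columns `i`, `j` enumerating the
#'   cells of the focal region.
#' @param cell_area_km2 Area of one grid cell (default 2500 km2, the
#'   resolution used for European occurrence aggregation).
#' @return Tibble with columns `species`, `n_cells`, `aoo_km2`. Species with
#'   no cells inside the region get an AOO of 0.
#' @export
compute_aoo <- function(occurrences, region_cells, cell_area_km2 = 2500) {
  stopifnot(all(c("species", "i", "j") %in% names(occurrences)),
            all(c("i", "j") %in% names(region_cells)),
            cell_area_km2 > 0)
  if (nrow(region_cells) == 0L) {
    stop("region_cells must be non-empty", call. = FALSE)
  }
  occ <- dplyr::distinct(occurrences, .data$species, .data$i, .data$j)
  inside <- dplyr::semi_join(occ, region_cells, by = c("i", "j"))
  counts <- dplyr::count(inside, .data$species, name = "n_cells")
  all_sp <- tibble::tibble(species = unique(occurrences$species))
  out <- dplyr::left_join(all_sp, counts, by = "species")
  out$n_cells[is.na(out$n_cells)] <- 0L
  out$aoo_km2 <- out$n_cells * cell_area_km2
  out
}

#' Earliest introduction year per species
#'
#' Collapses regional first records to the earliest record per species and
#' drops species whose earliest record predates the post-Columbian cutoff
#' (records in the cutoff year itself are excluded: "introduced after").
#'
#' @param records Data frame with columns `species` and `year` (integers;
#'   negative values denote BCE).
#' @param cutoff_year Species whose earliest record is `<= cutoff_year` are
#'   dropped (default 1492).
#' @return Tibble `species`, `intro_year`; attribute `n_dropped` counts the
#'   excluded species.
#' @export
earliest_introduction <- function(records, cutoff_year = 1492) {
  stopifnot(all(c("species", "year") %in% names(records)))
  if (any(!is.finite(records$year))) {
    stop("years must be finite integers", call. = FALSE)
  }
  out <- records |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(intro_year = min(.data$year), .groups = "drop")
  drop <- out$intro_year <= cutoff_year
  message(sprintf(
    "earliest_introduction: dropped %d species with records at or before %d",
    sum(drop), cutoff_year))
  res <- out[!drop, , drop = FALSE]
  attr(res, "n_dropped") <- sum(drop)
  res
}
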