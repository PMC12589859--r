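#' Generate a synthetic flora with taxonomy, origin and covariates
#'
#' Builds the plant side of the synthetic study system: nested
#' family/genus/species labels (genera are homogeneous in growth form, as
#' woodiness is strongly conserved), exact origin x woodiness group counts,
#' a reported woodiness column with a configurable missing fraction, and,
#' for non-natives, introduction years, native-range centroids with region
#' memberships, centroid distance to the European reference point, and
#' occupied grid-cell sets whose counts are log-uniform.
#'
#' Relatedness structure is built in: non-natives are placed into genera
#' shared with natives (congeneric), native families without shared genera
#' (confamilial) or reserved alien families (unrelated) according to the
#' configured mix.
#'
#' @param config A [synthetic_config()].
#' @return Tibble of plants. Truth columns that the raw pipeline inputs do
#'   not expose (`woodiness_true`, `aoo_km2`, `intro_year`,
#'   `centroid_dist_km`, `relatedness_true`, `pre1492`) are included for
#'   test bookkeeping; `cells` is a list-column of occupied `(i, j)` cells.
#' @export
generate_flora <- function(config) {
  stopifnot(inherits(config, "troph_config"))
  cfg <- validate_config(config)
  set.seed(sub_seed(cfg$seed, 0L))

  taxa <- build_taxonomy(cfg)
  genera <- taxa$genera

  quota <- c(native_nonwoody = cfg$n_native_nonwoody,
             native_woody = cfg$n_native_woody,
             nonnative_nonwoody = cfg$n_nonnative_nonwoody,
             nonnative_woody = cfg$n_nonnative_woody)

  # natives first: their genus set defines relatedness for the non-natives
  nat <- rbind(
    assign_native(quota[["native_nonwoody"]], "non-woody", genera),
    assign_native(quota[["native_woody"]], "woody", genera))
  native_genus_ids <- unique(nat$genus_id)
  native_family_ids <- unique(genera$family_id[match(native_genus_ids,
                                                     genera$genus_id)])

  non <- rbind(
    assign_nonnative(quota[["nonnative_nonwoody"]], "non-woody", genera,
                     native_genus_ids, native_family_ids, cfg),
    assign_nonnative(quota[["nonnative_woody"]], "woody", genera,
                     native_genus_ids, native_family_ids, cfg))

  plants <- rbind(
    cbind(nat, origin = rep("native", nrow(nat)),
          relatedness_true = rep(NA_character_, nrow(nat))),
    cbind(non[c("genus_id", "woodiness_true")],
          origin = rep("non-native", nrow(non)),
          relatedness_true = non$relatedness_true))
  plants <- tibble::as_tibble(plants)
  plants$genus <- genera$genus[match(plants$genus_id, genera$genus_id)]
  plants$family <- genera$family[match(plants$genus_id, genera$genus_id)]
  sp_idx <- stats::ave(seq_len(nrow(plants)), plants$genus_id,
                       FUN = seq_along)
  plants$accepted_name <- paste0(plants$genus, " sp", sprintf("%03d", sp_idx))

  # reported woodiness: true state with a missing fraction
  n <- nrow(plants)
  plants$woodiness <- plants$woodiness_true
  hide <- runif(n) < cfg$missing_woodiness_fraction
  plants$woodiness[hide] <- "unknown"

  plants <- nonnative_covariates(plants, cfg)
  regions <- attr(plants, "region_centroids")

  out <- plants[, c("accepted_name", "genus", "family", "origin", "woodiness",
                    "woodiness_true", "relatedness_true", "intro_year",
                    "pre1492", "centroid_lat", "centroid_lon",
                    "centroid_dist_km", "native_regions", "n_cells",
                    "aoo_km2", "cells")]
  attr(out, "region_centroids") <- regions
  out
}

# Families and genera with a fixed growth-form pattern. The last quarter of
# genera in each native family is reserved for confamilial non-natives; a
# trailing ~5% of families is reserved for unrelated non-natives.
build_taxonomy <- function(cfg) {
  n_alien_fam <- if (cfg$n_families >= 4) {
    max(1L, round(0.05 * cfg$n_families))
  } else 0L
  fam_id <- seq_len(cfg$n_families)
  G <- cfg$genera_per_family
  genera <- tidyr::expand_grid(family_id = fam_id, g = seq_len(G))
  genera$genus_id <- seq_len(nrow(genera))
  genera$family <- sprintf("fam%03d", genera$family_id)
  genera$genus <- sprintf("G%03d-%02d", genera$family_id, genera$g)
  genera$woodiness_true <- rep_len(c("non-woody", "woody", "non-woody"),
                                   nrow(genera))
  genera$alien_family <- genera$family_id > cfg$n_families - n_alien_fam
  n_reserved <- if (G >= 4) max(1L, floor(G / 4)) else 0L
  genera$reserved <- genera$g > G - n_reserved
  list(genera = genera, n_alien_fam = n_alien_fam)
}

assign_native <- function(n, woodiness, genera) {
  if (n == 0L) {
    return(data.frame(genus_id = integer(), woodiness_true = character()))
  }
  pool <- genera$genus_id[genera$woodiness_true == woodiness &
                            !genera$alien_family & !genera$reserved]
  if (length(pool) == 0L) {
    pool <- genera$genus_id[genera$woodiness_true == woodiness]
  }
  if (length(pool) == 0L) {
    stop("no genera available for ", woodiness, " natives", call. = FALSE)
  }
  data.frame(genus_id = sample(pool, n, replace = TRUE),
             woodiness_true = woodiness)
}

assign_nonnative <- function(n, woodiness, genera, native_genus_ids,
                             native_family_ids, cfg) {
  empty <- data.frame(genus_id = integer(), woodiness_true = character(),
                      relatedness_true = character())
  if (n == 0L) return(empty)
  right_wood <- genera$woodiness_true == woodiness
  pool_con <- intersect(genera$genus_id[right_wood], native_genus_ids)
  pool_fam <- genera$genus_id[right_wood & genera$reserved &
                                genera$family_id %in% native_family_ids]
  pool_unrel <- genera$genus_id[right_wood & genera$alien_family]
  probs <- c(cfg$p_congeneric, cfg$p_confamilial,
             1 - cfg$p_congeneric - cfg$p_confamilial)
  cat3 <- sample(c("congeneric", "confamilial", "unrelated"), n,
                 replace = TRUE, prob = probs)
  pick <- function(category) {
    pools <- switch(category,
                    congeneric = list(pool_con, pool_fam, pool_unrel),
                    confamilial = list(pool_fam, pool_con, pool_unrel),
                    unrelated = list(pool_unrel, pool_fam, pool_con))
    for (p in pools) if (length(p) > 0) return(p)
    stop("no genera available for non-native plants", call. = FALSE)
  }
  gid <- integer(n)
  for (cat in unique(cat3)) {
    idx <- which(cat3 == cat)
    pool <- pick(cat)
    gid[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }
  # realised relatedness can differ from the draw when a pool was empty
  fam_of <- genera$family_id[match(gid, genera$genus_id)]
  realised <- ifelse(gid %in% native_genus_ids, "congeneric",
                     ifelse(fam_of %in% native_family_ids, "confamilial",
                            "unrelated"))
  data.frame(genus_id = gid, woodiness_true = woodiness,
             relatedness_true = realised)
}

# Introduction years, native-range centroids/regions and occupied cells for
# the non-native plants; natives get NA covariates.
nonnative_covariates <- function(plants, cfg) {
  n <- nrow(plants)
  non <- which(plants$origin == "non-native")
  m <- length(non)

  plants$intro_year <- rep(NA_integer_, n)
  plants$pre1492 <- rep(FALSE, n)
  plants$centroid_lat <- rep(NA_real_, n)
  plants$centroid_lon <- rep(NA_real_, n)
  plants$centroid_dist_km <- rep(NA_real_, n)
  plants$native_regions <- rep(NA_character_, n)
  plants$n_cells <- rep(NA_integer_, n)
  plants$aoo_km2 <- rep(NA_real_, n)
  plants$cells <- rep(list(NULL), n)
  if (m == 0L) return(plants)

  plants$intro_year[non] <- as.integer(round(runif(m, cfg$year_min,
                                                   cfg$year_max)))
  plants$pre1492[non] <- runif(m) < cfg$pre1492_fraction

  d <- runif(m, cfg$dist_min_km, cfg$dist_max_km)
  near <- runif(m) < cfg$near_fraction
  d[near] <- runif(sum(near), 500, 2499)
  bearing <- runif(m, 0, 360)
  dest <- destination_point(EUROPE_CENTROID[["lat"]],
                            EUROPE_CENTROID[["lon"]], bearing, d)
  plants$centroid_lat[non] <- dest$lat
  plants$centroid_lon[non] <- dest$lon
  plants$centroid_dist_km[non] <- d

  # 1 region at the centroid, or 3 with symmetric latitude offsets whose
  # mean is the centroid (exercises centroid averaging downstream)
  three <- runif(m) < 0.3 & abs(dest$lat) <= 84
  region_rows <- vector("list", m)
  counter <- 0L
  codes <- character(m)
  for (k in seq_len(m)) {
    if (three[k]) {
      lats <- dest$lat[k] + c(-5, 0, 5)
      ids <- counter + 1:3
      counter <- counter + 3L
    } else {
      lats <- dest$lat[k]
      ids <- counter + 1L
      counter <- counter + 1L
    }
    region_rows[[k]] <- data.frame(region_code = sprintf("R%05d", ids),
                                   lat = lats, lon = dest$lon[k])
    codes[k] <- paste(sprintf("R%05d", ids), collapse = ";")
  }
  plants$native_regions[non] <- codes
  attr(plants, "region_centroids") <-
    tibble::as_tibble(do.call(rbind, region_rows))

  ncells <- round(10^runif(m, log10(cfg$min_cells), log10(cfg$max_cells)))
  ncells <- pmax(ncells, cfg$min_cells)
  plants$n_cells[non] <- as.integer(ncells)
  plants$aoo_km2[non] <- ncells * cfg$cell_area_km2
  n_grid <- cfg$region_ni * cfg$region_nj
  cells <- vector("list", m)
  for (k in seq_len(m)) {
    inside <- sample.int(n_grid, ncells[k])
    ij <- cbind(i = ((inside - 1L) %% cfg$region_ni) + 1L,
                j = ((inside - 1L) %/% cfg$region_ni) + 1L)
    n_out <- rbinom(1, 3, 0.3) # stray occurrences outside the region
    if (n_out > 0) {
      ij <- rbind(ij, cbind(i = cfg$region_ni + sample.int(10, n_out,
                                                           replace = TRUE),
                            j = sample.int(cfg$region_nj, n_out,
                                           replace = TRUE)))
    }
    cells[[k]] <- ij
  }
  plants$cells[non] <- cells
  plants
}

# Destination point on the sphere: start, initial bearing (deg), distance km.
destination_point <- function(lat, lon, bearing_deg, dist_km) {
  to_rad <- pi / 180
  phi1 <- lat * to_rad
  lam1 <- lon * to_rad
  theta <- bearing_deg * to_rad
  delta <- dist_km / EARTH_RADIUS_KM
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(theta))
  lam2 <- lam1 + atan2(sin(theta) * sin(delta) * cos(phi1),
                       cos(delta) - sin(phi1) * sin(phi2))
  lon2 <- ((lam2 / to_rad + 180) %% 360) - 180
  lon2[lon2 == -180] <- 180
  list(lat = phi2 / to_rad, lon = lon2)
}
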